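#' Write a trial to the on-disk CSV layout
#'
#' Each trial occupies one directory: `grf.csv` (`time_s`, `grf_ap`, `grf_vt`,
#' `grf_ml` at the force-plate rate), `markers.csv` (`time_s` plus one
#' `<side>_<marker>_<axis>` column per channel at the kinematic rate;
#' missing samples stored as empty cells), `events.csv` (`event_type`,
#' `side`, `time_s`) and `meta.json` (ids, trial type, rates, duration).
#'
#' @param trial A `trial_recording`.
#' @param path Directory to create/write.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "trial_recording"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  n_g <- nrow(trial$grf); n_k <- nrow(trial$markers)
  grf <- data.table::data.table(time_s = (seq_len(n_g) - 1L) / trial$fs_grf)
  for (ch in colnames(trial$grf)) grf[[paste0("grf_", ch)]] <- trial$grf[, ch]
  data.table::fwrite(grf, file.path(path, "grf.csv"))
  mk <- data.table::data.table(time_s = (seq_len(n_k) - 1L) / trial$fs_kin)
  for (ch in colnames(trial$markers)) mk[[ch]] <- trial$markers[, ch]
  data.table::fwrite(mk, file.path(path, "markers.csv"), na = "")
  data.table::fwrite(trial$events[, c("event_type", "side", "time_s")],
                     file.path(path, "events.csv"))
  meta <- list(trial_id = trial$trial_id, subject_id = trial$subject_id,
               trial_type = trial$trial_type, fs_grf = trial$fs_grf,
               fs_kin = trial$fs_kin, duration_s = trial$duration_s,
               subject = trial$subject[c("cadence", "step_length")])
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

check_time_column <- function(tm, fs, file) {
  if (any(diff(tm) <= 0))
    stop("non-monotone time column in ", file, " at line ",
         which(diff(tm) <= 0)[1L] + 1L)
  if (max(abs(diff(tm) - 1 / fs)) > 1e-6)
    stop("sampling rate in ", file, " inconsistent with meta.json (",
         fs, " Hz)")
}

#' Read a trial from the on-disk CSV layout
#'
#' Validates column headers, time monotonicity and sampling-rate consistency;
#' empty marker cells are read back as missing values (gap-fill with
#' [fill_gaps_nearest()] before filtering).
#'
#' @param path Trial directory written by [write_trial()].
#' @return A `trial_recording`.
#' @export
read_trial <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  gf <- file.path(path, "grf.csv")
  grf <- data.table::fread(gf, na.strings = "")
  want <- c("time_s", "grf_ap", "grf_vt", "grf_ml")
  if (!identical(names(grf), want))
    stop("malformed header in ", gf, ": expected ", paste(want, collapse = ","))
  check_time_column(grf$time_s, meta$fs_grf, gf)
  mf <- file.path(path, "markers.csv")
  mk <- data.table::fread(mf, na.strings = "")
  if (names(mk)[1L] != "time_s" || !all(marker_names() %in% names(mk)))
    stop("malformed header in ", mf)
  check_time_column(mk$time_s, meta$fs_kin, mf)
  ef <- file.path(path, "events.csv")
  ev <- as.data.frame(data.table::fread(ef))
  if (!identical(names(ev), c("event_type", "side", "time_s")))
    stop("malformed header in ", ef)
  bad <- which(ev$time_s < 0 | ev$time_s >= meta$duration_s)
  if (length(bad) > 0L)
    stop("event time out of [0, ", meta$duration_s, ") in ", ef,
         " at line ", bad[1L] + 1L)
  ev$frame <- round(ev$time_s * meta$fs_kin)
  grf_m <- as.matrix(grf[, -1L])
  colnames(grf_m) <- c("ap", "vt", "ml")
  mk_m <- as.matrix(mk[, marker_names(), with = FALSE])
  structure(list(trial_id = meta$trial_id, subject_id = meta$subject_id,
                 trial_type = meta$trial_type, grf = grf_m, markers = mk_m,
                 events = ev, fs_grf = meta$fs_grf, fs_kin = meta$fs_kin,
                 duration_s = meta$duration_s,
                 subject = c(list(subject_id = meta$subject_id), meta$subject),
                 perturbation = NULL),
            class = "trial_recording")
}

#' Write or read a whole trial store
#'
#' A trial store is a root directory with one subdirectory per trial (named
#' by `trial_id`) and a `manifest.json` listing the trials and the simulation
#' seed.
#'
#' @param trials List of `trial_recording` objects.
#' @param root Store root directory.
#' @return `write_dataset`: `root`, invisibly. `read_dataset`: list of
#'   trials.
#' @export
write_dataset <- function(trials, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (tr in trials) write_trial(tr, file.path(root, tr$trial_id))
  cfg <- attr(trials, "config")
  manifest <- list(trial_ids = vapply(trials, `[[`, "", "trial_id"),
                   seed = if (!is.null(cfg)) cfg$seed else NA)
  jsonlite::write_json(manifest, file.path(root, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(root)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(root) {
  manifest <- jsonlite::read_json(file.path(root, "manifest.json"),
                                  simplifyVector = TRUE)
  trials <- lapply(manifest$trial_ids, function(id)
    read_trial(file.path(root, id)))
  names(trials) <- manifest$trial_ids
  trials
}
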