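#' Peak-decoding configuration
#'
#' @param min_separation_ms Minimum interval between neighbouring detected
#'   peaks in milliseconds (default 250, the physiological minimum between
#'   successive gait events).
#' @param min_height Minimum peak height on the model-output scale (default
#'   0.3).
#' @param fs Frame rate of the decoded trace in Hz (default 120).
#' @return A list of class `peak_config`.
#' @export
peak_config <- function(min_separation_ms = 250, min_height = 0.3, fs = 120) {
  if (min_separation_ms <= 0 || min_height <= 0)
    stop("min_separation_ms and min_height must be positive")
  structure(list(min_separation_ms = min_separation_ms,
                 min_height = min_height, fs = fs), class = "peak_config")
}

#' Convert a duration in milliseconds to whole frames
#'
#' @param ms Duration in milliseconds.
#' @param fs Frame rate in Hz.
#' @return Integer frame count, `round(ms / 1000 * fs)` (50 ms at 120 Hz is 6
#'   frames; 250 ms is 30 frames).
#' @export
ms_to_frames <- function(ms, fs) as.integer(round(ms / 1000 * fs))

#' Decode event frames from a model-output trace
#'
#' Candidate peaks are interior local maxima (strictly greater than both
#' neighbours; a plateau contributes its midpoint frame, rounded down).
#' Candidates below `min_height` are discarded; the rest are suppressed
#' greedily in descending height (ties broken toward the earlier frame) so
#' all surviving peaks are at least `ms_to_frames(min_separation_ms, fs)`
#' frames apart.
#'
#' @param y Numeric trace (length >= 3).
#' @param cfg A [peak_config()].
#' @return Sorted integer vector of 0-based peak frames.
#' @export
find_event_peaks <- function(y, cfg = peak_config()) {
  stopifnot(inherits(cfg, "peak_config"))
  if (length(y) < 3L) stop("trace must have at least 3 frames")
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- seq_along(r$values)
  interior <- k > 1L & k < length(r$values)
  is_peak <- interior & c(FALSE, diff(r$values) > 0) &
    c(r$values[-length(r$values)] > r$values[-1L], FALSE)
  cand <- which(is_peak)
  if (length(cand) == 0L) return(integer(0))
  frames <- as.integer((starts[cand] - 1L + ends[cand] - 1L) %/% 2)  # 0-based midpoint
  heights <- r$values[cand]
  keep <- heights > cfg$min_height
  frames <- frames[keep]; heights <- heights[keep]
  if (length(frames) == 0L) return(integer(0))
  sep <- ms_to_frames(cfg$min_separation_ms, cfg$fs)
  ord <- order(-heights, frames)
  accepted <- integer(0)
  for (i in ord) {
    if (all(abs(frames[i] - accepted) >= sep))
      accepted <- c(accepted, frames[i])
  }
  sort(accepted)
}

#' Match detected event frames to ground truth
#'
#' One-to-one greedy matching by ascending absolute frame difference: the
#' closest (true, detected) pair is matched first, each frame used at most
#' once. Unmatched true events are misses; unmatched detections are extras.
#'
#' @param detected,true Sorted integer frame vectors.
#' @param fs Frame rate in Hz, used to express errors in milliseconds.
#' @return List with `pairs` (data.frame: `true_frame`, `detected_frame`,
#'   `error_ms`), `n_miss`, `n_extra`.
#' @export
match_events <- function(detected, true, fs = 120) {
  if (length(true) == 0L || length(detected) == 0L)
    return(list(pairs = data.frame(true_frame = integer(0),
                                   detected_frame = integer(0),
                                   error_ms = numeric(0)),
                n_miss = length(true), n_extra = length(detected)))
  g <- expand.grid(ti = seq_along(true), di = seq_along(detected))
  g$ad <- abs(true[g$ti] - detected[g$di])
  g <- g[order(g$ad, true[g$ti], detected[g$di]), ]
  used_t <- logical(length(true)); used_d <- logical(length(detected))
  ti <- di <- integer(0)
  for (i in seq_len(nrow(g))) {
    a <- g$ti[i]; b <- g$di[i]
    if (!used_t[a] && !used_d[b]) {
      used_t[a] <- TRUE; used_d[b] <- TRUE
      ti <- c(ti, a); di <- c(di, b)
    }
  }
  ord <- order(true[ti])
  pairs <- data.frame(true_frame = true[ti][ord],
                      detected_frame = detected[di][ord],
                      error_ms = abs(true[ti][ord] - detected[di][ord]) * 1000 / fs)
  list(pairs = pairs, n_miss = sum(!used_t), n_extra = sum(!used_d))
}

#' Tolerance-based detection metrics
#'
#' Mean and SD of the matched absolute errors, plus the detection accuracy at
#' each tolerance: the share of *all* true events whose matched error is
#' within the tolerance (missed events count against accuracy but are
#' excluded from the mean error).
#'
#' @param errors_ms Matched absolute errors in milliseconds.
#' @param n_miss Number of unmatched true events.
#' @param n_extra Number of unmatched detections (reported through).
#' @param tolerances_ms Tolerances in milliseconds (default 50 and 30).
#' @return List with `n_true`, `n_matched`, `n_miss`, `n_extra`,
#'   `mean_error_ms`, `sd_error_ms` and `accuracy_pct` (named vector, percent).
#' @export
detection_metrics <- function(errors_ms, n_miss = 0L, n_extra = 0L,
                              tolerances_ms = c(50, 30)) {
  n_true <- length(errors_ms) + n_miss
  if (n_true == 0L) stop("no true events to evaluate")
  acc <- vapply(tolerances_ms,
                function(tol) 100 * sum(errors_ms <= tol) / n_true, 1)
  names(acc) <- paste0("within_", tolerances_ms, "ms")
  list(n_true = n_true, n_matched = length(errors_ms), n_miss = n_miss,
       n_extra = n_extra,
       mean_error_ms = if (length(errors_ms)) mean(errors_ms) else NA_real_,
       sd_error_ms = if (length(errors_ms) > 1L) sd(errors_ms) else NA_real_,
       accuracy_pct = acc)
}

#' Detect and score events on a set of predicted traces
#'
#' Decodes each trace with [find_event_peaks()], matches against the true
#' left-side event frames with [match_events()] and aggregates
#' [detection_metrics()] overall and per trial type.
#'
#' @param traces List of predicted traces (one per trial).
#' @param true_frames List of 0-based true event frame vectors, same order.
#' @param trial_types Character vector of trial types, same order.
#' @param cfg A [peak_config()].
#' @param tolerances_ms Tolerances passed to [detection_metrics()].
#' @return List with `per_event` (data.frame of matched pairs with trial ids),
#'   `overall` metrics and `by_type` (list of metrics per trial type).
#' @export
evaluate_detection <- function(traces, true_frames, trial_types = NULL,
                               cfg = peak_config(), tolerances_ms = c(50, 30)) {
  stopifnot(length(traces) == length(true_frames))
  ids <- names(traces)
  if (is.null(ids)) ids <- as.character(seq_along(traces))
  if (is.null(trial_types)) trial_types <- rep("all", length(traces))
  rows <- list(); miss <- extra <- integer(length(traces))
  for (i in seq_along(traces)) {
    det <- find_event_peaks(traces[[i]], cfg)
    m <- match_events(det, true_frames[[i]], cfg$fs)
    miss[i] <- m$n_miss; extra[i] <- m$n_extra
    if (nrow(m$pairs) > 0L)
      rows[[length(rows) + 1L]] <-
        cbind(trial_id = ids[i], trial_type = trial_types[i], m$pairs)
  }
  per_event <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trial_id = character(0), trial_type = character(0),
               true_frame = integer(0), detected_frame = integer(0),
               error_ms = numeric(0))
  overall <- detection_metrics(per_event$error_ms, sum(miss), sum(extra),
                               tolerances_ms)
  by_type <- lapply(split(seq_along(traces), trial_types), function(ii) {
    errs <- per_event$error_ms[per_event$trial_id %in% ids[ii]]
    detection_metrics(errs, sum(miss[ii]), sum(extra[ii]), tolerances_ms)
  })
  list(per_event = per_event, overall = overall, by_type = by_type)
}
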