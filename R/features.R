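#' Input channel matrix for one trial
#'
#' Builds the model input for a trial under one of the three dataset
#' selectors:
#' * `grf` — the 3 force channels (AP, VT, ML), low-pass filtered at
#'   `grf_cutoff_hz` (default 50 Hz) at the force-plate rate and decimated to
#'   the kinematic rate;
#' * `marker` — 16 channels: heel, toe, knee and hip markers of both limbs in
#'   AP and VT, gap-filled and low-pass filtered at `kin_cutoff_hz` (default
#'   12 Hz);
#' * `angle` — 6 channels: sagittal foot, shank and thigh angles of both
#'   limbs, computed from the filtered markers.
#'
#' @param trial A `trial_recording`.
#' @param dataset `"grf"`, `"marker"` or `"angle"`.
#' @param grf_cutoff_hz,kin_cutoff_hz Butterworth cutoffs (4th order,
#'   bidirectional).
#' @return Numeric matrix (kinematic frames x channels) with named columns.
#' @export
trial_features <- function(trial, dataset = c("marker", "grf", "angle"),
                           grf_cutoff_hz = 50, kin_cutoff_hz = 12) {
  dataset <- match.arg(dataset)
  stopifnot(inherits(trial, "trial_recording"))
  if (dataset == "grf") {
    spec <- filter_spec(grf_cutoff_hz)
    factor <- trial$fs_grf %/% trial$fs_kin
    out <- apply(trial$grf, 2L, function(ch)
      downsample_to_kin_rate(lowpass_bidirectional(ch, trial$fs_grf, spec),
                             factor))
    colnames(out) <- paste0("grf_", colnames(trial$grf))
    return(out)
  }
  spec <- filter_spec(kin_cutoff_hz)
  mk <- apply(trial$markers, 2L, function(ch)
    lowpass_bidirectional(fill_gaps_nearest(ch), trial$fs_kin, spec))
  colnames(mk) <- colnames(trial$markers)
  if (dataset == "angle") return(segment_angles(mk))
  sel <- as.vector(outer(c("l", "r"),
                         as.vector(outer(c("heel", "toe", "knee", "hip"),
                                         c("ap", "vt"), paste, sep = "_")),
                         paste, sep = "_"))
  mk[, sel, drop = FALSE]
}

#' Prepare model inputs and targets for a set of trials
#'
#' Extracts the input channel matrix ([trial_features()]) and builds the raw
#' and HRF-smoothed per-frame targets for the left-side TD and LO events of
#' every trial (events are detected on the left side, the limb taking the
#' first recovery step after a perturbation).
#'
#' @param trials List of `trial_recording` objects.
#' @param dataset Dataset selector, see [trial_features()].
#' @param hrf An [hrf_params()] for target smoothing.
#' @param ... Passed to [trial_features()].
#' @return A list of class `model_data`: `X` (list of T x D matrices), `y_td`
#'   and `y_lo` (lists of smoothed targets), `frames_td` / `frames_lo` (lists
#'   of 0-based true event frames), `meta` (data.frame), `kernel`.
#' @export
prepare_model_data <- function(trials, dataset = c("marker", "grf", "angle"),
                               hrf = hrf_params(), ...) {
  dataset <- match.arg(dataset)
  stopifnot(length(trials) > 0L)
  fs <- trials[[1L]]$fs_kin
  kernel <- hrf_kernel(hrf, fs)
  n_frames <- round(trials[[1L]]$duration_s * fs)
  X <- lapply(trials, trial_features, dataset = dataset, ...)
  left <- lapply(trials, function(tr) tr$events[tr$events$side == "left", ])
  raw_td <- lapply(left, encode_raw, n_frames = n_frames, mode = "td_only")
  raw_lo <- lapply(left, encode_raw, n_frames = n_frames, mode = "lo_only")
  meta <- data.frame(
    trial_id = vapply(trials, `[[`, "", "trial_id"),
    subject_id = vapply(trials, `[[`, "", "subject_id"),
    trial_type = vapply(trials, `[[`, "", "trial_type"),
    row.names = NULL)
  structure(list(
    X = X,
    y_td = lapply(raw_td, smooth_targets, kernel = kernel),
    y_lo = lapply(raw_lo, smooth_targets, kernel = kernel),
    frames_td = lapply(left, function(e) sort(e$frame[e$event_type == "TD"])),
    frames_lo = lapply(left, function(e) sort(e$frame[e$event_type == "LO"])),
    meta = meta, dataset = dataset, fs = fs, kernel = kernel),
    class = "model_data")
}
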