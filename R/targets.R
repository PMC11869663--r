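#' Encode gait events as a per-frame impulse vector
#'
#' Builds the raw per-frame training target: in `joint` mode touchdowns are
#' encoded as +1, liftoffs as -1 and non-event frames as 0; `td_only` /
#' `lo_only` encode just the one event type as +1 (each event type gets its
#' own model, and the decoder looks for positive peaks).
#'
#' @param events Data frame with columns `event_type` (`"TD"`/`"LO"`) and
#'   `frame` (0-based frame index at the kinematic rate). Typically the
#'   left-side rows of a trial's `events` table.
#' @param n_frames Output length (360 for a 3 s window at 120 Hz).
#' @param mode `"joint"`, `"td_only"` or `"lo_only"`.
#' @return Integer vector of length `n_frames` over \{0, 1, -1\}.
#' @examples
#' ev <- data.frame(event_type = c("TD", "LO"), frame = c(100L, 180L))
#' y <- encode_raw(ev, 360)
#' which(y != 0) - 1L  # 100 180
#' @export
encode_raw <- function(events, n_frames, mode = c("joint", "td_only", "lo_only")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(events), n_frames >= 1L)
  keep <- switch(mode,
                 joint = rep(TRUE, nrow(events)),
                 td_only = events$event_type == "TD",
                 lo_only = events$event_type == "LO")
  ev <- events[keep, , drop = FALSE]
  out <- integer(n_frames)
  if (nrow(ev) == 0L) return(out)
  if (any(ev$frame < 0L | ev$frame >= n_frames))
    stop("event frame out of range [0, ", n_frames - 1L, "]")
  if (anyDuplicated(ev$frame))
    stop("two events share frame ", ev$frame[duplicated(ev$frame)][1L])
  val <- if (mode == "joint") ifelse(ev$event_type == "TD", 1L, -1L) else 1L
  out[ev$frame + 1L] <- val
  out
}

#' Parameters of the double-gamma smoothing kernel
#'
#' The impulse kernel used to spread binary event labels into smooth peaks is
#' a difference of two gamma densities (the canonical hemodynamic-response
#' shape), rescaled to gait time-scales. All times are in seconds.
#'
#' @param peak_delay_s Time-to-peak of the main bump (default 0.25).
#' @param undershoot_delay_s Time-to-trough of the undershoot (default 0.6).
#' @param dispersion_s Width (SD) of the main bump (default 0.08); the
#'   undershoot uses twice this width.
#' @param undershoot_ratio Undershoot amplitude relative to the main bump
#'   (default 0.1); 0 disables the undershoot.
#' @param kernel_len_s Kernel support length (default 1.5); must cover the
#'   undershoot.
#' @return A list of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay_s = 0.25, undershoot_delay_s = 0.6,
                       dispersion_s = 0.08, undershoot_ratio = 0.1,
                       kernel_len_s = 1.5) {
  vals <- c(peak_delay_s, undershoot_delay_s, dispersion_s, kernel_len_s)
  if (any(vals <= 0) || undershoot_ratio < 0)
    stop("all hrf_params fields must be positive (undershoot_ratio >= 0)")
  if (kernel_len_s <= undershoot_delay_s)
    stop("kernel_len_s must cover the undershoot delay")
  structure(list(peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 dispersion_s = dispersion_s,
                 undershoot_ratio = undershoot_ratio,
                 kernel_len_s = kernel_len_s), class = "hrf_params")
}

#' Double-gamma smoothing kernel, peak-aligned and peak-normalized
#'
#' Samples the gamma-difference kernel at the kinematic frame rate, shifts it
#' so its global maximum sits at lag 0 and rescales so that maximum equals
#' exactly 1. Convolving an isolated unit impulse with this kernel therefore
#' yields a smooth peak of height exactly 1 at the event frame, which is what
#' the peak decoder assumes.
#'
#' @param params An [hrf_params()].
#' @param fs Sampling rate in Hz (120 for the kinematic frame grid).
#' @return Numeric vector of kernel values with attribute `peak_index` (the
#'   1-based position of lag 0).
#' @export
hrf_kernel <- function(params = hrf_params(), fs = 120) {
  stopifnot(inherits(params, "hrf_params"))
  t <- seq(0, params$kernel_len_s, by = 1 / fs)
  if (length(t) < 3L) stop("kernel must span at least 3 samples")
  # gamma density with mean p and SD d: shape (p/d)^2, rate p/d^2
  gpdf <- function(t, p, d) dgamma(t, shape = (p / d)^2, rate = p / d^2)
  main <- gpdf(t, params$peak_delay_s, params$dispersion_s)
  k <- main / max(main)
  if (params$undershoot_ratio > 0) {
    under <- gpdf(t, params$undershoot_delay_s, 2 * params$dispersion_s)
    k <- k - params$undershoot_ratio * under / max(under)
  }
  peak <- which.max(k)
  k <- k / k[peak]
  structure(k, peak_index = peak)
}

#' Smooth a raw event vector with a peak-aligned kernel
#'
#' Linear convolution of the \{0, 1, -1\} impulse vector with the kernel,
#' aligned so each event's kernel peak lands on the event frame, then clipped
#' to \[-1, 1\] where overlapping kernels would sum past the encoding range.
#' An isolated event yields a smoothed extremum of exactly +/-1 at its frame.
#'
#' @param raw Integer vector over \{0, 1, -1\} from [encode_raw()].
#' @param kernel Kernel from [hrf_kernel()] (peak-normalized, with a
#'   `peak_index` attribute).
#' @return Numeric vector, same length as `raw`, values in \[-1, 1\].
#' @export
smooth_targets <- function(raw, kernel) {
  stopifnot(all(raw %in% c(-1L, 0L, 1L)))
  peak <- attr(kernel, "peak_index")
  if (is.null(peak)) stop("kernel must carry a peak_index attribute")
  n <- length(raw)
  out <- numeric(n)
  for (j in which(raw != 0)) {
    lo <- j - (peak - 1L)
    idx <- seq.int(lo, lo + length(kernel) - 1L)
    ok <- idx >= 1L & idx <= n
    out[idx[ok]] <- out[idx[ok]] + raw[j] * kernel[ok]
  }
  pmin(pmax(out, -1), 1)
}
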