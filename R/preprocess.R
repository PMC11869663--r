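#' Filter specification for zero-phase low-pass filtering
#'
#' @param cutoff_hz Low-pass cutoff frequency in Hz. Must lie strictly between
#'   0 and the Nyquist frequency of the signal it is applied to.
#' @param order Butterworth filter order (each pass), default 4.
#' @param bidirectional Apply the filter forward and backward for zero phase
#'   shift (default `TRUE`).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(cutoff_hz, order = 4L, bidirectional = TRUE) {
  stopifnot(is.numeric(cutoff_hz), length(cutoff_hz) == 1L, cutoff_hz > 0)
  order <- as.integer(order)
  if (order < 1L) stop("filter order must be >= 1")
  structure(list(cutoff_hz = cutoff_hz, order = order,
                 bidirectional = isTRUE(bidirectional)),
            class = "filter_spec")
}

# scipy-style steady-state initial conditions for a direct-form-II-transposed
# IIR filter, so a constant input produces a constant output from sample one.
lfilter_zi <- function(b, a) {
  n <- length(a)
  comp <- matrix(0, n - 1L, n - 1L)
  comp[1L, ] <- -a[-1L] / a[1L]
  if (n > 2L) comp[cbind(2L:(n - 1L), 1L:(n - 2L))] <- 1
  IminusA <- diag(n - 1L) - t(comp)
  B <- b[-1L] - a[-1L] * b[1L]
  solve(IminusA, B)
}

#' Zero-phase (bidirectional) Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass filter forward and then backward so the net
#' phase shift is zero; the effective attenuation at the cutoff frequency is
#' two -3 dB passes, i.e. amplitude ratio 0.5. Edges are handled by
#' odd-reflection padding with steady-state initial filter conditions, so a
#' constant signal passes through exactly.
#'
#' @param x Numeric vector, a single channel sampled at `fs`. Must contain no
#'   missing values (gap-fill first, see [fill_gaps_nearest()]).
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @examples
#' x <- sin(2 * pi * 2 * seq(0, 3, by = 1 / 120)) + rnorm(361, sd = 0.1)
#' xf <- lowpass_bidirectional(x, 120, filter_spec(12))
#' @export
lowpass_bidirectional <- function(x, fs, spec) {
  stopifnot(inherits(spec, "filter_spec"), is.numeric(x))
  if (anyNA(x)) stop("signal contains missing values; gap-fill before filtering")
  if (spec$cutoff_hz >= fs / 2)
    stop("cutoff_hz must be below the Nyquist frequency (", fs / 2, " Hz)")
  bf <- signal::butter(spec$order, spec$cutoff_hz / (fs / 2), type = "low")
  b <- bf$b
  a <- bf$a
  pad <- 3L * (spec$order + 1L)
  n <- length(x)
  if (n <= pad)
    stop("signal too short for stable bidirectional filtering (need > ",
         pad, " samples, got ", n, ")")
  zi <- lfilter_zi(b, a)
  one_pass <- function(v) cpp_iir_df2t(b, a, v, zi * v[1L])
  xp <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- one_pass(xp)
  if (spec$bidirectional) y <- rev(one_pass(rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' Downsample a force-plate channel to the kinematic frame rate
#'
#' Keeps every `factor`-th sample starting at the first one (frame 0). The
#' signal must already be low-pass filtered below the target Nyquist rate; no
#' additional anti-alias filtering is applied here.
#'
#' @param x Numeric vector sampled at the force-plate rate (600 Hz by default
#'   conventions).
#' @param factor Integer decimation factor, default 5 (600 Hz to 120 Hz).
#' @return Vector of length `length(x) / factor`.
#' @export
downsample_to_kin_rate <- function(x, factor = 5L) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (length(x) %% factor != 0L)
    stop("signal length (", length(x), ") is not divisible by ", factor,
         "; trim the signal to a whole number of kinematic frames first")
  x[seq.int(1L, length(x), by = factor)]
}

#' Fill missing samples with the temporally nearest observed value
#'
#' Every missing sample is replaced by the nearest non-missing sample in time;
#' when the previous and next observations are equidistant the earlier one
#' wins. Observed samples are never altered.
#'
#' @param x Numeric vector, possibly containing `NA`.
#' @return `x` with all `NA` replaced.
#' @examples
#' fill_gaps_nearest(c(NA, NA, 3, 7))  # 3 3 3 7
#' fill_gaps_nearest(c(1, NA, 5))      # 1 1 5 (tie broken to the earlier side)
#' @export
fill_gaps_nearest <- function(x) {
  obs <- which(!is.na(x))
  if (length(obs) == 0L) stop("all values are missing; nothing to fill from")
  if (length(obs) == length(x)) return(x)
  idx <- seq_along(x)
  pi_ <- findInterval(idx, obs)                # last obs <= i (0 if none)
  ni_ <- findInterval(idx - 1L, obs) + 1L      # first obs >= i
  dprev <- ifelse(pi_ == 0L, Inf, idx - obs[pmax(pi_, 1L)])
  dnext <- ifelse(ni_ > length(obs), Inf, obs[pmin(ni_, length(obs))] - idx)
  src <- ifelse(dprev <= dnext, obs[pmax(pi_, 1L)], obs[pmin(ni_, length(obs))])
  x[idx] <- x[src]
  x
}

#' Sagittal-plane segment angles from marker trajectories
#'
#' Computes per-frame foot, shank and thigh angles (degrees) for both limbs
#' from a marker matrix as produced by [simulate_trial()] / [read_trial()].
#' Each angle is measured against the horizontal: the foot angle uses the
#' heel-to-toe vector, the shank the ankle-to-knee vector and the thigh the
#' knee-to-hip vector (distal to proximal), via the four-quadrant arctangent
#' of (delta VT, delta AP). A horizontal segment gives 0 degrees; the foot
#' angle is positive when the toe is higher than the heel.
#'
#' @param markers Numeric matrix (frames x channels) with columns named
#'   `<side>_<marker>_<axis>`, e.g. `l_heel_ap`; sides `l`/`r`, markers
#'   `heel`, `toe`, `ankle`, `knee`, `hip`, axes `ap`/`vt`.
#' @return Matrix (frames x 6) with columns `foot_l`, `foot_r`, `shank_l`,
#'   `shank_r`, `thigh_l`, `thigh_r`, angles in degrees in (-180, 180].
#' @export
segment_angles <- function(markers) {
  stopifnot(is.matrix(markers), !is.null(colnames(markers)))
  if (anyNA(markers)) stop("markers contain missing values; gap-fill first")
  col <- function(nm) {
    if (!nm %in% colnames(markers)) stop("missing marker column: ", nm)
    markers[, nm]
  }
  seg <- function(from, to, side) {
    dap <- col(paste(side, to, "ap", sep = "_")) - col(paste(side, from, "ap", sep = "_"))
    dvt <- col(paste(side, to, "vt", sep = "_")) - col(paste(side, from, "vt", sep = "_"))
    zero <- which(dap == 0 & dvt == 0)
    if (length(zero) > 0L)
      stop("coincident ", from, "/", to, " markers (side ", side,
           ") at frame ", zero[1L] - 1L)
    atan2(dvt, dap) * 180 / pi
  }
  out <- cbind(
    foot_l = seg("heel", "toe", "l"), foot_r = seg("heel", "toe", "r"),
    shank_l = seg("ankle", "knee", "l"), shank_r = seg("ankle", "knee", "r"),
    thigh_l = seg("knee", "hip", "l"), thigh_r = seg("knee", "hip", "r"))
  out
}
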