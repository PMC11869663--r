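# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized/matrix code paths: scalar loops and brute force only.

# Scalar-loop GRU update: every gate element computed with plain arithmetic.
gru_step_scalar <- function(x, h_prev, p) {
  H <- length(h_prev)
  h <- numeric(H)
  for (i in seq_len(H)) {
    az <- p$bz[i]; ar <- p$br[i]; ah <- p$bh[i]
    for (j in seq_along(x)) {
      az <- az + p$Wz[i, j] * x[j]
      ar <- ar + p$Wr[i, j] * x[j]
      ah <- ah + p$Wh[i, j] * x[j]
    }
    for (j in seq_len(H)) {
      az <- az + p$Uz[i, j] * h_prev[j]
      ar <- ar + p$Ur[i, j] * h_prev[j]
    }
    z <- 1 / (1 + exp(-az))
    r <- 1 / (1 + exp(-ar))
    # r depends on the whole gate vector, so recompute ah with r * h_prev
    ahh <- p$bh[i]
    for (j in seq_along(x)) ahh <- ahh + p$Wh[i, j] * x[j]
    for (j in seq_len(H)) {
      rj <- 0
      arj <- p$br[j]
      for (k in seq_along(x)) arj <- arj + p$Wr[j, k] * x[k]
      for (k in seq_len(H)) arj <- arj + p$Ur[j, k] * h_prev[k]
      rj <- 1 / (1 + exp(-arj))
      ahh <- ahh + p$Uh[i, j] * (rj * h_prev[j])
    }
    hbar <- tanh(ahh)
    h[i] <- (1 - z) * h_prev[i] + z * hbar
  }
  h
}

# Scalar-loop scan over a sequence.
gru_scan_scalar <- function(X, p) {
  h <- numeric(nrow(p$Uz))
  out <- matrix(0, nrow(X), length(h))
  for (t in seq_len(nrow(X))) {
    h <- gru_step_scalar(X[t, ], h, p)
    out[t, ] <- h
  }
  out
}

random_cell <- function(input_size, hidden_size, scale = 0.5) {
  p <- gru_cell_params(input_size, hidden_size, init = "zero")
  for (nm in c("Wz", "Wr", "Wh"))
    p[[nm]] <- matrix(runif(hidden_size * input_size, -scale, scale),
                      hidden_size, input_size)
  for (nm in c("Uz", "Ur", "Uh"))
    p[[nm]] <- matrix(runif(hidden_size^2, -scale, scale),
                      hidden_size, hidden_size)
  for (nm in c("bz", "br", "bh"))
    p[[nm]] <- runif(hidden_size, -scale, scale)
  p
}

# Brute-force shift-multiply-accumulate convolution of an impulse vector with
# a peak-aligned kernel, then clipping.
smooth_targets_brute <- function(raw, kernel) {
  peak <- attr(kernel, "peak_index")
  n <- length(raw)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      k_idx <- (i - j) + peak
      if (k_idx >= 1 && k_idx <= length(kernel))
        acc <- acc + raw[j] * kernel[k_idx]
    }
    out[i] <- acc
  }
  pmin(pmax(out, -1), 1)
}

# Independent greedy peak suppression: local maxima above the height floor,
# kept highest-first (earlier frame on ties) under the separation constraint.
find_peaks_brute <- function(y, min_height, sep_frames) {
  cand <- integer(0); hgt <- numeric(0)
  i <- 2L
  n <- length(y)
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L
      if (j < n && y[j + 1L] < y[i]) {
        cand <- c(cand, as.integer(((i - 1L) + (j - 1L)) %/% 2))
        hgt <- c(hgt, y[i])
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  keep <- hgt > min_height
  cand <- cand[keep]; hgt <- hgt[keep]
  acc <- integer(0)
  for (k in order(-hgt, cand)) {
    if (all(abs(cand[k] - acc) >= sep_frames)) acc <- c(acc, cand[k])
  }
  sort(acc)
}

# Tiny noiseless simulator config shared by several tests.
quiet_config <- function(...) {
  synthetic_config(noise_sd = list(grf = 0, marker = 0), ...)
}
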