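#' GRU cell parameter bundle
#'
#' Holds the six weight matrices and three bias vectors of a gated recurrent
#' unit: input-to-hidden `Wz`, `Wr`, `Wh` (hidden x input), hidden-to-hidden
#' `Uz`, `Ur`, `Uh` (hidden x hidden), biases `bz`, `br`, `bh` (length
#' hidden).
#'
#' @param input_size,hidden_size Dimensions.
#' @param init `"glorot"` (the default: uniform Glorot/Xavier input weights
#'   with orthogonal recurrent weights, the customary recipe for stable GRU
#'   training) or `"zero"`.
#' @return A list of class `gru_cell_params`.
#' @export
gru_cell_params <- function(input_size, hidden_size, init = c("glorot", "zero")) {
  init <- match.arg(init)
  wmat <- function(r, c) {
    if (init == "zero") return(matrix(0, r, c))
    lim <- sqrt(6 / (r + c))
    matrix(runif(r * c, -lim, lim), r, c)
  }
  umat <- function(n) {
    if (init == "zero") return(matrix(0, n, n))
    qr.Q(qr(matrix(rnorm(n * n), n, n)))
  }
  structure(list(Wz = wmat(hidden_size, input_size),
                 Wr = wmat(hidden_size, input_size),
                 Wh = wmat(hidden_size, input_size),
                 Uz = umat(hidden_size),
                 Ur = umat(hidden_size),
                 Uh = umat(hidden_size),
                 bz = numeric(hidden_size), br = numeric(hidden_size),
                 bh = numeric(hidden_size)),
            class = "gru_cell_params")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One GRU update step
#'
#' Computes the gated-recurrent-unit state update
#' \deqn{z_t = \sigma(W_z x_t + U_z h_{t-1} + b_z)}
#' \deqn{r_t = \sigma(W_r x_t + U_r h_{t-1} + b_r)}
#' \deqn{\bar h_t = \tanh(W_h x_t + U_h (r_t \odot h_{t-1}) + b_h)}
#' \deqn{h_t = (1 - z_t) \odot h_{t-1} + z_t \odot \bar h_t}
#' The reset gate is the standard formulation (applied to \eqn{h_{t-1}});
#' `literal_reset_gate = TRUE` instead feeds \eqn{x_t} through `Ur` (a
#' non-standard variant kept for replication of alternative write-ups; it
#' requires square-compatible shapes).
#'
#' @param x_t Input vector (length `input_size`).
#' @param h_prev Previous hidden state (length `hidden_size`); the initial
#'   state is the zero vector.
#' @param p A [gru_cell_params()].
#' @param literal_reset_gate See Description; default `FALSE`.
#' @return Hidden state vector `h_t`.
#' @export
gru_step <- function(x_t, h_prev, p, literal_reset_gate = FALSE) {
  stopifnot(inherits(p, "gru_cell_params"))
  if (length(x_t) != ncol(p$Wz) || length(h_prev) != nrow(p$Uz))
    stop("shape mismatch: x_t must have length ", ncol(p$Wz),
         " and h_prev length ", nrow(p$Uz))
  z <- sigmoid(drop(p$Wz %*% x_t) + drop(p$Uz %*% h_prev) + p$bz)
  r_in <- if (literal_reset_gate) drop(p$Ur %*% x_t) else drop(p$Ur %*% h_prev)
  r <- sigmoid(drop(p$Wr %*% x_t) + r_in + p$br)
  hbar <- tanh(drop(p$Wh %*% x_t) + drop(p$Uh %*% (r * h_prev)) + p$bh)
  (1 - z) * h_prev + z * hbar
}

#' Bidirectional GRU layer over a sequence
#'
#' Runs a forward GRU over frames 1..T and a backward GRU over the reversed
#' sequence, then concatenates the two hidden states per frame (the backward
#' states re-aligned to original time order).
#'
#' @param X Sequence matrix (T x input_size).
#' @param layer List with elements `fwd` and `bwd`, each a
#'   [gru_cell_params()] with identical sizes.
#' @param literal_reset_gate Passed to [gru_step()].
#' @return Matrix (T x 2*hidden_size); columns 1..H are the forward states.
#' @export
bigru_sequence <- function(X, layer, literal_reset_gate = FALSE) {
  stopifnot(is.matrix(X))
  if (nrow(X) < 1L) stop("empty sequence")
  scan <- function(p, idx) {
    h <- numeric(nrow(p$Uz))
    out <- matrix(0, length(idx), nrow(p$Uz))
    for (k in seq_along(idx)) {
      h <- gru_step(X[idx[k], ], h, p, literal_reset_gate)
      out[k, ] <- h
    }
    out
  }
  T_ <- nrow(X)
  fwd <- scan(layer$fwd, seq_len(T_))
  bwd <- scan(layer$bwd, rev(seq_len(T_)))[rev(seq_len(T_)), , drop = FALSE]
  cbind(fwd, bwd)
}

#' Build an untrained Bi-GRU detector model
#'
#' Two bidirectional GRU layers followed by per-feature batch normalization,
#' dropout and a per-frame affine dense head mapping to a scalar output (no
#' output nonlinearity; targets live in \[-1, 1\] and the decoder thresholds
#' at 0.3).
#'
#' @param input_size Number of input channels.
#' @param hidden_size Hidden units per direction (both layers).
#' @param dropout_rate Dropout probability in \[0, 1) (default 0.2).
#' @param init Weight initializer, see [gru_cell_params()].
#' @return A list of class `bigru_model` with elements `layers` (l1/l2, each
#'   fwd/bwd) and `head` (gamma, beta, running stats, dense `v`, `b`).
#' @export
bigru_model <- function(input_size, hidden_size, dropout_rate = 0.2,
                        init = "glorot") {
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  f2 <- 2L * hidden_size
  lim <- sqrt(6 / (f2 + 1))
  structure(list(
    layers = list(
      l1 = list(fwd = gru_cell_params(input_size, hidden_size, init),
                bwd = gru_cell_params(input_size, hidden_size, init)),
      l2 = list(fwd = gru_cell_params(f2, hidden_size, init),
                bwd = gru_cell_params(f2, hidden_size, init))),
    head = list(gamma = rep(1, f2), beta = numeric(f2),
                run_mean = NULL, run_var = NULL,
                v = if (init == "zero") numeric(f2) else runif(f2, -lim, lim),
                b = 0, dropout_rate = dropout_rate, eps = 1e-5),
    input_size = input_size, hidden_size = hidden_size),
    class = "bigru_model")
}

#' Forward pass of the Bi-GRU detector (reference implementation)
#'
#' Maps each input sequence to a length-T real-valued event trace:
#' Bi-GRU, Bi-GRU, batch normalization (batch statistics in `train` mode,
#' running statistics in `infer` mode), dropout (inverted scaling in `train`
#' mode, identity in `infer` mode) and a per-frame affine dense layer. This is
#' the plain-R reference path; training uses an equivalent compiled batch
#' engine.
#'
#' @param Xs A single T x D matrix or a list of them (the batch).
#' @param model A [bigru_model()].
#' @param mode `"infer"` (default) or `"train"`.
#' @param dropout_mask Optional pre-drawn inverted-dropout mask (rows =
#'   stacked frames of all sequences, trial-major; entries 0 or 1/(1-p));
#'   drawn from the RNG when `NULL` and `mode = "train"`.
#' @return A list of length-T numeric vectors (one per input sequence).
#' @export
bigru_forward <- function(Xs, model, mode = c("infer", "train"),
                          dropout_mask = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "bigru_model"))
  if (is.matrix(Xs)) Xs <- list(Xs)
  h <- model$head
  if (mode == "infer" && is.null(h$run_mean))
    stop("running batch-norm statistics not available; train the model first ",
         "(or use mode = 'train')")
  O2 <- lapply(Xs, function(X)
    bigru_sequence(bigru_sequence(X, model$layers$l1), model$layers$l2))
  Z <- do.call(rbind, O2)
  if (mode == "train") {
    mu <- colMeans(Z)
    va <- colMeans(sweep(Z, 2L, mu)^2)
  } else {
    mu <- h$run_mean
    va <- h$run_var
  }
  Zn <- sweep(sweep(Z, 2L, mu), 2L, sqrt(va + h$eps), "/")
  Zn <- sweep(sweep(Zn, 2L, h$gamma, "*"), 2L, h$beta, "+")
  if (mode == "train" && h$dropout_rate > 0) {
    if (is.null(dropout_mask))
      dropout_mask <- matrix(rbinom(length(Zn), 1L, 1 - h$dropout_rate) /
                               (1 - h$dropout_rate), nrow(Zn))
    Zn <- Zn * dropout_mask
  }
  y <- drop(Zn %*% h$v) + h$b
  lens <- vapply(Xs, nrow, 1L)
  split(y, rep(seq_along(Xs), lens))
}

#' Weighted squared-error loss
#'
#' The exact training criterion \eqn{L = \sum_t \lambda_t (y_t - \bar y_t)^2}
#' with positive per-frame weights; frames whose target is close to +/-1 (the
#' event peaks) receive higher weight than the abundant non-event frames.
#'
#' @param y_pred,y_true Equal-length numeric vectors.
#' @param lambda Positive weights, same length.
#' @return Scalar loss.
#' @examples
#' weighted_mse(c(0.5, 0.5), c(0, 1), lambda = c(1, 2))  # 0.75
#' @export
weighted_mse <- function(y_pred, y_true, lambda) {
  if (length(y_pred) != length(y_true) || length(y_pred) != length(lambda))
    stop("y_pred, y_true and lambda must have equal length")
  if (any(lambda <= 0)) stop("lambda weights must be positive")
  sum(lambda * (y_pred - y_true)^2)
}

#' Per-frame loss weights from a smoothed target
#'
#' Realizes "frames closer to an event get higher weight" as
#' \eqn{\lambda_t = 1 + \alpha |\bar y_t|}.
#'
#' @param y_true Smoothed target vector.
#' @param alpha Weighting strength (default 9, so event peaks weigh 10x a
#'   non-event frame).
#' @return Positive weight vector.
#' @export
loss_weights <- function(y_true, alpha = 9) 1 + alpha * abs(y_true)
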