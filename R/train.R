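#' Training configuration for the Bi-GRU detector
#'
#' @param hidden_units GRU hidden units per direction (default 64).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size Mini-batch size (default 64 trials).
#' @param max_epochs Maximum number of epochs (default 100).
#' @param patience_epochs Early-stopping patience: training halts after this
#'   many consecutive epochs without validation-loss improvement (default 3).
#' @param loss_weight_alpha Strength of the event-proximity loss weighting
#'   \eqn{\lambda_t = 1 + \alpha |\bar y_t|} (default 9).
#' @param dropout_rate Dropout probability before the dense head (default 0.2).
#' @param test_frac Fraction of trials held out as the test set (default 0.2).
#' @param val_frac Fraction of the remaining training trials used for
#'   validation (default 0.2).
#' @param split_by `"trial"` (shuffle trials) or `"subject"` (keep each
#'   subject's trials in a single partition).
#' @param bn_momentum Exponential-moving-average momentum for the batch-norm
#'   running statistics (default 0.1).
#' @param seed Seed for weight initialization, shuffling and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(hidden_units = 64L, learning_rate = 1e-3,
                         batch_size = 64L, max_epochs = 100L,
                         patience_epochs = 3L, loss_weight_alpha = 9,
                         dropout_rate = 0.2, test_frac = 0.2, val_frac = 0.2,
                         split_by = c("trial", "subject"), bn_momentum = 0.1,
                         seed = 1L) {
  split_by <- match.arg(split_by)
  if (test_frac <= 0 || test_frac >= 1 || val_frac <= 0 || val_frac >= 1)
    stop("split fractions must lie in (0, 1)")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience_epochs = as.integer(patience_epochs),
                 loss_weight_alpha = loss_weight_alpha,
                 dropout_rate = dropout_rate, test_frac = test_frac,
                 val_frac = val_frac, split_by = split_by,
                 bn_momentum = bn_momentum, seed = as.integer(seed)),
            class = "train_config")
}

#' Split trials into train / validation / test partitions
#'
#' First holds out `test_frac` of the trials as the test set, then takes
#' `val_frac` of the remainder for validation. With `split_by = "subject"`
#' whole subjects are assigned to a partition so no subject's trials are
#' shared across partitions. Deterministic given `seed`.
#'
#' @param meta Data frame with one row per trial and a `subject_id` column.
#' @param test_frac,val_frac,split_by,seed See [train_config()].
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(meta, test_frac = 0.2, val_frac = 0.2,
                          split_by = c("trial", "subject"), seed = 1L) {
  split_by <- match.arg(split_by)
  n <- nrow(meta)
  if (n < 5L) stop("need at least 5 trials to split")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (split_by == "trial") {
    perm <- sample.int(n)
    n_test <- round(test_frac * n)
    test <- perm[seq_len(n_test)]
    rest <- perm[-seq_len(n_test)]
    n_val <- round(val_frac * length(rest))
    val <- rest[seq_len(n_val)]
    train <- rest[-seq_len(n_val)]
  } else {
    subj <- unique(meta$subject_id)
    perm <- sample(subj)
    counts <- vapply(perm, function(s) sum(meta$subject_id == s), 1L)
    cum <- cumsum(counts)
    k_test <- which(cum >= test_frac * n)[1L]
    test_subj <- perm[seq_len(k_test)]
    rest_subj <- perm[-seq_len(k_test)]
    rest_counts <- cumsum(counts[-seq_len(k_test)])
    k_val <- which(rest_counts >= val_frac * (n - cum[k_test]))[1L]
    val_subj <- rest_subj[seq_len(k_val)]
    train_subj <- rest_subj[-seq_len(k_val)]
    test <- which(meta$subject_id %in% test_subj)
    val <- which(meta$subject_id %in% val_subj)
    train <- which(meta$subject_id %in% train_subj)
  }
  if (length(train) == 0L || length(val) == 0L || length(test) == 0L)
    stop("split would leave an empty partition; use more trials or smaller fractions")
  list(train = sort(train), val = sort(val), test = sort(test))
}

# --- batch stacking ---------------------------------------------------------
# Sequences are stacked "time-major flat": row t*B + b holds trial b, frame t
# (0-based), which the compiled engine expects.

stack_batch <- function(Xs) {
  T_ <- nrow(Xs[[1L]]); D <- ncol(Xs[[1L]]); B <- length(Xs)
  A <- array(unlist(Xs, use.names = FALSE), dim = c(T_, D, B))
  matrix(aperm(A, c(3L, 1L, 2L)), nrow = B * T_, ncol = D)
}

stack_targets <- function(ys) {
  as.vector(t(matrix(unlist(ys, use.names = FALSE), ncol = length(ys))))
}

unstack_pred <- function(y, B) t(matrix(y, nrow = B))  # T x B

# --- parameter plumbing -----------------------------------------------------

trainable_params <- function(model) {
  list(l1f = unclass(model$layers$l1$fwd), l1b = unclass(model$layers$l1$bwd),
       l2f = unclass(model$layers$l2$fwd), l2b = unclass(model$layers$l2$bwd),
       head = list(gamma = model$head$gamma, beta = model$head$beta,
                   v = model$head$v, b = model$head$b))
}

cpp_params <- function(params, run_mean, run_var) {
  p <- params
  p$head$run_mean <- run_mean
  p$head$run_var <- run_var
  p
}

install_params <- function(model, params, run_mean, run_var) {
  for (nm in c("Wz", "Wr", "Wh", "Uz", "Ur", "Uh", "bz", "br", "bh")) {
    model$layers$l1$fwd[[nm]] <- params$l1f[[nm]]
    model$layers$l1$bwd[[nm]] <- params$l1b[[nm]]
    model$layers$l2$fwd[[nm]] <- params$l2f[[nm]]
    model$layers$l2$bwd[[nm]] <- params$l2b[[nm]]
  }
  model$head$gamma <- params$head$gamma
  model$head$beta <- params$head$beta
  model$head$v <- params$head$v
  model$head$b <- params$head$b
  model$head$run_mean <- run_mean
  model$head$run_var <- run_var
  model
}

# Adam in flattened parameter space; `skeleton` restores the nested shape.
adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = st)
}

# --- training ---------------------------------------------------------------

#' Train a Bi-GRU event detector
#'
#' Mini-batch Adam on the weighted squared-error loss; early stopping monitors
#' the validation loss with the configured patience and the best-validation
#' weights are restored. TD and LO detectors are trained in separate
#' invocations. Input channels are z-scored with training-set statistics
#' (stored in the returned object and re-applied at prediction time).
#'
#' @param data Model data from [prepare_model_data()].
#' @param event_type `"TD"` or `"LO"`.
#' @param split Partition from [split_dataset()]; computed from `config` when
#'   `NULL`.
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return A list of class `gait_detector`: trained `model`, normalization
#'   stats, `history` (per-epoch train/val loss), `split`, `config`.
#' @export
train_bigru <- function(data, event_type = c("TD", "LO"), split = NULL,
                        config = train_config(), verbose = FALSE) {
  event_type <- match.arg(event_type)
  stopifnot(inherits(config, "train_config"))
  ys <- if (event_type == "TD") data$y_td else data$y_lo
  Xs <- data$X
  if (is.null(split))
    split <- split_dataset(data$meta, config$test_frac, config$val_frac,
                           config$split_by, config$seed)
  T_ <- nrow(Xs[[1L]]); D <- ncol(Xs[[1L]])

  # channel z-scoring from the training partition only
  tr_all <- do.call(rbind, Xs[split$train])
  mu <- colMeans(tr_all)
  sdv <- apply(tr_all, 2L, sd)
  sdv[sdv < 1e-12] <- 1
  norm1 <- function(X) sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  Xn <- lapply(Xs, norm1)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  model <- bigru_model(D, config$hidden_units, config$dropout_rate)
  params <- trainable_params(model)
  theta <- unlist(params, use.names = FALSE)
  ast <- adam_state(length(theta))
  f2 <- 2L * config$hidden_units
  run_mean <- numeric(f2)
  run_var <- rep(1, f2)
  mom <- config$bn_momentum

  XF_val <- stack_batch(Xn[split$val])
  yv <- stack_targets(ys[split$val])
  lv <- loss_weights(yv, config$loss_weight_alpha)
  B_val <- length(split$val)

  best_val <- Inf; best <- NULL; wait <- 0L
  n_upd <- 0L  # running-stat updates so far; cumulative average while young
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  no_mask <- matrix(0, 0L, 0L)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(split$train)
    chunks <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tl <- 0
    for (ch in chunks) {
      B <- length(ch)
      XF <- stack_batch(Xn[ch])
      yt <- stack_targets(ys[ch])
      lam <- loss_weights(yt, config$loss_weight_alpha)
      mask <- if (config$dropout_rate > 0)
        matrix(rbinom(B * T_ * f2, 1L, 1 - config$dropout_rate) /
                 (1 - config$dropout_rate), B * T_, f2)
      else no_mask
      res <- cpp_bigru_pass(XF, T_, B, cpp_params(params, run_mean, run_var),
                            yt, lam, mask, TRUE, TRUE, model$head$eps)
      if (!is.finite(res$loss))
        stop("non-finite training loss at epoch ", epoch,
             "; lower the learning rate")
      g <- unlist(res$grads, use.names = FALSE)
      up <- adam_step(theta, g, ast, config$learning_rate)
      theta <- up$theta; ast <- up$state
      params <- utils::relist(theta, params)
      n_upd <- n_upd + 1L
      m <- max(mom, 1 / n_upd)  # so few batches per epoch that a plain EMA
                                # would lag the weights for many epochs
      run_mean <- (1 - m) * run_mean + m * res$bn_mean
      run_var <- (1 - m) * run_var + m * res$bn_var
      tl <- tl + res$loss * B
    }
    tl <- tl / length(split$train)
    valr <- cpp_bigru_pass(XF_val, T_, B_val,
                           cpp_params(params, run_mean, run_var),
                           yv, lv, no_mask, FALSE, FALSE, model$head$eps)
    vl <- valr$loss
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl,
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch, tl, vl))
    if (vl < best_val - 1e-12) {
      best_val <- vl; wait <- 0L
      best <- list(params = params, run_mean = run_mean, run_var = run_var)
    } else {
      wait <- wait + 1L
      if (wait >= config$patience_epochs) break
    }
  }
  if (!is.null(best)) {
    params <- best$params; run_mean <- best$run_mean; run_var <- best$run_var
  }
  model <- install_params(model, params, run_mean, run_var)
  structure(list(model = model, norm = list(mean = mu, sd = sdv),
                 event_type = event_type, history = hist, split = split,
                 config = config, channels = colnames(Xs[[1L]])),
            class = "gait_detector")
}

#' Predict event traces for new trials
#'
#' Applies the stored channel normalization and runs the trained model in
#' inference mode (running batch-norm statistics, dropout inactive).
#'
#' @param object A `gait_detector` from [train_bigru()].
#' @param Xs A T x D matrix or list of them.
#' @param ... Unused.
#' @return A list of length-T numeric event traces.
#' @export
predict.gait_detector <- function(object, Xs, ...) {
  if (is.matrix(Xs)) Xs <- list(Xs)
  norm1 <- function(X) sweep(sweep(X, 2L, object$norm$mean), 2L,
                             object$norm$sd, "/")
  Xn <- lapply(Xs, norm1)
  T_ <- nrow(Xn[[1L]]); B <- length(Xn)
  params <- trainable_params(object$model)
  res <- cpp_bigru_pass(stack_batch(Xn), T_, B,
                        cpp_params(params, object$model$head$run_mean,
                                   object$model$head$run_var),
                        numeric(0), numeric(0), matrix(0, 0L, 0L),
                        FALSE, FALSE, object$model$head$eps)
  yy <- unstack_pred(res$y_pred, B)
  out <- lapply(seq_len(B), function(b) yy[, b])
  names(out) <- names(Xs)
  out
}

#' @export
print.gait_detector <- function(x, ...) {
  cat(sprintf("<gait_detector %s> %d channels, %d hidden units/direction, %d epochs\n",
              x$event_type, length(x$channels), x$config$hidden_units,
              nrow(x$history)))
  cat(sprintf("  best validation loss %.5f\n", min(x$history$val_loss)))
  invisible(x)
}
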