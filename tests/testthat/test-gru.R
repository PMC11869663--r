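test_that("the GRU step reproduces the closed-form limits of its gates", {
  p <- gru_cell_params(3, 2, init = "zero")
  # all parameters zero: z = r = 0.5, candidate = 0, so h stays 0
  expect_equal(gru_step(c(1, 2, 3), c(0, 0), p), c(0, 0))
  # z -> 0 holds the previous state
  p$bz <- rep(-30, 2)
  h_prev <- c(0.4, -0.2)
  expect_equal(gru_step(rnorm(3), h_prev, p), h_prev, tolerance = 1e-10)
  expect_error(gru_step(c(1, 2), c(0, 0), p), "shape")
})

test_that("gru_step matches the scalar-loop oracle over random instances", {
  set.seed(21)
  for (rep in 1:20) {
    d <- sample(1:5, 1); H <- sample(1:5, 1)
    p <- random_cell(d, H)
    x <- rnorm(d); h <- rnorm(H, sd = 0.5)
    expect_equal(gru_step(x, h, p), gru_step_scalar(x, h, p),
                 tolerance = 1e-12)
  }
})

test_that("multi-step hidden states match the oracle and stay inside (-1, 1)", {
  set.seed(22)
  d <- 3; H <- 4
  p <- random_cell(d, H)
  X <- matrix(rnorm(5 * d), 5, d)
  h <- numeric(H)
  for (t in 1:5) {
    h <- gru_step(X[t, ], h, p)
    expect_equal(h, gru_scan_scalar(X[seq_len(t), , drop = FALSE], p)[t, ],
                 tolerance = 1e-10)
    expect_true(all(h > -1 & h < 1))
  }
})

test_that("the bidirectional layer satisfies its structural identities", {
  set.seed(23)
  d <- 3; H <- 4
  layer <- list(fwd = random_cell(d, H), bwd = random_cell(d, H))
  # single frame: both directions see only x_1 from the zero state
  x1 <- matrix(rnorm(d), 1, d)
  out1 <- bigru_sequence(x1, layer)
  expect_equal(out1[1, ], c(gru_step(x1[1, ], numeric(H), layer$fwd),
                            gru_step(x1[1, ], numeric(H), layer$bwd)))
  # identical directions + palindromic input: forward equals reversed backward
  layer_sym <- list(fwd = layer$fwd, bwd = layer$fwd)
  A <- matrix(rnorm(3 * d), 3, d)
  Xpal <- rbind(A, A[2:1, , drop = FALSE])  # rows 1 2 3 2 1
  out <- bigru_sequence(Xpal, layer_sym)
  expect_equal(out[, 1:H], out[5:1, H + 1:H], tolerance = 1e-12)
  expect_error(bigru_sequence(matrix(0, 0, d), layer), "empty")
})

test_that("the backward half equals reverse, forward-scan, reverse", {
  set.seed(24)
  for (rep in 1:5) {
    d <- sample(2:4, 1); H <- sample(2:5, 1); T_ <- sample(2:8, 1)
    layer <- list(fwd = random_cell(d, H), bwd = random_cell(d, H))
    X <- matrix(rnorm(T_ * d), T_, d)
    out <- bigru_sequence(X, layer)
    rev_scan <- gru_scan_scalar(X[T_:1, , drop = FALSE], layer$bwd)
    expect_equal(out[, H + 1:H, drop = FALSE],
                 rev_scan[T_:1, , drop = FALSE], tolerance = 1e-10)
  }
})

test_that("the weighted loss obeys its identities", {
  expect_equal(weighted_mse(c(1, 2, 3), c(1, 2, 3), rep(1, 3)), 0)
  expect_equal(weighted_mse(c(0.5, 0.5), c(0, 1), c(1, 2)), 0.75)
  set.seed(25)
  yp <- rnorm(10); yt <- rnorm(10); lam <- runif(10, 0.1, 2)
  expect_equal(weighted_mse(yp, yt, 3.7 * lam),
               3.7 * weighted_mse(yp, yt, lam))
  expect_gt(weighted_mse(yp, yt, lam), 0)
  expect_error(weighted_mse(yp, yt[-1], lam), "equal length")
  expect_error(weighted_mse(yp, yt, -lam), "positive")
})

test_that("the head behaves per contract in inference mode", {
  set.seed(26)
  m <- bigru_model(3, 4, dropout_rate = 0.5)
  m$head$run_mean <- rnorm(8)
  m$head$run_var <- runif(8, 0.5, 2)
  X <- matrix(rnorm(12 * 3), 12, 3)
  y1 <- bigru_forward(X, m, mode = "infer")
  m0 <- m; m0$head$dropout_rate <- 0
  expect_equal(y1, bigru_forward(X, m0, mode = "infer"))  # dropout inactive
  # zero dense weights: constant output at the bias
  mc <- m; mc$head$v <- numeric(8); mc$head$b <- 2.5
  expect_equal(unname(unlist(bigru_forward(X, mc, mode = "infer"))),
               rep(2.5, 12))
  mnew <- bigru_model(3, 4)
  expect_error(bigru_forward(X, mnew, mode = "infer"), "statistics")
})

test_that("the full forward pass matches a hand-rolled composition of its stages", {
  set.seed(27)
  m <- bigru_model(2, 2, dropout_rate = 0)
  Xs <- lapply(1:3, function(i) matrix(rnorm(4 * 2), 4, 2))
  got <- bigru_forward(Xs, m, mode = "train")
  # oracle: scalar GRU scans, explicit batch-norm, affine head
  O2 <- do.call(rbind, lapply(Xs, function(X) {
    o1f <- gru_scan_scalar(X, m$layers$l1$fwd)
    o1b <- gru_scan_scalar(X[4:1, , drop = FALSE], m$layers$l1$bwd)[4:1, ]
    o1 <- cbind(o1f, o1b)
    o2f <- gru_scan_scalar(o1, m$layers$l2$fwd)
    o2b <- gru_scan_scalar(o1[4:1, , drop = FALSE], m$layers$l2$bwd)[4:1, ]
    cbind(o2f, o2b)
  }))
  mu <- colMeans(O2)
  va <- colMeans(sweep(O2, 2, mu)^2)
  Z <- sweep(sweep(O2, 2, mu), 2, sqrt(va + m$head$eps), "/")
  y_oracle <- drop(sweep(sweep(Z, 2, m$head$gamma, "*"), 2, m$head$beta, "+")
                   %*% m$head$v) + m$head$b
  expect_equal(unname(unlist(got)), unname(y_oracle), tolerance = 1e-8)
})

test_that("the compiled batch engine reproduces the reference forward pass", {
  set.seed(28)
  D <- 5; H <- 4; T_ <- 12; B <- 3
  m <- bigru_model(D, H, dropout_rate = 0)
  Xs <- lapply(1:B, function(i) matrix(rnorm(T_ * D), T_, D))
  ref <- unname(unlist(bigru_forward(Xs, m, mode = "train")))
  tp <- gaitevents:::trainable_params(m)
  res <- gaitevents:::cpp_bigru_pass(
    gaitevents:::stack_batch(Xs), T_, B,
    gaitevents:::cpp_params(tp, numeric(2 * H), rep(1, 2 * H)),
    numeric(0), numeric(0), matrix(0, 0, 0), TRUE, FALSE, m$head$eps)
  got <- as.vector(t(matrix(res$y_pred, nrow = B)))
  # engine computes in single precision
  expect_equal(got, ref, tolerance = 1e-4)
})
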