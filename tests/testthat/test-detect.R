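test_that("peak decoding applies the height and separation rules", {
  cfg <- peak_config()  # 250 ms, 0.3, 120 Hz
  expect_equal(find_event_peaks(numeric(360), cfg), integer(0))
  bump <- function(frame, height, n = 360, half = 5) {
    y <- numeric(n)
    idx <- (frame - half):(frame + half)
    y[idx + 1L] <- height * (1 - abs(idx - frame) / (half + 1))
    y
  }
  expect_equal(find_event_peaks(bump(100, 0.9), cfg), 100L)
  expect_equal(find_event_peaks(bump(100, 0.2), cfg), integer(0))
  # 10 frames apart (< 30): keep the higher; 35 apart: keep both
  expect_equal(find_event_peaks(bump(50, 0.9) + bump(60, 0.8), cfg), 50L)
  expect_equal(find_event_peaks(bump(50, 0.9) + bump(85, 0.8), cfg),
               c(50L, 85L))
  expect_error(find_event_peaks(c(0, 1), cfg), "3 frames")
})

test_that("plateau peaks report the floored midpoint frame", {
  y <- numeric(100)
  y[41:44] <- 0.8  # plateau frames 40..43 -> midpoint floor 41
  expect_equal(find_event_peaks(y, peak_config()), 41L)
})

test_that("decoded peaks always satisfy the stated constraints", {
  set.seed(31)
  cfg <- peak_config()
  sep <- ms_to_frames(cfg$min_separation_ms, cfg$fs)
  for (rep in 1:50) {
    y <- cumsum(rnorm(360, sd = 0.3))
    y <- y - mean(y)
    pk <- find_event_peaks(y, cfg)
    if (length(pk) > 1L) expect_true(all(diff(pk) >= sep))
    for (f in pk) {
      expect_gt(y[f + 1L], cfg$min_height)
      expect_gte(y[f + 1L], y[f])      # not below neighbours
      expect_gte(y[f + 1L], y[f + 2L])
    }
  }
})

test_that("event matching is one-to-one with minimal-error greed", {
  m <- match_events(c(101L, 260L), c(100L, 200L), fs = 120)
  expect_equal(m$pairs$error_ms, c(1000 / 120, 60 * 1000 / 120),
               tolerance = 1e-12)
  ident <- match_events(c(10L, 50L), c(10L, 50L), fs = 120)
  expect_equal(ident$pairs$error_ms, c(0, 0))
  expect_equal(ident$n_miss + ident$n_extra, 0L)
  m2 <- match_events(c(90L, 104L), 100L, fs = 120)
  expect_equal(m2$pairs$detected_frame, 104L)
  expect_equal(m2$pairs$error_ms, 4 * 1000 / 120, tolerance = 1e-12)
  expect_equal(m2$n_extra, 1L)
  m3 <- match_events(integer(0), c(5L, 10L), fs = 120)
  expect_equal(m3$n_miss, 2L)
})

test_that("matching agrees with exhaustive minimal-total-error assignment on small cases", {
  set.seed(32)
  for (rep in 1:25) {
    true <- sort(sample(0:359, sample(1:4, 1)))
    det <- sort(sample(0:359, sample(1:4, 1)))
    m <- match_events(det, true, fs = 120)
    # brute force over all one-to-one assignments
    k <- min(length(true), length(det))
    best <- Inf
    combs_t <- utils::combn(seq_along(true), k, simplify = FALSE)
    perms <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    for (ct in combs_t) for (cd in perms(seq_along(det))) {
      cd_k <- cd[seq_len(k)]
      best <- min(best, sum(abs(true[ct] - det[cd_k])))
    }
    expect_equal(nrow(m$pairs), k)
    # greedy is not always optimal, but must be within the optimum on sorted
    # disjoint gait-like inputs; here assert totals are >= optimum and the
    # pairing is a valid assignment
    expect_gte(sum(abs(m$pairs$true_frame - m$pairs$detected_frame)),
               best - 1e-9)
    expect_false(anyDuplicated(m$pairs$true_frame) > 0)
    expect_false(anyDuplicated(m$pairs$detected_frame) > 0)
  }
})

test_that("error multiset is invariant to input order", {
  set.seed(33)
  true <- sort(sample(0:359, 5)); det <- sort(sample(0:359, 6))
  e1 <- sort(match_events(det, true, 120)$pairs$error_ms)
  e2 <- sort(match_events(rev(det), rev(true), 120)$pairs$error_ms)
  expect_equal(e1, e2)
})

test_that("tolerance metrics follow the stated accuracy definition", {
  m <- detection_metrics(c(8.33, 500), n_miss = 0)
  expect_equal(unname(m$accuracy_pct), c(50, 50))
  expect_equal(m$mean_error_ms, mean(c(8.33, 500)))
  m2 <- detection_metrics(c(0, 0, 0), n_miss = 0)
  expect_equal(unname(m2$accuracy_pct), c(100, 100))
  m3 <- detection_metrics(c(10, 20, 40), n_miss = 1)
  expect_equal(unname(m3$accuracy_pct), c(75, 50))
  expect_equal(m3$n_true, 4L)
  expect_error(detection_metrics(numeric(0), n_miss = 0), "no true events")
})
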