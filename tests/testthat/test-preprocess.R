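test_that("zero-phase filter passes DC exactly and preserves the zero signal", {
  spec <- filter_spec(12)
  expect_equal(lowpass_bidirectional(rep(3.7, 400), 120, spec),
               rep(3.7, 400), tolerance = 1e-10)
  expect_equal(lowpass_bidirectional(numeric(400), 120, spec), numeric(400))
})

test_that("a sinusoid at the cutoff is attenuated to half amplitude by the two passes", {
  fs <- 600
  t <- (0:(5 * fs - 1)) / fs
  x <- sin(2 * pi * 50 * t)
  y <- lowpass_bidirectional(x, fs, filter_spec(50))
  mid <- y[(fs):(4 * fs)]  # away from the edges
  expect_equal(max(abs(mid)), 0.5, tolerance = 0.01)
})

test_that("filtering is idempotent in the passband", {
  fs <- 600
  t <- (0:(3 * fs - 1)) / fs
  x <- sin(2 * pi * 1.2 * t) + 0.5 * cos(2 * pi * 2.5 * t)
  spec <- filter_spec(50)
  y1 <- lowpass_bidirectional(x, fs, spec)
  y2 <- lowpass_bidirectional(y1, fs, spec)
  expect_lt(sqrt(mean((y2 - y1)^2)) / sqrt(mean(y1^2)), 0.01)
})

test_that("filter rejects unusable inputs", {
  expect_error(lowpass_bidirectional(rnorm(10), 120, filter_spec(12)),
               "too short")
  expect_error(lowpass_bidirectional(c(rnorm(100), NA), 120, filter_spec(12)),
               "missing")
  expect_error(lowpass_bidirectional(rnorm(100), 20, filter_spec(12)),
               "Nyquist")
})

test_that("decimation keeps every fifth sample from frame zero", {
  expect_length(downsample_to_kin_rate(numeric(1800)), 360L)
  expect_equal(downsample_to_kin_rate(rep(2.5, 100)), rep(2.5, 20))
  expect_equal(downsample_to_kin_rate(0:1799), seq(0, 1795, by = 5))
  expect_error(downsample_to_kin_rate(numeric(1801)), "divisible")
})

test_that("nearest-value gap filling obeys the earlier-wins tie rule", {
  expect_equal(fill_gaps_nearest(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(fill_gaps_nearest(c(NA, NA, 3, 7)), c(3, 3, 3, 7))
  expect_equal(fill_gaps_nearest(c(1, NA, 5)), c(1, 1, 5))
  expect_error(fill_gaps_nearest(c(NA_real_, NA_real_)), "all values")
})

test_that("gap filling matches an explicit nearest-scan oracle and never alters data", {
  set.seed(4)
  for (rep in 1:20) {
    x <- rnorm(50)
    x[sample(50, 15)] <- NA
    if (all(is.na(x))) next
    filled <- fill_gaps_nearest(x)
    obs <- which(!is.na(x))
    oracle <- vapply(seq_along(x), function(i) {
      d <- abs(obs - i)
      x[obs[which(d == min(d))[1L]]]  # ties: earlier observation
    }, 1)
    expect_equal(filled, oracle)
    expect_identical(filled[obs], x[obs])
    expect_false(anyNA(filled))
  }
})

test_that("segment angles follow the stated conventions", {
  mk <- matrix(0, 2, 20, dimnames = list(NULL, gaitevents:::marker_names()))
  mk[, "l_heel_ap"] <- 0;    mk[, "l_heel_vt"] <- 0
  mk[, "l_toe_ap"] <- 0.20;  mk[, "l_toe_vt"] <- c(0, 0.20)
  mk[, "r_toe_ap"] <- 0.10;  mk[, "r_toe_vt"] <- 0.10
  mk[, "l_ankle_vt"] <- 0.1; mk[, "l_knee_vt"] <- 0.5; mk[, "l_hip_vt"] <- 0.9
  mk[, "r_ankle_vt"] <- 0.1; mk[, "r_knee_vt"] <- 0.5; mk[, "r_hip_vt"] <- 0.9
  ang <- segment_angles(mk)
  expect_equal(unname(ang[1, "foot_l"]), 0)
  expect_equal(unname(ang[2, "foot_l"]), 45)
  expect_equal(unname(ang[1, "foot_r"]), 45)
})

test_that("angles agree with a direct trigonometry oracle and are translation invariant", {
  set.seed(9)
  mk <- matrix(rnorm(40 * 20), 40, 20,
               dimnames = list(NULL, gaitevents:::marker_names()))
  ang <- segment_angles(mk)
  oracle <- atan2(mk[, "l_toe_vt"] - mk[, "l_heel_vt"],
                  mk[, "l_toe_ap"] - mk[, "l_heel_ap"]) * 180 / pi
  expect_equal(ang[, "foot_l"], oracle, tolerance = 1e-10)
  oracle_sh <- atan2(mk[, "r_knee_vt"] - mk[, "r_ankle_vt"],
                     mk[, "r_knee_ap"] - mk[, "r_ankle_ap"]) * 180 / pi
  expect_equal(ang[, "shank_r"], oracle_sh, tolerance = 1e-10)
  mk2 <- mk
  mk2[, grepl("_ap$", colnames(mk2))] <- mk2[, grepl("_ap$", colnames(mk2))] + 3.2
  mk2[, grepl("_vt$", colnames(mk2))] <- mk2[, grepl("_vt$", colnames(mk2))] - 1.1
  expect_equal(segment_angles(mk2), ang, tolerance = 1e-10)
})

test_that("coincident markers are rejected with the offending frame", {
  mk <- matrix(1, 3, 20, dimnames = list(NULL, gaitevents:::marker_names()))
  mk[, "l_toe_ap"] <- c(1.2, 1, 1.2)
  mk[, "l_toe_vt"] <- c(1.2, 1, 1.2)
  mk[, "l_heel_ap"] <- 1; mk[, "l_heel_vt"] <- 1
  expect_error(segment_angles(mk), "frame 1")
})
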