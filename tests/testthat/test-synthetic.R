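test_that("simulation is bitwise deterministic under a fixed seed", {
  cfg <- quiet_config()
  t1 <- simulate_trial(cfg, "slip", seed = 99)
  t2 <- simulate_trial(cfg, "slip", seed = 99)
  expect_identical(t1, t2)
  cfg2 <- synthetic_config(n_subjects = 2, trials_per_type = 1, seed = 7)
  expect_identical(simulate_dataset(cfg2), simulate_dataset(cfg2))
})

test_that("noiseless regular trials have zero vertical force throughout swing", {
  cfg <- quiet_config()
  tr <- simulate_trial(cfg, "regular", seed = 3)
  ev <- tr$events[tr$events$side == "left", ]
  tg <- (seq_len(nrow(tr$grf)) - 1) / tr$fs_grf
  los <- ev$time_s[ev$event_type == "LO"]
  tds <- ev$time_s[ev$event_type == "TD"]
  for (lo in los) {
    nxt <- tds[tds > lo]
    if (length(nxt) == 0L) nxt <- tr$duration_s
    inside <- tg > lo & tg < min(nxt)
    expect_true(all(tr$grf[inside, "vt"] == 0))
  }
})

test_that("a 5%-body-weight threshold scan recovers stored events within one 600 Hz frame", {
  cfg <- quiet_config()
  for (seed in c(3, 17, 41)) {
    tr <- simulate_trial(cfg, "regular", seed = seed)
    vt <- tr$grf[, "vt"]
    above <- vt > 0.05
    cross_up <- which(diff(above) == 1) / tr$fs_grf    # touchdowns
    cross_dn <- which(diff(above) == -1) / tr$fs_grf   # liftoffs
    ev <- tr$events[tr$events$side == "left", ]
    for (t_td in ev$time_s[ev$event_type == "TD"]) {
      expect_lt(min(abs(cross_up - t_td)), 1 / tr$fs_grf + 1e-9)
    }
    for (t_lo in ev$time_s[ev$event_type == "LO"]) {
      expect_lt(min(abs(cross_dn - t_lo)), 1 / tr$fs_grf + 1e-9)
    }
  }
})

test_that("datasets have the configured composition and subject-level parameters", {
  cfg <- synthetic_config(n_subjects = 2, trials_per_type = 1, seed = 5)
  trials <- simulate_dataset(cfg)
  expect_length(trials, 6L)
  subj <- vapply(trials, `[[`, "", "subject_id")
  expect_length(unique(subj), 2L)
  types <- vapply(trials, `[[`, "", "trial_type")
  expect_equal(sort(unique(types)), c("regular", "slip", "trip"))
  # trials within a subject share cadence and step length
  cad <- vapply(trials, function(tr) tr$subject$cadence, 1)
  expect_length(unique(cad[subj == subj[1]]), 1L)
})

test_that("every simulated trial satisfies the recording invariants", {
  cfg <- synthetic_config(n_subjects = 2, trials_per_type = 2, seed = 12)
  trials <- simulate_dataset(cfg)
  for (tr in trials) {
    expect_true(all(tr$grf[, "vt"] >= 0))
    expect_true(all(tr$events$time_s >= 0 & tr$events$time_s < tr$duration_s))
    expect_true(all(tr$events$frame >= 0 &
                      tr$events$frame < tr$duration_s * tr$fs_kin))
    for (s in unique(tr$events$side)) {
      ev <- tr$events[tr$events$side == s, ]
      ev <- ev[order(ev$time_s), ]
      # alternation TD -> LO -> TD and >= 250 ms spacing per side
      expect_true(all(ev$event_type[-1] != ev$event_type[-nrow(ev)]))
      expect_true(all(diff(ev$time_s) >= 0.25 - 1e-9))
    }
  }
})

test_that("empirical stance fraction of noiseless regular trials matches the configuration", {
  cfg <- quiet_config(stance_fraction = 0.60)
  fracs <- vapply(1:5, function(seed) {
    tr <- simulate_trial(cfg, "regular", seed = seed)
    ev <- tr$events[tr$events$side == "left", ]
    tds <- ev$time_s[ev$event_type == "TD"]
    los <- ev$time_s[ev$event_type == "LO"]
    stance <- min(los[los > tds[1]]) - tds[1]
    stance / diff(tds)[1]
  }, 1)
  expect_true(all(abs(fracs - 0.60) <= 0.05))
})

test_that("aborted slip recoveries drag the foot: vertical force never fully unloads", {
  cfg <- quiet_config(slip_params = list(onset_phase = 0.35,
                                         backward_slide_m = 0.12,
                                         recovery_delay_ms_range = c(80, 250),
                                         abort_prob = 1))
  tr <- simulate_trial(cfg, "slip", seed = 8)
  expect_true(isTRUE(tr$perturbation$abort))
  ev <- tr$events[tr$events$side == "left", ]
  # recovery step: first left TD after the slip onset
  rec_td <- min(ev$time_s[ev$event_type == "TD" & ev$time_s > tr$perturbation$t_p])
  rec_lo <- min(ev$time_s[ev$event_type == "LO" & ev$time_s > rec_td])
  nxt_td <- ev$time_s[ev$event_type == "TD" & ev$time_s > rec_lo]
  if (length(nxt_td) > 0) {
    tg <- (seq_len(nrow(tr$grf)) - 1) / tr$fs_grf
    inside <- tg > rec_lo + 0.01 & tg < min(nxt_td) - 0.01
    expect_true(all(tr$grf[inside, "vt"] > 0))
  }
  # annotations remain well-formed despite the dragging
  expect_true(all(diff(sort(ev$time_s)) >= 0.25 - 1e-9))
})

test_that("invalid requests are rejected", {
  cfg <- quiet_config()
  expect_error(simulate_trial(cfg, "hop"), "arg")
  expect_error(simulate_dataset(synthetic_config(n_subjects = 0)),
               "at least 1")
})
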