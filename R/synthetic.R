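#' Configuration for the synthetic perturbed-gait simulator
#'
#' Defines the study conditions the simulator emulates: 3-second windows,
#' force-plate data at 600 Hz and kinematics at 120 Hz, regular walking plus
#' slip and trip perturbations with variable recovery-step timing.
#'
#' @param n_subjects Number of simulated subjects.
#' @param trials_per_type Trials per subject for each of the three trial types
#'   (`regular`, `slip`, `trip`).
#' @param duration_s Trial duration in seconds (default 3).
#' @param fs_kin Kinematic sampling rate in Hz (default 120).
#' @param fs_grf Force-plate sampling rate in Hz (default 600); must be an
#'   integer multiple of `fs_kin`.
#' @param cadence_range Range of subject cadences in steps/min (default
#'   95-120); one cadence is drawn per subject.
#' @param stance_fraction Stance duration as a fraction of the gait cycle
#'   (stride) for regular walking (default 0.60).
#' @param step_length_range Range of subject step lengths in meters (default
#'   0.55-0.75); one value is drawn per subject.
#' @param noise_sd List with per-channel Gaussian noise SDs: `grf` in
#'   body-weight fractions (default 0.02) and `marker` in meters (default
#'   0.003).
#' @param slip_params List: `onset_phase` (fraction of the trial at which the
#'   slip-triggering contralateral touchdown occurs, default 0.35),
#'   `backward_slide_m` (slider travel, default 0.12), `recovery_delay_ms_range`
#'   (extra delay of the recovery step, default 80-250 ms), `abort_prob`
#'   (probability the recovery step is aborted with foot dragging, default
#'   0.15).
#' @param trip_params List: `onset_phase` (fraction of the perturbed swing at
#'   which the foot strikes the obstacle, default 0.4), `elevation_m` (extra
#'   foot elevation, default 0.10), `td_delay_ms_range` (touchdown delay,
#'   default 60-200 ms).
#' @param seed Integer seed for [simulate_dataset()].
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 30L, trials_per_type = 3L,
                             duration_s = 3, fs_kin = 120L, fs_grf = 600L,
                             cadence_range = c(95, 120),
                             stance_fraction = 0.60,
                             step_length_range = c(0.55, 0.75),
                             noise_sd = list(grf = 0.02, marker = 0.003),
                             slip_params = list(onset_phase = 0.35,
                                                backward_slide_m = 0.12,
                                                recovery_delay_ms_range = c(80, 250),
                                                abort_prob = 0.15),
                             trip_params = list(onset_phase = 0.4,
                                                elevation_m = 0.10,
                                                td_delay_ms_range = c(60, 200)),
                             seed = 1L) {
  fs_kin <- as.integer(fs_kin); fs_grf <- as.integer(fs_grf)
  if (abs(duration_s * fs_kin - round(duration_s * fs_kin)) > 1e-9)
    stop("duration_s * fs_kin must be an integer frame count")
  if (fs_grf %% fs_kin != 0L)
    stop("fs_grf must be an integer multiple of fs_kin")
  if (stance_fraction <= 0 || stance_fraction >= 1)
    stop("stance_fraction must lie in (0, 1)")
  if (slip_params$abort_prob < 0 || slip_params$abort_prob > 1)
    stop("abort_prob must lie in [0, 1]")
  if (slip_params$onset_phase < 0 || slip_params$onset_phase > 1 ||
      trip_params$onset_phase < 0 || trip_params$onset_phase > 1)
    stop("onset_phase fields must lie in [0, 1]")
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_type = as.integer(trials_per_type),
                 duration_s = duration_s, fs_kin = fs_kin, fs_grf = fs_grf,
                 cadence_range = cadence_range,
                 stance_fraction = stance_fraction,
                 step_length_range = step_length_range,
                 noise_sd = noise_sd, slip_params = slip_params,
                 trip_params = trip_params, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Smooth monotone step: s(0)=0, s(1)=1, zero velocity at both ends.
smooth_step <- function(u) u - sin(2 * pi * u) / (2 * pi)

marker_names <- function() {
  mk_axis <- as.vector(outer(c("heel", "toe", "ankle", "knee", "hip"),
                             c("ap", "vt"), paste, sep = "_"))
  as.vector(outer(c("l", "r"), mk_axis, paste, sep = "_"))
}

# Footfall schedule for one trial: left/right touchdown times (extending past
# the window so boundary stances are complete), stance duration, and the
# perturbation descriptor.
build_schedule <- function(config, trial_type, cadence) {
  t_str <- 2 * 60 / cadence
  stance <- config$stance_fraction * t_str
  dur <- config$duration_s
  phase0 <- runif(1, 0, t_str)
  k <- seq(-3L, ceiling((dur + 3 * t_str) / t_str))
  td_l <- phase0 + k * t_str
  td_r <- td_l + t_str / 2
  pert <- list(kind = "none")
  if (trial_type == "slip") {
    sp <- config$slip_params
    tp_idx <- which.min(abs(td_r - sp$onset_phase * dur))
    t_p <- td_r[tp_idx]
    delay <- runif(1, sp$recovery_delay_ms_range[1],
                   sp$recovery_delay_ms_range[2]) / 1000
    td_l[td_l > t_p] <- td_l[td_l > t_p] + delay
    td_r[td_r > t_p] <- td_r[td_r > t_p] + delay
    pert <- list(kind = "slip", t_p = t_p, delay = delay,
                 slide = sp$backward_slide_m, r_stance_idx = tp_idx,
                 rec_td_idx = which(td_l > t_p)[1L],
                 abort = runif(1) < sp$abort_prob)
  } else if (trial_type == "trip") {
    tp <- config$trip_params
    jt <- which.min(abs(td_l - 0.45 * dur))
    if (jt < 2L) jt <- 2L
    lo_prev <- td_l[jt - 1L] + stance
    t_c <- lo_prev + tp$onset_phase * (td_l[jt] - lo_prev)
    delay <- runif(1, tp$td_delay_ms_range[1], tp$td_delay_ms_range[2]) / 1000
    td_l[td_l >= td_l[jt]] <- td_l[td_l >= td_l[jt]] + delay
    td_r[td_r > t_c] <- td_r[td_r > t_c] + delay
    pert <- list(kind = "trip", t_c = t_c, delay = delay, jt = jt,
                 elev = tp$elevation_m)
  }
  list(t_str = t_str, stance = stance, td_l = td_l, td_r = td_r, pert = pert)
}

# Left-foot GRF channels (AP, VT, ML) in body-weight fractions at fs_grf.
# The vertical profile is a double-bump stance shape with a powered-sine
# envelope, so loading onset/offset is crisp enough that a 5%-BW threshold
# crossing pins the stored events to within one 600 Hz frame.
build_grf <- function(config, sched) {
  n <- round(config$duration_s * config$fs_grf)
  tg <- (seq_len(n) - 1L) / config$fs_grf
  vt <- ap <- ml <- numeric(n)
  td <- sched$td_l
  lo <- td + sched$stance
  pert <- sched$pert
  for (j in seq_along(td)) {
    if (lo[j] < 0 || td[j] > config$duration_s) next
    idx <- which(tg >= td[j] & tg <= lo[j])
    if (length(idx) == 0L) next
    phi <- (tg[idx] - td[j]) / sched$stance
    load <- 1
    if (pert$kind == "slip" && j == pert$rec_td_idx) load <- 1.25
    if (pert$kind == "trip" && j == pert$jt) load <- 1.3
    env <- sin(pi * phi)^0.25
    vt[idx] <- vt[idx] + load * 0.95 * env * (1 + 0.15 * cos(4 * pi * (phi - 0.25)))
    ap[idx] <- ap[idx] - load * 0.18 * sin(2 * pi * phi) * sin(pi * phi)
    ml[idx] <- ml[idx] + 0.05 * sin(pi * phi)
    if (pert$kind == "slip" && j == pert$rec_td_idx) {
      early <- phi < 0.3
      ap[idx[early]] <- ap[idx[early]] - 0.10 * sin(pi * phi[early] / 0.3)
    }
  }
  if (pert$kind == "slip" && isTRUE(pert$abort)) {
    # aborted recovery: the foot drags after the nominal liftoff, so VT never
    # fully unloads during that swing
    j <- pert$rec_td_idx
    idx <- which(tg > lo[j] & tg < td[j + 1L])
    if (length(idx) > 0L) {
      u <- (tg[idx] - lo[j]) / (td[j + 1L] - lo[j])
      vt[idx] <- vt[idx] + 0.04 + 0.03 * sin(pi * u)
    }
  }
  cbind(ap = ap, vt = vt, ml = ml)
}

# Foot (heel) trajectory for one side: AP position and VT height at times tk.
foot_trajectory <- function(tk, td, stance, speed, pert, side) {
  land_x <- speed * td + 0.12
  end_x <- land_x
  sliding <- pert$kind == "slip" && side == "r"
  if (sliding) end_x[pert$r_stance_idx] <- land_x[pert$r_stance_idx] - pert$slide
  j <- findInterval(tk, td)
  j[j < 1L] <- 1L
  in_stance <- tk <= td[j] + stance & tk >= td[j]
  ap <- numeric(length(tk))
  vt <- numeric(length(tk))
  # stance: planted at the landing position (slid backward during a slip)
  si <- which(in_stance)
  ap[si] <- land_x[j[si]]
  if (sliding) {
    t0 <- pert$t_p + 0.05  # slider releases shortly after contralateral TD
    k <- si[j[si] == pert$r_stance_idx & tk[si] >= t0]
    if (length(k) > 0L) {
      u <- pmin((tk[k] - t0) / 0.3, 1)
      ap[k] <- land_x[pert$r_stance_idx] - pert$slide * smooth_step(u)
    }
  }
  # swing: smooth progression to the next landing, sine height profile
  wi <- which(!in_stance)
  lo <- td[j[wi]] + stance
  nxt <- pmin(j[wi] + 1L, length(td))
  u <- (tk[wi] - lo) / (td[nxt] - lo)
  u[!is.finite(u)] <- 0
  u <- pmin(pmax(u, 0), 1)
  ap[wi] <- end_x[j[wi]] + (land_x[nxt] - end_x[j[wi]]) * smooth_step(u)
  vt[wi] <- 0.07 * sin(pi * u)
  if (pert$kind == "trip" && side == "l") {
    # obstacle contact elevates the remainder of the perturbed swing
    k <- wi[j[wi] == pert$jt - 1L & tk[wi] >= pert$t_c]
    if (length(k) > 0L) {
      u2 <- (tk[k] - pert$t_c) / (td[pert$jt] - pert$t_c)
      vt[k] <- vt[k] + pert$elev * sin(pi * pmin(pmax(u2, 0), 1))
    }
  }
  list(ap = ap, vt = vt, swing_u = ifelse(in_stance, 0, NA))
}

build_markers <- function(config, sched, step_length) {
  n <- round(config$duration_s * config$fs_kin)
  tk <- (seq_len(n) - 1L) / config$fs_kin
  speed <- step_length / (sched$t_str / 2)
  out <- matrix(0, n, 20L, dimnames = list(NULL, marker_names()))
  for (side in c("l", "r")) {
    td <- if (side == "l") sched$td_l else sched$td_r
    ft <- foot_trajectory(tk, td, sched$stance, speed, sched$pert, side)
    heel_ap <- ft$ap; heel_vt <- ft$vt
    hip_ap <- speed * tk + 0.02 * sin(4 * pi * tk / sched$t_str)
    hip_vt <- 0.92 + 0.015 * cos(4 * pi * (tk - td[1L]) / sched$t_str)
    out[, paste0(side, "_heel_ap")] <- heel_ap
    out[, paste0(side, "_heel_vt")] <- heel_vt
    out[, paste0(side, "_toe_ap")] <- heel_ap + 0.22
    out[, paste0(side, "_toe_vt")] <- heel_vt * 0.85
    out[, paste0(side, "_ankle_ap")] <- heel_ap + 0.04
    out[, paste0(side, "_ankle_vt")] <- heel_vt + 0.09
    out[, paste0(side, "_knee_ap")] <- 0.5 * (heel_ap + 0.04 + hip_ap)
    out[, paste0(side, "_knee_vt")] <- 0.50 + 0.7 * heel_vt
    out[, paste0(side, "_hip_ap")] <- hip_ap
    out[, paste0(side, "_hip_vt")] <- hip_vt
  }
  out
}

schedule_events <- function(config, sched) {
  n_kin <- round(config$duration_s * config$fs_kin)
  one_side <- function(td, side) {
    lo <- td + sched$stance
    ev <- rbind(data.frame(event_type = "TD", side = side, time_s = td),
                data.frame(event_type = "LO", side = side, time_s = lo))
    ev
  }
  ev <- rbind(one_side(sched$td_l, "left"), one_side(sched$td_r, "right"))
  # reject schedules that violate the physiological minimum event spacing
  for (s in c("left", "right")) {
    tt <- sort(ev$time_s[ev$side == s])
    if (any(diff(tt) < 0.25 - 1e-9))
      stop("perturbation parameters force same-side events closer than 250 ms")
  }
  ev$frame <- round(ev$time_s * config$fs_kin)
  ev <- ev[ev$time_s >= 0 & ev$time_s < config$duration_s &
             ev$frame >= 0L & ev$frame <= n_kin - 1L, ]
  ev <- ev[order(ev$time_s), ]
  rownames(ev) <- NULL
  ev
}

#' Simulate a single gait trial with exactly known events
#'
#' Generates one trial of regular, slip- or trip-perturbed walking: left-foot
#' ground reaction forces (AP/VT/ML, body-weight fractions, 600 Hz), ten
#' marker trajectories (heel, toe, ankle, knee, hip for both limbs; AP and VT
#' axes, meters, 120 Hz) and the ground-truth touchdown/liftoff annotations
#' the signals were built from. Slip trials displace the contralateral stance
#' foot backward and delay the recovery step (optionally aborting it into
#' foot dragging); trip trials truncate a swing with an elevated foot path and
#' a delayed touchdown. Additive Gaussian noise is applied last.
#'
#' @param config A [synthetic_config()].
#' @param trial_type One of `"regular"`, `"slip"`, `"trip"`.
#' @param subject Optional list with fields `subject_id`, `cadence`
#'   (steps/min) and `step_length` (m); drawn from `config` ranges if `NULL`.
#' @param trial_id Identifier stored with the trial.
#' @param seed Optional integer; if given, the trial is generated from a
#'   private RNG state so the call is fully deterministic and leaves the
#'   global RNG untouched.
#' @return A list of class `trial_recording` with elements `trial_id`,
#'   `subject_id`, `trial_type`, `grf` (matrix n x 3), `markers` (matrix
#'   n x 20), `events` (data.frame: `event_type`, `side`, `time_s`, `frame`),
#'   sampling metadata and the subject parameters used.
#' @examples
#' cfg <- synthetic_config(noise_sd = list(grf = 0, marker = 0))
#' tr <- simulate_trial(cfg, "regular", seed = 42)
#' subset(tr$events, side == "left")
#' @export
simulate_trial <- function(config, trial_type = c("regular", "slip", "trip"),
                           subject = NULL, trial_id = "trial", seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  trial_type <- match.arg(trial_type)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  if (is.null(subject))
    subject <- list(subject_id = "s01",
                    cadence = runif(1, config$cadence_range[1], config$cadence_range[2]),
                    step_length = runif(1, config$step_length_range[1],
                                        config$step_length_range[2]))
  sched <- build_schedule(config, trial_type, subject$cadence)
  grf <- build_grf(config, sched)
  markers <- build_markers(config, sched, subject$step_length)
  events <- schedule_events(config, sched)
  if (config$noise_sd$grf > 0) {
    grf <- grf + matrix(rnorm(length(grf), 0, config$noise_sd$grf), nrow(grf))
    grf[, "vt"] <- pmax(grf[, "vt"], 0)
  }
  if (config$noise_sd$marker > 0)
    markers <- markers + matrix(rnorm(length(markers), 0, config$noise_sd$marker),
                                nrow(markers))
  structure(list(trial_id = trial_id, subject_id = subject$subject_id,
                 trial_type = trial_type, grf = grf, markers = markers,
                 events = events, fs_grf = config$fs_grf,
                 fs_kin = config$fs_kin, duration_s = config$duration_s,
                 subject = subject, perturbation = sched$pert),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording %s> subject %s, type %s, %.1f s\n",
              x$trial_id, x$subject_id, x$trial_type, x$duration_s))
  cat(sprintf("  grf: %d x %d @ %d Hz | markers: %d x %d @ %d Hz | %d events\n",
              nrow(x$grf), ncol(x$grf), x$fs_grf, nrow(x$markers),
              ncol(x$markers), x$fs_kin, nrow(x$events)))
  invisible(x)
}

#' Simulate a full dataset of regular, slip and trip trials
#'
#' Subject-level gait parameters (cadence, step length) are drawn once per
#' subject so trials within a subject are correlated; each subject contributes
#' `trials_per_type` trials of each of the three trial types. Fully
#' deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list of [simulate_trial()] results, with the configuration
#'   attached as attribute `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_subjects < 1L || config$trials_per_type < 1L)
    stop("n_subjects and trials_per_type must both be at least 1")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  trials <- list()
  for (s in seq_len(config$n_subjects)) {
    subject <- list(subject_id = sprintf("s%03d", s),
                    cadence = runif(1, config$cadence_range[1], config$cadence_range[2]),
                    step_length = runif(1, config$step_length_range[1],
                                        config$step_length_range[2]))
    for (type in c("regular", "slip", "trip")) {
      for (r in seq_len(config$trials_per_type)) {
        id <- sprintf("%s_%s_%02d", subject$subject_id, type, r)
        trials[[id]] <- simulate_trial(config, type, subject = subject,
                                       trial_id = id)
      }
    }
  }
  attr(trials, "config") <- config
  trials
}
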