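# Synthetic multi-sensor IMU sessions with exact ground truth.
#
# Emulates intermittent straight walks separated by ~180 degree turns:
# each turn follows a minimum-jerk yaw S-curve (zero angular velocity and
# acceleration at the endpoints, so turn boundaries are kinematically
# sharp), upper-body segments can lead/lag each other (sequential
# head-first turning vs en-bloc turning), and ankle yaw is step-quantized
# into discrete swings. Gyro signals carry constant per-axis bias and
# Gaussian noise; accelerometer carries gravity plus a double-cadence
# vertical gait oscillation; magnetometer is a constant field rotated by
# the local yaw.

# Minimum-jerk unit step and its derivative
mj_s <- function(tau) {
  tau <- pmin(1, pmax(0, tau))
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}
mj_ds <- function(tau) {
  out <- numeric(length(tau))
  inside <- tau > 0 & tau < 1
  ti <- tau[inside]
  out[inside] <- 30 * ti^2 - 60 * ti^3 + 30 * ti^4
  out
}

#' Synthetic-session configuration
#'
#' Presets mirror the two turning phenotypes the toolkit targets:
#' `"control"` turns are faster (2.5 +/- 0.7 s), sequential (head leads
#' the trunk by 0.15 s per segment) and use about 3 steps; `"pd"` turns
#' are slower (3.5 +/- 1.0 s), en bloc (no segment lag), and use about 5
#' steps at a slightly slower cadence.
#'
#' @param preset `"control"` or `"pd"`
#' @param n_turns number of turns (default 3, i.e. four intermittent
#'   straight walks)
#' @param turn_angle_mean,turn_angle_sd turn magnitude draw, deg
#'   (default 180 +/- 10)
#' @param turn_dur_mean,turn_dur_sd turn duration draw, s
#' @param segment_lag_s head -> neck -> lower-back onset lag, s
#' @param steps_per_turn mean steps per turn
#' @param step_hz gait cadence, Hz
#' @param gait_acc_amp_g amplitude of the double-cadence vertical
#'   acceleration oscillation during movement (walking and turning), g;
#'   the PD-like preset reduces it, emulating diminished movement
#'   amplitude
#' @param gyro_bias_dps per-axis constant gyro bias; `NULL` draws each
#'   axis and location from U(-1, 1) deg/s
#' @param noise_gyr_dps,noise_acc_g,noise_mag_gauss Gaussian noise SDs
#' @param fs sample rate, Hz
#' @param walk_s straight-walk bout length, s
#' @param still_s still (standing) period at the session start/end, s
#' @param seed RNG seed; every random draw flows from it
#' @param ... overrides of any field above
#' @return a `synth_config` list
#' @export
synth_config <- function(preset = c("control", "pd"), n_turns = 3,
                         turn_angle_mean = 180, turn_angle_sd = 10,
                         turn_dur_mean = NULL, turn_dur_sd = NULL,
                         segment_lag_s = NULL, steps_per_turn = NULL,
                         step_hz = NULL, gait_acc_amp_g = NULL,
                         gyro_bias_dps = NULL,
                         noise_gyr_dps = 1.0, noise_acc_g = 0.02,
                         noise_mag_gauss = 0.005, fs = 128,
                         walk_s = 8, still_s = 3, seed = 1, ...) {
  preset <- match.arg(preset)
  defaults <- if (preset == "control") {
    list(turn_dur_mean = 2.5, turn_dur_sd = 0.7, segment_lag_s = 0.15,
         steps_per_turn = 3, step_hz = 1.8, gait_acc_amp_g = 0.08)
  } else {
    # slower, en-bloc, more-stepped turns with reduced movement amplitude
    list(turn_dur_mean = 3.5, turn_dur_sd = 1.0, segment_lag_s = 0,
         steps_per_turn = 5, step_hz = 1.6, gait_acc_amp_g = 0.05)
  }
  cfg <- list(
    preset = preset, n_turns = n_turns,
    turn_angle_mean = turn_angle_mean, turn_angle_sd = turn_angle_sd,
    turn_dur_mean = turn_dur_mean %||% defaults$turn_dur_mean,
    turn_dur_sd = turn_dur_sd %||% defaults$turn_dur_sd,
    segment_lag_s = segment_lag_s %||% defaults$segment_lag_s,
    steps_per_turn = steps_per_turn %||% defaults$steps_per_turn,
    step_hz = step_hz %||% defaults$step_hz,
    gait_acc_amp_g = gait_acc_amp_g %||% defaults$gait_acc_amp_g,
    gyro_bias_dps = gyro_bias_dps,
    noise_gyr_dps = noise_gyr_dps, noise_acc_g = noise_acc_g,
    noise_mag_gauss = noise_mag_gauss,
    fs = fs, walk_s = walk_s, still_s = still_s, seed = seed
  )
  cfg <- modifyList(cfg, list(...))
  structure(cfg, class = "synth_config")
}

#' A zero-noise, zero-bias, en-bloc variant of a configuration
#'
#' Convenience for noiseless pipeline-identity checks.
#'
#' @param cfg a [synth_config()]
#' @return the configuration with all noise and bias terms set to zero
#' @export
noiseless <- function(cfg) {
  modifyList(cfg, list(noise_gyr_dps = 0, noise_acc_g = 0,
                       noise_mag_gauss = 0, gyro_bias_dps = c(0, 0, 0)))
}

#' Simulate one five-sensor IMU session with ground truth
#'
#' @param cfg a [synth_config()]
#' @param seed overrides `cfg$seed`
#' @param subject_id subject identifier (default `"synth"`)
#' @param group_label optional `"PD"`/`"CL"` label attached to the session
#' @return list with elements `session` (an [imu_session()]) and `truth`
#'   (list: `turns` tibble per location, `steps` tibble, `yaw` named list
#'   of `t`/`psi` tibbles)
#' @export
simulate_session <- function(cfg, seed = NULL, subject_id = "synth",
                             group_label = NULL) {
  seed <- seed %||% cfg$seed
  withr::with_seed(seed, simulate_session_impl(cfg, subject_id, group_label))
}

simulate_session_impl <- function(cfg, subject_id, group_label) {
  fs <- cfg$fs; dt <- 1 / fs
  n_turns <- cfg$n_turns
  durs <- pmin(9.5, pmax(0.8, rnorm(n_turns, cfg$turn_dur_mean, cfg$turn_dur_sd)))
  if (any(durs * fs < 8)) stopf("infeasible config: < 8 samples per turn")
  mags <- pmax(90, rnorm(n_turns, cfg$turn_angle_mean, cfg$turn_angle_sd))
  dirs <- rep(c(1, -1), length.out = n_turns) *
    (if (runif(1) < 0.5) 1 else -1)
  angles <- mags * dirs
  lag <- cfg$segment_lag_s
  # steps per turn; each swing must stay detectable (>= ~36 deg)
  k_steps <- pmin(floor(mags / 36),
                  pmax(2, round(rnorm(n_turns, cfg$steps_per_turn, 0.5))))
  k_steps <- pmax(2, k_steps)

  # timeline: still | walk | turn | walk | turn | ... | walk | still
  base <- numeric(n_turns)
  cursor <- cfg$still_s
  walk_bouts <- list()
  for (i in seq_len(n_turns)) {
    walk_bouts[[length(walk_bouts) + 1]] <- c(cursor, cursor + cfg$walk_s)
    cursor <- cursor + cfg$walk_s
    base[i] <- cursor
    cursor <- cursor + durs[i] + 2 * lag
  }
  walk_bouts[[length(walk_bouts) + 1]] <- c(cursor, cursor + cfg$walk_s)
  total <- cursor + cfg$walk_s + cfg$still_s
  t <- seq(0, total, by = dt)
  n <- length(t)
  walking <- rep(FALSE, n)
  for (b in walk_bouts) walking[t >= b[1] & t < b[2]] <- TRUE

  onset <- list(HD = 0, C7 = lag, L5 = 2 * lag)
  psi_upper <- lapply(onset, function(lg) {
    psi <- numeric(n); omega <- numeric(n)
    for (i in seq_len(n_turns)) {
      tau <- (t - (base[i] + lg)) / durs[i]
      psi <- psi + angles[i] * mj_s(tau)
      omega <- omega + angles[i] / durs[i] * mj_ds(tau)
    }
    list(psi = psi, omega = omega)
  })

  # ankle swings: k slots per turn over the L5 window; outer foot offset
  # by half a slot
  l5_start <- base + 2 * lag
  swing_tbl <- list()
  psi_ankle <- list(LA = numeric(n), RA = numeric(n))
  omega_ankle <- list(LA = numeric(n), RA = numeric(n))
  for (i in seq_len(n_turns)) {
    roles <- assign_inner_outer(if (angles[i] < 0) "left" else "right")
    slot <- durs[i] / k_steps[i]
    inc <- angles[i] / k_steps[i]
    for (role in c("inner", "outer")) {
      loc <- roles[[role]]
      off <- if (role == "inner") 0 else 0.5 * slot
      for (j in seq_len(k_steps[i])) {
        s0 <- l5_start[i] + (j - 1) * slot + off
        sd_ <- 0.55 * slot
        tau <- (t - s0) / sd_
        psi_ankle[[loc]] <- psi_ankle[[loc]] + inc * mj_s(tau)
        omega_ankle[[loc]] <- omega_ankle[[loc]] + inc / sd_ * mj_ds(tau)
        swing_tbl[[length(swing_tbl) + 1]] <-
          tibble(l5_turn = i, ankle_role = role, location = loc,
                 start_s = s0, end_s = s0 + sd_, angle_deg = inc)
      }
    }
  }

  bias_for <- function() {
    if (!is.null(cfg$gyro_bias_dps)) rep(cfg$gyro_bias_dps, length.out = 3)
    else runif(3, -1, 1)
  }
  # movement (stepping) continues through turns; amplitude is a group trait
  moving <- walking
  for (i in seq_len(n_turns))
    moving[t >= base[i] & t < base[i] + durs[i] + 2 * lag] <- TRUE
  cadence <- cfg$step_hz
  amp <- cfg$gait_acc_amp_g
  gait_vt <- amp * sin(2 * pi * 2 * cadence * t) * moving
  gait_ap <- 0.4 * amp * sin(2 * pi * cadence * t) * moving
  gait_ml <- 0.4 * amp * cos(2 * pi * cadence * t) * moving
  H <- 0.2; V <- 0.4

  make_rec <- function(loc, psi, omega) {
    b <- bias_for()
    gn <- function() rnorm(n, 0, cfg$noise_gyr_dps)
    an <- function() rnorm(n, 0, cfg$noise_acc_g)
    mn <- function() rnorm(n, 0, cfg$noise_mag_gauss)
    osc_g <- (if (loc %in% .ANKLES) 25 else 8) * amp / 0.08  # deg/s wobble
    gyr <- cbind(
      omega + b[1] + gn(),
      osc_g * sin(2 * pi * cadence * t) * moving + b[2] + gn(),
      osc_g * cos(2 * pi * cadence * t) * moving + b[3] + gn()
    )
    acc <- cbind(1 + gait_vt + an(), gait_ap + an(), gait_ml + an())
    pr <- psi * pi / 180
    mag <- cbind(V + mn(), H * cos(pr) + mn(), -H * sin(pr) + mn())
    imu_recording(t, acc, gyr, mag, location = loc, fs = fs)
  }

  recs <- list()
  yaw_truth <- list()
  for (loc in .UPPER_BODY) {
    pu <- psi_upper[[loc]]
    recs[[loc]] <- make_rec(loc, pu$psi, pu$omega)
    yaw_truth[[loc]] <- tibble(t = t, psi = pu$psi)
  }
  for (loc in .ANKLES) {
    recs[[loc]] <- make_rec(loc, psi_ankle[[loc]], omega_ankle[[loc]])
    yaw_truth[[loc]] <- tibble(t = t, psi = psi_ankle[[loc]])
  }

  turns_truth <- bind_rows(lapply(names(onset), function(loc) {
    tibble(location = loc,
           start_s = base + onset[[loc]], end_s = base + onset[[loc]] + durs,
           angle_deg = angles,
           direction = ifelse(angles < 0, "left", "right"))
  }))
  ankle_truth <- bind_rows(swing_tbl) |>
    group_by(.data$l5_turn, .data$ankle_role, .data$location) |>
    summarise(start_s = min(.data$start_s), end_s = max(.data$end_s),
              angle_deg = sum(.data$angle_deg), .groups = "drop") |>
    mutate(direction = ifelse(.data$angle_deg < 0, "left", "right"))
  turns_truth <- bind_rows(
    turns_truth,
    ankle_truth |> select("location", "start_s", "end_s", "angle_deg",
                          "direction")
  )

  list(
    session = imu_session(recs, subject_id = subject_id,
                          group_label = group_label),
    truth = list(turns = turns_truth, steps = bind_rows(swing_tbl),
                 yaw = yaw_truth,
                 angles = angles, durations = durs, k_steps = k_steps,
                 l5_start = l5_start, l5_end = l5_start + durs)
  )
}

#' Simulate a labelled two-group cohort
#'
#' Subject-level heterogeneity is added on top of the group presets
#' (turn-duration mean jittered by N(0, 0.25 s), cadence by N(0, 0.1 Hz));
#' all randomness derives from `seed`.
#'
#' @param n_pd,n_cl subjects per group (>= 2 each)
#' @param seed master seed
#' @param pd_preset,cl_preset [synth_config()]s for the two groups
#' @return list: `sessions` (named list of [imu_session()]), `truths`,
#'   `labels` tibble (`subject_id`, `group_label`)
#' @export
simulate_cohort <- function(n_pd, n_cl, seed = 1,
                            pd_preset = synth_config("pd"),
                            cl_preset = synth_config("control")) {
  stopifnot(n_pd >= 2, n_cl >= 2)
  n <- n_pd + n_cl
  plan <- withr::with_seed(seed, tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    group_label = c(rep("PD", n_pd), rep("CL", n_cl)),
    sub_seed = sample.int(.Machine$integer.max - 1, n),
    dur_jit = rnorm(n, 0, 0.25),
    cad_jit = rnorm(n, 0, 0.1)
  ))
  sessions <- list(); truths <- list()
  for (i in seq_len(n)) {
    cfg <- if (plan$group_label[i] == "PD") pd_preset else cl_preset
    cfg <- modifyList(cfg, list(
      turn_dur_mean = max(1, cfg$turn_dur_mean + plan$dur_jit[i]),
      step_hz = max(1, cfg$step_hz + plan$cad_jit[i])
    ))
    res <- simulate_session(cfg, seed = plan$sub_seed[i],
                            subject_id = plan$subject_id[i],
                            group_label = plan$group_label[i])
    sessions[[plan$subject_id[i]]] <- res$session
    truths[[plan$subject_id[i]]] <- res$truth
  }
  list(sessions = sessions, truths = truths,
       labels = select(plan, "subject_id", "group_label"))
}
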