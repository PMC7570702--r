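# Yaw estimation.
#
# Upper-body locations (HD, C7, L5): constant gyroscope bias is estimated
# from the stillest window of the trace and subtracted, then yaw is the
# cumulative trapezoidal integral of the vertical angular velocity.
# Ankles (LA, RA): a two-state Kalman filter fuses gyro-propagated yaw with
# the tilt-compensated magnetometer heading (accelerometer supplies the
# tilt estimate), which bounds integration drift.
#
# Sign convention: counter-clockwise rotation about the anatomical vertical
# axis, viewed from above, is positive; left turns therefore carry negative
# yaw displacement.

new_yaw_trace <- function(t, psi, omega_vt, location, fs) {
  tr <- tibble(t = t, psi = psi, omega_vt = omega_vt)
  structure(tr, location = location, fs = fs,
            class = c("yaw_trace", class(tr)))
}

#' Estimate and remove static gyroscope bias
#'
#' Per-axis constant bias is estimated as the mean gyro signal over the
#' window of length `static_window_s` with the lowest moving variance of
#' the gyro magnitude (the "stillest" part of the trace, e.g. standing
#' before a walk) and subtracted from all three axes. Optionally a
#' zero-phase high-pass is applied to the vertical axis to remove residual
#' slow drift before integration.
#'
#' @param rec an [imu_recording()] (intended for HD/C7/L5)
#' @param static_window_s still-window length in seconds (default 2)
#' @param still_var_max largest gyro-magnitude variance (deg^2/s^2)
#'   accepted as "still"; above it the whole-trace median is used as bias,
#'   with a warning (default 25, i.e. SD 5 deg/s)
#' @param highpass_enabled apply a zero-phase high-pass to the corrected
#'   vertical axis (default `FALSE`)
#' @param highpass_cutoff_hz high-pass cutoff in Hz (default 0.02)
#' @return the recording with bias-corrected gyro columns; the estimated
#'   per-axis bias (deg/s, VT/AP/ML order) is stored in attribute
#'   `gyro_bias`.
#' @export
compensate_gyro <- function(rec, static_window_s = 2,
                            still_var_max = 25,
                            highpass_enabled = FALSE,
                            highpass_cutoff_hz = 0.02) {
  fs <- rec_fs(rec)
  w <- max(2L, round(static_window_s * fs))
  if (nrow(rec) < w)
    stopf("recording shorter than static_window_s = %g s", static_window_s)
  gmag <- sqrt(rec$gyr_vt^2 + rec$gyr_ap^2 + rec$gyr_ml^2)
  mv <- moving_var(gmag, w)
  i0 <- which.min(mv)
  if (mv[i0] <= still_var_max) {
    idx <- i0:(i0 + w - 1)
    bias <- c(mean(rec$gyr_vt[idx]), mean(rec$gyr_ap[idx]), mean(rec$gyr_ml[idx]))
  } else {
    warnf("no still window found (min variance %.1f > %.1f deg^2/s^2); using whole-trace median bias",
          mv[i0], still_var_max)
    bias <- c(median(rec$gyr_vt), median(rec$gyr_ap), median(rec$gyr_ml))
  }
  rec$gyr_vt <- rec$gyr_vt - bias[1]
  rec$gyr_ap <- rec$gyr_ap - bias[2]
  rec$gyr_ml <- rec$gyr_ml - bias[3]
  if (highpass_enabled) {
    wn <- highpass_cutoff_hz / (fs / 2)
    bf <- signal::butter(2, wn, type = "high")
    rec$gyr_vt <- as.numeric(signal::filtfilt(bf, rec$gyr_vt))
  }
  attr(rec, "gyro_bias") <- bias
  rec
}

#' Integrate vertical angular velocity to yaw
#'
#' Cumulative trapezoidal integration of bias-corrected vertical angular
#' velocity; `psi[1] = 0` by convention.
#'
#' @param x an [imu_recording()] (its `gyr_vt` channel is integrated) or a
#'   numeric deg/s series
#' @param fs sample rate in Hz, required when `x` is a bare numeric vector
#'   and `t` is not given
#' @param t optional time vector in seconds
#' @return a `yaw_trace` tibble with columns `t`, `psi` (deg), `omega_vt`
#'   (deg/s)
#' @export
integrate_yaw <- function(x, fs = NULL, t = NULL) {
  if (inherits(x, "imu_recording")) {
    omega <- x$gyr_vt; t <- x$t; fs <- rec_fs(x); loc <- rec_location(x)
  } else {
    omega <- as.numeric(x)
    if (is.null(t)) {
      if (is.null(fs)) stopf("supply fs or t with a numeric series")
      t <- (seq_along(omega) - 1) / fs
    }
    if (is.null(fs)) fs <- 1 / median(diff(t))
    loc <- NA_character_
  }
  if (anyNA(omega)) stopf("NaN/NA samples in angular velocity")
  psi <- as.numeric(pracma::cumtrapz(t, omega))
  new_yaw_trace(t, psi, omega, loc, fs)
}

# Roll/pitch from (quasi-static) accelerometer, radians.
# Convention: x = AP, y = ML, z = VT; level accelerometer reads (0, 0, +1) g.
acc_tilt <- function(acc_vt, acc_ap, acc_ml) {
  nrm <- sqrt(acc_vt^2 + acc_ap^2 + acc_ml^2)
  nrm[nrm == 0] <- 1
  pitch <- asin(pmin(1, pmax(-1, -acc_ap / nrm)))
  roll <- atan2(acc_ml, acc_vt)
  list(roll = roll, pitch = pitch)
}

# Tilt-compensated magnetic heading in degrees, same sign convention as yaw.
mag_heading <- function(rec, roll, pitch) {
  cr <- cos(roll); sr <- sin(roll); cp <- cos(pitch); sp <- sin(pitch)
  # de-rotate roll then pitch: m_h = Ry(pitch) %*% Rx(roll) %*% m_body
  mx <- rec$mag_ap; my <- rec$mag_ml; mz <- rec$mag_vt
  my1 <- cr * my - sr * mz
  mz1 <- sr * my + cr * mz
  mx2 <- cp * mx + sp * mz1
  atan2(-my1, mx2) * 180 / pi
}

#' Ankle yaw by 9-DOF sensor fusion
#'
#' Fuses the three IMU modalities into a yaw estimate: the gyroscope
#' propagates yaw, the accelerometer supplies roll/pitch for tilt
#' compensation, and the tilt-compensated magnetometer heading corrects the
#' propagated yaw through a two-state (yaw + gyro bias) Kalman filter. The
#' output is unwrapped (no +/-180 deg jumps) and re-zeroed at the trace
#' start. Without a magnetometer the filter degrades to bias-compensated
#' integration (6-DOF), with a warning.
#'
#' @param rec an [imu_recording()] (intended for LA/RA)
#' @param heading_noise_deg measurement SD assigned to the magnetic heading
#'   (default 2)
#' @param gyro_noise_dps process SD of the gyro-propagated yaw rate
#'   (default 0.5)
#' @param bias_walk_dps process SD of the gyro bias random walk
#'   (default 0.01)
#' @return a `yaw_trace` tibble; `omega_vt` is the bias-corrected vertical
#'   angular velocity using the filter's time-varying bias estimate.
#' @export
fuse_orientation_9dof <- function(rec, heading_noise_deg = 2,
                                  gyro_noise_dps = 0.5,
                                  bias_walk_dps = 0.01) {
  fs <- rec_fs(rec)
  if (!has_mag(rec)) {
    warnf("magnetometer absent at %s; degrading to 6-DOF (bias-compensated integration)",
          rec_location(rec))
    comp <- compensate_gyro(rec)
    tr <- integrate_yaw(comp)
    attr(tr, "location") <- rec_location(rec)
    return(tr)
  }
  n <- nrow(rec)
  # smooth the accelerometer before tilt extraction: gait impacts are far
  # above the orientation band
  a_vt <- lowpass_zero_phase(rec$acc_vt, fs, 2)
  a_ap <- lowpass_zero_phase(rec$acc_ap, fs, 2)
  a_ml <- lowpass_zero_phase(rec$acc_ml, fs, 2)
  tilt <- acc_tilt(a_vt, a_ap, a_ml)
  z <- mag_heading(rec, tilt$roll, tilt$pitch)

  psi <- numeric(n); bias <- numeric(n)
  x <- c(z[1], 0)                     # state: yaw (deg), gyro bias (deg/s)
  P <- diag(c(25, 1))
  R <- heading_noise_deg^2
  for (i in 2:n) {
    dt <- rec$t[i] - rec$t[i - 1]
    # predict
    x[1] <- x[1] + (rec$gyr_vt[i] - x[2]) * dt
    Fm <- matrix(c(1, -dt, 0, 1), 2, 2, byrow = TRUE)
    Q <- diag(c((gyro_noise_dps * dt)^2, (bias_walk_dps * dt)^2))
    P <- Fm %*% P %*% t(Fm) + Q
    # update with wrapped heading innovation
    innov <- wrap_deg(z[i] - x[1])
    S <- P[1, 1] + R
    K <- P[, 1] / S
    x <- x + K * innov
    P <- P - K %*% P[1, , drop = FALSE]
    psi[i] <- x[1]; bias[i] <- x[2]
  }
  psi[1] <- z[1]; bias[1] <- bias[2]
  new_yaw_trace(rec$t, psi - psi[1], rec$gyr_vt - bias,
                rec_location(rec), fs)
}

#' Estimate yaw for a recording, routed by location
#'
#' HD/C7/L5 use [compensate_gyro()] + [integrate_yaw()]; LA/RA use
#' [fuse_orientation_9dof()].
#'
#' @param rec an [imu_recording()]
#' @param static_window_s still-window length for bias estimation (s)
#' @param ... passed to the location-specific estimator
#' @return a `yaw_trace`
#' @export
estimate_yaw <- function(rec, static_window_s = 2, ...) {
  loc <- rec_location(rec)
  if (loc %in% .UPPER_BODY) {
    integrate_yaw(compensate_gyro(rec, static_window_s = static_window_s, ...))
  } else {
    fuse_orientation_9dof(rec, ...)
  }
}

#' @export
print.yaw_trace <- function(x, ...) {
  cat(sprintf("<yaw_trace> %s, %d samples, net yaw %.1f deg\n",
              attr(x, "location") %||% "?", nrow(x), x$psi[nrow(x)]))
  NextMethod()
}

#' Plot a yaw trace with optional detected turns
#'
#' @param object a `yaw_trace`
#' @param turns optional `turn_events` tibble; detected windows are shaded
#' @param ... unused
#' @return a ggplot object
#' @method autoplot yaw_trace
#' @export
autoplot.yaw_trace <- function(object, turns = NULL, ...) {
  p <- ggplot(as_tibble(object), aes(x = .data$t, y = .data$psi)) +
    geom_line(linewidth = 0.4) +
    labs(x = "time (s)", y = "yaw (deg)",
         title = sprintf("Yaw, %s", attr(object, "location") %||% "")) +
    theme_minimal()
  if (!is.null(turns) && nrow(turns)) {
    p <- p + geom_rect(
      data = as_tibble(turns),
      aes(xmin = .data$start_s, xmax = .data$end_s,
          ymin = -Inf, ymax = Inf, fill = .data$direction),
      alpha = 0.2, inherit.aes = FALSE
    )
  }
  p
}
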