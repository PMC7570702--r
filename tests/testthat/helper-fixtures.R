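# Shared fixtures: tiny hand-built recordings and yaw traces.

fixture_fs <- 128

# Recording with prescribed channel matrices (defaults: still, level)
make_recording <- function(duration_s = 10, location = "L5", fs = fixture_fs,
                           gyr = NULL, acc = NULL, mag = NULL) {
  t <- seq(0, duration_s, by = 1 / fs)
  n <- length(t)
  if (is.null(gyr)) gyr <- matrix(0, n, 3)
  if (is.null(acc)) acc <- cbind(rep(1, n), 0, 0)
  imu_recording(t, acc, gyr, mag, location = location, fs = fs)
}

# Yaw trace directly from an angular-velocity vector (deg/s)
make_trace <- function(omega, fs = fixture_fs, location = "L5") {
  tr <- integrate_yaw(omega, fs = fs)
  attr(tr, "location") <- location
  tr
}

# Minimum-jerk yaw burst: angle deg over [t0, t0 + dur] on a 0..total grid
mj_omega <- function(total_s, t0, dur, angle, fs = fixture_fs) {
  t <- seq(0, total_s, by = 1 / fs)
  tau <- pmin(1, pmax(0, (t - t0) / dur))
  inside <- tau > 0 & tau < 1
  om <- numeric(length(t))
  om[inside] <- angle / dur * (30 * tau[inside]^2 - 60 * tau[inside]^3 +
                                 30 * tau[inside]^4)
  om
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
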