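# Internal numeric helpers shared across modules.

#' Root-mean-square of a numeric vector
#' @param x numeric vector
#' @param na.rm drop missing values first
#' @return scalar RMS
#' @export
rms <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  sqrt(mean(x^2))
}

# Wrap angle (degrees) to (-180, 180]
wrap_deg <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

# Central-difference derivative, forward/backward at the ends.
# Matches the classic gradient stencil; t may be irregular.
central_diff <- function(y, t) {
  n <- length(y)
  if (n < 2) return(rep(NA_real_, n))
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    idx <- 2:(n - 1)
    d[idx] <- (y[idx + 1] - y[idx - 1]) / (t[idx + 1] - t[idx - 1])
  }
  d
}

# O(n) moving variance over a window of w samples (population variance).
# Returns a vector of length n - w + 1; entry i covers samples i..(i+w-1).
moving_var <- function(x, w) {
  n <- length(x)
  if (w > n) return(numeric(0))
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  i <- seq_len(n - w + 1)
  s <- cs[i + w] - cs[i]
  s2 <- cs2[i + w] - cs2[i]
  pmax(s2 / w - (s / w)^2, 0)
}

# Zero-phase 4th-order low-pass Butterworth. cutoff_hz >= Nyquist -> identity.
lowpass_zero_phase <- function(x, fs, cutoff_hz = 20, order = 4) {
  wn <- cutoff_hz / (fs / 2)
  if (wn >= 1) return(x)
  bf <- signal::butter(order, wn, type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# Least-squares linear detrend
detrend_linear <- function(x, t = seq_along(x)) {
  if (length(x) < 3) return(x - mean(x))
  tc <- t - mean(t)
  x - mean(x) - (sum(tc * (x - mean(x))) / sum(tc^2)) * tc
}

stopf <- function(...) abort(sprintf(...))
warnf <- function(...) warn(sprintf(...))
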