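# Turning-characteristic extraction.
#
# The schema is pinned: 109 characteristics per upper-body location
# (21 spatiotemporal + 88 signal-based) for HD, C7 and L5 (327 total) and
# 49 per ankle role (9 spatiotemporal + 40 signal-based) for the inner and
# outer ankle, for a grand total of 425. The manifest below is the single
# source of truth for ids and ordering; extraction functions fill it.

.SIG_AXES <- c("vt", "ap", "ml", "r")
.PHASES <- c("overall", "start", "mid", "end")

upper_spt_entries <- function(loc) {
  e <- function(name, statistic, phase = "overall")
    tibble(feature_id = paste(loc, "spt", name, sep = "_"), location = loc,
           category = "spatiotemporal", axis = "none", phase = phase,
           statistic = statistic)
  bind_rows(
    e("n_turns", "count", "none"),
    e("n_left", "count", "none"),
    e("n_right", "count", "none"),
    bind_rows(lapply(c("mean", "min", "max", "sd"),
                     function(s) e(paste0("turn_time_", s), s))),
    bind_rows(lapply(c("mean", "min", "max", "sd"),
                     function(s) e(paste0("turn_angle_", s), s))),
    e("ang_vel_mean", "mean"), e("ang_vel_sd", "sd"),
    e("peak_ang_freq_mean", "mean"), e("peak_ang_freq_sd", "sd"),
    bind_rows(lapply(c("start", "mid", "end"), function(ph) bind_rows(
      e(paste0("ang_freq_", ph, "_mean"), "mean", ph),
      e(paste0("ang_freq_", ph, "_sd"), "sd", ph)
    )))
  )
}

ankle_spt_entries <- function(role) {
  e <- function(name, statistic)
    tibble(feature_id = paste(role, "spt", name, sep = "_"), location = role,
           category = "spatiotemporal", axis = "none", phase = "overall",
           statistic = statistic)
  bind_rows(
    bind_rows(lapply(c("mean", "min", "max", "sd"),
                     function(s) e(paste0("turn_angle_", s), s))),
    e("turn_time_mean", "mean"), e("turn_time_sd", "sd"),
    e("ang_vel_mean", "mean"), e("ang_vel_sd", "sd"),
    e("steps_mean", "mean")
  )
}

sig_entries <- function(loc, full = TRUE) {
  e <- function(quantity, statistic, axis, phase)
    tibble(feature_id = paste(loc, "sig", quantity, statistic, axis, phase,
                              sep = "_"),
           location = loc, category = "signal", axis = toupper(axis),
           phase = phase, statistic = statistic)
  rows <- list()
  for (q in c("acc", "gyr"))
    for (ax in .SIG_AXES)
      for (ph in .PHASES)
        rows[[length(rows) + 1]] <- e(q, "rms", ax, ph)
  for (q in c("jerk", "angacc")) {
    stats_set <- if (full) c("rms", "max", "min", "range") else "rms"
    for (st in stats_set)
      for (ax in .SIG_AXES)
        rows[[length(rows) + 1]] <- e(q, st, ax, "overall")
    if (full)
      for (ph in c("start", "mid", "end"))
        for (ax in .SIG_AXES)
          rows[[length(rows) + 1]] <- e(q, "rms", ax, ph)
  }
  bind_rows(rows)
}

#' The pinned 425-entry turning-characteristic manifest
#'
#' Ordered schema of every extracted characteristic: 21 spatiotemporal and
#' 88 signal-based entries for each of HD, C7 and L5; 9 spatiotemporal and
#' 40 signal-based for each ankle role (inner, outer). Ankle signal
#' entries are the RMS of acceleration and angular velocity over all four
#' axes and phases plus overall jerk and angular-acceleration RMS per axis.
#'
#' @return tibble with columns `feature_id`, `location`, `category`,
#'   `axis`, `phase`, `statistic`
#' @export
feature_manifest <- function() {
  bind_rows(
    bind_rows(lapply(.UPPER_BODY, function(loc)
      bind_rows(upper_spt_entries(loc), sig_entries(loc, full = TRUE)))),
    bind_rows(lapply(.ANKLE_ROLES, function(role)
      bind_rows(ankle_spt_entries(role), sig_entries(role, full = FALSE))))
  )
}

phase_indices <- function(idx, t, phase_mode = c("thirds", "window0.1")) {
  phase_mode <- match.arg(phase_mode)
  n <- length(idx)
  if (phase_mode == "thirds") {
    b <- round(seq(0, n, length.out = 4))
    list(overall = idx,
         start = idx[seq_len(max(1, b[2]))],
         mid = idx[(b[2] + 1):max(b[2] + 1, b[3])],
         end = idx[(b[3] + 1):n])
  } else {
    t0 <- t[idx[1]]; t1 <- t[idx[n]]; tm <- (t0 + t1) / 2
    list(overall = idx,
         start = idx[t[idx] <= t0 + 0.1],
         mid = idx[abs(t[idx] - tm) <= 0.05],
         end = idx[t[idx] >= t1 - 0.1])
  }
}

#' Spatiotemporal turning characteristics for one location
#'
#' Upper-body set (21): turn/left/right counts; mean, min, max and
#' variability (SD across turns) of turn time and turn angle magnitude;
#' mean and variability of overall angular velocity (angle/duration,
#' deg/s); mean and variability of peak angular frequency (max |omega|
#' within the turn, rad/s); mean and variability of the mean angular
#' frequency over a 0.1 s window at turn start, mid and end (rad/s).
#' Ankle-role set (9): angle mean/min/max/variability, duration
#' mean/variability, angular velocity mean/variability, mean steps per
#' turn.
#'
#' @param turns `turn_events` tibble for the location (ankle roles: one
#'   row per lower-back turn, possibly with `NA` angle when no matching
#'   ankle rotation was found)
#' @param trace the location's `yaw_trace` (required for upper-body
#'   angular-frequency features)
#' @param location `"HD"`, `"C7"`, `"L5"`, `"inner"` or `"outer"`
#' @param steps_per_turn integer vector, steps in each turn (ankle roles)
#' @return named numeric vector over the location's spatiotemporal
#'   manifest ids
#' @export
extract_spatiotemporal <- function(turns, trace = NULL, location,
                                   steps_per_turn = NULL) {
  upper <- location %in% .UPPER_BODY
  man <- if (upper) upper_spt_entries(location) else ankle_spt_entries(location)
  out <- setNames(rep(NA_real_, nrow(man)), man$feature_id)
  id <- function(name) paste(location, "spt", name, sep = "_")
  ok <- !is.na(turns$angle_deg)
  ang <- abs(turns$angle_deg[ok])
  dur <- (turns$end_s - turns$start_s)[ok]
  if (length(ang) == 0) return(out)
  if (upper) {
    out[id("n_turns")] <- nrow(turns)
    out[id("n_left")] <- sum(turns$direction == "left")
    out[id("n_right")] <- sum(turns$direction == "right")
  }
  out[id("turn_time_mean")] <- mean(dur)
  out[id("turn_time_sd")] <- sd(dur)
  out[id("turn_angle_mean")] <- mean(ang)
  out[id("turn_angle_min")] <- min(ang)
  out[id("turn_angle_max")] <- max(ang)
  out[id("turn_angle_sd")] <- sd(ang)
  if (upper) {
    out[id("turn_time_min")] <- min(dur)
    out[id("turn_time_max")] <- max(dur)
  }
  av <- ang / dur
  out[id("ang_vel_mean")] <- mean(av)
  out[id("ang_vel_sd")] <- sd(av)
  if (!upper) {
    if (!is.null(steps_per_turn) && length(steps_per_turn))
      out[id("steps_mean")] <- mean(steps_per_turn)
    return(out)
  }
  if (is.null(trace)) return(out)
  deg2rad <- pi / 180
  peak <- numeric(0)
  phf <- list(start = numeric(0), mid = numeric(0), end = numeric(0))
  tt <- turns[ok, , drop = FALSE]
  for (k in seq_len(nrow(tt))) {
    idx <- which(trace$t >= tt$start_s[k] & trace$t <= tt$end_s[k])
    if (length(idx) < 2) next
    w <- trace$omega_vt[idx]
    peak <- c(peak, max(abs(w)) * deg2rad)
    tmid <- (tt$start_s[k] + tt$end_s[k]) / 2
    wins <- list(
      start = idx[trace$t[idx] <= tt$start_s[k] + 0.1],
      mid = idx[abs(trace$t[idx] - tmid) <= 0.05],
      end = idx[trace$t[idx] >= tt$end_s[k] - 0.1]
    )
    for (ph in names(wins))
      phf[[ph]] <- c(phf[[ph]],
                     abs(mean(trace$omega_vt[wins[[ph]]])) * deg2rad)
  }
  out[id("peak_ang_freq_mean")] <- mean(peak)
  out[id("peak_ang_freq_sd")] <- sd(peak)
  for (ph in names(phf)) {
    out[id(paste0("ang_freq_", ph, "_mean"))] <- mean(phf[[ph]])
    out[id(paste0("ang_freq_", ph, "_sd"))] <- sd(phf[[ph]])
  }
  out
}

# Per-turn signal statistics. RMS uses the detrended set (`sig4`); jerk
# and angular acceleration differentiate the filtered, non-detrended set
# (`raw4`): a derivative is invariant to the constant offset detrending
# removes, but detrending a window would also subtract the window's mean
# slope and bias the derivative itself.
turn_signal_stats <- function(sig4, raw4, t, idx, phase_mode, full, quantity) {
  res <- list()
  phases <- phase_indices(idx, t, phase_mode)
  deriv <- lapply(raw4, function(x) central_diff(x[idx], t[idx]))
  for (ax in .SIG_AXES) {
    x <- sig4[[ax]]
    for (ph in .PHASES)
      res[[paste(quantity$raw, "rms", ax, ph, sep = "_")]] <-
        rms(x[phases[[ph]]])
    d <- deriv[[ax]]
    res[[paste(quantity$deriv, "rms", ax, "overall", sep = "_")]] <- rms(d)
    if (full) {
      res[[paste(quantity$deriv, "max", ax, "overall", sep = "_")]] <- max(d)
      res[[paste(quantity$deriv, "min", ax, "overall", sep = "_")]] <- min(d)
      res[[paste(quantity$deriv, "range", ax, "overall", sep = "_")]] <-
        max(d) - min(d)
      for (ph in c("start", "mid", "end")) {
        sub <- match(phases[[ph]], idx)
        res[[paste(quantity$deriv, "rms", ax, ph, sep = "_")]] <- rms(d[sub])
      }
    }
  }
  res
}

#' Signal-based turning characteristics for one location or ankle role
#'
#' Acceleration and angular-velocity channels are zero-phase low-pass
#' filtered (4th-order Butterworth, 20 Hz), then per turn window each axis
#' is linearly detrended, the resultant R = sqrt(VT^2 + AP^2 + ML^2) is
#' formed, and statistics are computed per turn and averaged across turns:
#' RMS of acceleration (g) and angular velocity (rad/s) per axis and phase
#' (overall/start/mid/end); RMS, max, min and range of jerk (g/s) and of
#' angular acceleration (rad/s^2) per axis over the whole turn, plus
#' per-phase jerk and angular-acceleration RMS (upper-body locations
#' only). Phases default to equal thirds of the turn window.
#'
#' @param rec the location's [imu_recording()]
#' @param turns `turn_events` (or any tibble with `start_s`, `end_s`)
#'   giving the windows; ankle roles pass their per-turn windows
#' @param location `"HD"`, `"C7"`, `"L5"`, `"inner"` or `"outer"`
#' @param phase_mode `"thirds"` (default) or `"window0.1"` (0.1 s windows)
#' @param cutoff_hz low-pass cutoff (default 20)
#' @return named numeric vector over the location's signal manifest ids
#' @export
extract_signal <- function(rec, turns, location, phase_mode = "thirds",
                           cutoff_hz = 20) {
  full <- location %in% .UPPER_BODY
  man <- sig_entries(location, full = full)
  out <- setNames(rep(NA_real_, nrow(man)), man$feature_id)
  if (nrow(turns) == 0) return(out)
  fs <- rec_fs(rec)
  deg2rad <- pi / 180
  acc <- lapply(c(vt = "acc_vt", ap = "acc_ap", ml = "acc_ml"),
                function(cl) lowpass_zero_phase(rec[[cl]], fs, cutoff_hz))
  gyr <- lapply(c(vt = "gyr_vt", ap = "gyr_ap", ml = "gyr_ml"),
                function(cl) lowpass_zero_phase(rec[[cl]], fs, cutoff_hz) * deg2rad)
  per_turn <- list()
  for (k in seq_len(nrow(turns))) {
    if (is.na(turns$start_s[k])) next
    idx <- which(rec$t >= turns$start_s[k] & rec$t <= turns$end_s[k])
    if (length(idx) < 3) {
      warnf("turn window %d at %s has < 3 samples; skipped", k, location)
      next
    }
    with_resultant <- function(ch3) {
      ch3$r <- sqrt(ch3$vt^2 + ch3$ap^2 + ch3$ml^2)
      ch3
    }
    prep <- function(ch3) {
      d <- lapply(ch3, function(x) {
        y <- x; y[idx] <- detrend_linear(x[idx], rec$t[idx]); y
      })
      with_resultant(d)
    }
    st <- c(
      turn_signal_stats(prep(acc), with_resultant(acc), rec$t, idx,
                        phase_mode, full, list(raw = "acc", deriv = "jerk")),
      turn_signal_stats(prep(gyr), with_resultant(gyr), rec$t, idx,
                        phase_mode, full, list(raw = "gyr", deriv = "angacc"))
    )
    per_turn[[length(per_turn) + 1]] <- unlist(st)
  }
  if (!length(per_turn)) return(out)
  avg <- Reduce(`+`, per_turn) / length(per_turn)
  ids <- paste(location, "sig", names(avg), sep = "_")
  out[ids] <- avg
  out
}

# Match an ankle-location turn event to each accepted L5 turn (same
# direction, overlapping the padded window; largest |angle| wins).
match_ankle_turns <- function(ankle_turns, l5, pad_s) {
  n <- nrow(l5)
  res <- tibble(start_s = rep(NA_real_, n), end_s = NA_real_,
                angle_deg = NA_real_)
  for (k in seq_len(n)) {
    lo <- l5$start_s[k] - pad_s; hi <- l5$end_s[k] + pad_s
    cand <- filter(ankle_turns,
                   .data$direction == l5$direction[k],
                   .data$end_s > lo, .data$start_s < hi)
    if (nrow(cand)) {
      j <- which.max(abs(cand$angle_deg))
      res$start_s[k] <- cand$start_s[j]
      res$end_s[k] <- cand$end_s[j]
      res$angle_deg[k] <- cand$angle_deg[j]
    }
  }
  res
}

#' Extract the full 425-entry feature vector for one session
#'
#' Runs (or reuses) session-level turn detection, then fills the manifest:
#' upper-body characteristics from each location's own accepted turns,
#' ankle characteristics per inner/outer role from the ankle rotations
#' matched to each accepted lower-back turn. A missing location yields
#' `NA` for its features, never silent zeros.
#'
#' @param session an [imu_session()]
#' @param detection optional result of [detect_session_turns()] (computed
#'   if absent)
#' @param config a [detection_config()]
#' @param phase_mode `"thirds"` or `"window0.1"`
#' @return one-row tibble: `subject_id`, `group_label`, `n_turns_used`,
#'   then the 425 manifest features in order
#' @export
extract_features <- function(session, detection = NULL,
                             config = detection_config(),
                             phase_mode = "thirds") {
  if (is.null(detection)) detection <- detect_session_turns(session, config)
  man <- feature_manifest()
  vals <- setNames(rep(NA_real_, nrow(man)), man$feature_id)
  turns <- detection$turns
  l5 <- filter(turns, .data$location == "L5") |> arrange(.data$start_s)
  for (loc in .UPPER_BODY) {
    if (!(loc %in% names(session$recordings))) next
    tloc <- filter(turns, .data$location == loc)
    spt <- extract_spatiotemporal(tloc, detection$yaw[[loc]], loc)
    sig <- extract_signal(session$recordings[[loc]], tloc, loc, phase_mode)
    vals[names(spt)] <- spt
    vals[names(sig)] <- sig
  }
  if (nrow(l5)) {
    for (role in .ANKLE_ROLES) {
      locs <- vapply(l5$direction, function(d) assign_inner_outer(d)[[role]],
                     character(1))
      if (!all(unique(locs) %in% names(session$recordings))) next
      # per-L5-turn matched ankle rotations for this role
      matched <- lapply(seq_len(nrow(l5)), function(k) {
        at <- filter(turns, .data$location == locs[k])
        match_ankle_turns(at, l5[k, , drop = FALSE], config$pad_s)
      }) |> bind_rows()
      nst <- vapply(seq_len(nrow(l5)), function(k)
        sum(detection$steps$l5_turn == k & detection$steps$ankle_role == role),
        numeric(1))
      spt <- extract_spatiotemporal(matched, NULL, role, steps_per_turn = nst)
      # signal windows: matched ankle rotation when found, else L5 window
      win <- matched
      miss <- is.na(win$start_s)
      win$start_s[miss] <- l5$start_s[miss]
      win$end_s[miss] <- l5$end_s[miss]
      # role statistics averaged over the contributing ankles, weighted by
      # how many L5 turns each ankle served in this role
      parts <- lapply(split(seq_len(nrow(l5)), locs), function(ks)
        list(v = extract_signal(session$recordings[[locs[ks[1]]]],
                                win[ks, , drop = FALSE], role, phase_mode),
             w = length(ks)))
      num <- Reduce(`+`, lapply(parts, function(p) {
        v <- p$v; v[is.na(v)] <- 0; v * p$w
      }))
      den <- Reduce(`+`, lapply(parts, function(p) (!is.na(p$v)) * p$w))
      sig <- num / ifelse(den == 0, NA, den)
      vals[names(spt)] <- spt
      vals[names(sig)] <- sig
    }
  }
  bind_cols(
    tibble(subject_id = session$subject_id,
           group_label = session$group_label %||% NA_character_,
           n_turns_used = nrow(l5)),
    as_tibble(as.list(vals))
  )
}

#' Build the subjects-by-features matrix for a list of sessions
#'
#' @param sessions list of [imu_session()] objects
#' @param config a [detection_config()]
#' @param phase_mode `"thirds"` or `"window0.1"`
#' @param standardize convert every feature column to a z-score
#'   (columnwise, ignoring `NA`)
#' @return tibble (one row per session) with the manifest as attribute
#'   `manifest`
#' @export
build_feature_matrix <- function(sessions, config = detection_config(),
                                 phase_mode = "thirds", standardize = FALSE) {
  rows <- lapply(sessions, extract_features, config = config,
                 phase_mode = phase_mode)
  X <- bind_rows(rows)
  man <- feature_manifest()
  if (standardize) X <- standardize_features(X)
  all_na <- man$feature_id[vapply(man$feature_id,
                                  function(f) all(is.na(X[[f]])), logical(1))]
  if (length(all_na))
    attr(X, "all_na_features") <- all_na
  attr(X, "manifest") <- man
  X
}

#' Z-score the feature columns of a feature table
#'
#' Non-feature columns (`subject_id`, `group_label`, `n_turns_used`) are
#' left untouched; constant columns become 0.
#'
#' @param X feature tibble from [build_feature_matrix()]
#' @return tibble of the same shape
#' @export
standardize_features <- function(X) {
  ids <- intersect(feature_manifest()$feature_id, names(X))
  for (f in ids) {
    v <- X[[f]]
    s <- sd(v, na.rm = TRUE)
    m <- mean(v, na.rm = TRUE)
    X[[f]] <- if (is.na(s) || s == 0) ifelse(is.na(v), NA, 0) else (v - m) / s
  }
  X
}
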