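# Turn detection from yaw traces.
#
# Pipeline: sign-consistent segments of vertical angular velocity
# (zero-crossing segmentation with an optional deadband), merging of
# gradual turns (same direction, gap < 0.5 s, each sub-turn > 10 deg),
# then per-location angle and duration thresholds. A turn from the lower
# back requires >= 90 deg; head, neck and ankles use 30 deg; accepted
# durations are 0.5 s <= d < 10 s.

#' Default detection configuration
#'
#' @param l5_min_angle lower-back turn angle threshold, deg (default 90)
#' @param other_min_angle head/neck/ankle threshold, deg (default 30)
#' @param min_dur,max_dur accepted turn duration bounds, s (default 0.5, 10;
#'   the lower bound is inclusive, the upper exclusive)
#' @param gradual_min_angle smallest sub-turn that participates in merging,
#'   deg (default 10)
#' @param gradual_max_gap largest inter-sub-turn gap that is merged, s
#'   (default 0.5)
#' @param deadband_dps deadband for zero-crossing sign determination, deg/s
#'   (default 5; set 0 for the literal zero-crossing rule)
#' @param step_min_angle smallest ankle rotation counted as a step, deg
#'   (default 30)
#' @param pad_s symmetric pad around the lower-back turn window when
#'   counting ankle steps, s (default 0.5)
#' @return a named list of detection parameters
#' @export
detection_config <- function(l5_min_angle = 90, other_min_angle = 30,
                             min_dur = 0.5, max_dur = 10,
                             gradual_min_angle = 10, gradual_max_gap = 0.5,
                             deadband_dps = 5, step_min_angle = 30,
                             pad_s = 0.5) {
  list(l5_min_angle = l5_min_angle, other_min_angle = other_min_angle,
       min_dur = min_dur, max_dur = max_dur,
       gradual_min_angle = gradual_min_angle, gradual_max_gap = gradual_max_gap,
       deadband_dps = deadband_dps, step_min_angle = step_min_angle,
       pad_s = pad_s)
}

as_turn_events <- function(df) {
  df <- as_tibble(df)
  if (!"duration_s" %in% names(df)) df$duration_s <- df$end_s - df$start_s
  structure(df, class = c("turn_events", class(df)))
}

empty_segments <- function() {
  tibble(start_s = numeric(0), end_s = numeric(0), i0 = integer(0),
         i1 = integer(0), angle_deg = numeric(0), direction = character(0))
}

#' Segment a yaw trace at zero crossings of angular velocity
#'
#' Returns maximal intervals over which the sign of the vertical angular
#' velocity is constant. Samples with |omega| below `deadband_dps` do not
#' seed a segment (noise suppression), but each candidate segment is then
#' extended outward to the nearest true zero crossing, so with
#' `deadband_dps = 0` the literal zero-crossing rule is recovered exactly.
#' Each segment carries its yaw displacement (trapezoidal integral of
#' omega over the segment).
#'
#' @param trace a `yaw_trace`
#' @param deadband_dps deadband in deg/s (default 5)
#' @return tibble with columns `start_s`, `end_s`, `i0`, `i1`,
#'   `angle_deg`, `direction`
#' @export
zero_crossing_segments <- function(trace, deadband_dps = 5) {
  omega <- trace$omega_vt
  t <- trace$t
  n <- length(omega)
  s <- sign(omega)
  s[abs(omega) < deadband_dps] <- 0
  runs <- rle(s)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values != 0
  if (!any(keep)) return(empty_segments())
  seg <- tibble(i0 = starts[keep], i1 = ends[keep], dir = runs$values[keep])
  # extend each segment outward while omega keeps the segment's sign
  sgn_raw <- sign(omega)
  for (k in seq_len(nrow(seg))) {
    i0 <- seg$i0[k]
    lo <- if (k > 1) seg$i1[k - 1] + 1 else 1
    while (i0 > lo && sgn_raw[i0 - 1] == seg$dir[k]) i0 <- i0 - 1
    seg$i0[k] <- i0
    i1 <- seg$i1[k]
    hi <- if (k < nrow(seg)) seg$i0[k + 1] - 1 else n
    while (i1 < hi && sgn_raw[i1 + 1] == seg$dir[k]) i1 <- i1 + 1
    seg$i1[k] <- i1
  }
  # same-sign segments may now touch (sub-deadband dip of the same sign):
  # coalesce them
  out <- list(); cur <- seg[1, ]
  for (k in seq_len(nrow(seg))[-1]) {
    if (seg$dir[k] == cur$dir && seg$i0[k] <= cur$i1 + 1) {
      cur$i1 <- seg$i1[k]
    } else {
      out[[length(out) + 1]] <- cur
      cur <- seg[k, ]
    }
  }
  out[[length(out) + 1]] <- cur
  seg <- bind_rows(out)
  seg$angle_deg <- map_dbl(seq_len(nrow(seg)), function(k) {
    idx <- seg$i0[k]:seg$i1[k]
    if (length(idx) < 2) return(0)
    pracma::trapz(t[idx], omega[idx])
  })
  tibble(start_s = t[seg$i0], end_s = t[seg$i1],
         i0 = seg$i0, i1 = seg$i1, angle_deg = seg$angle_deg,
         direction = ifelse(seg$dir < 0, "left", "right"))
}

#' Merge gradual turns
#'
#' Consecutive same-direction segments, each with displacement above
#' `min_angle`, separated by gaps shorter than `max_gap`, are combined into
#' one turn whose angle is the sum of the sub-angles. Sub-threshold
#' segments (< `min_angle`) neither merge nor break a merge chain. The
#' operation is idempotent.
#'
#' @param segments tibble from [zero_crossing_segments()]
#' @param min_angle smallest participating sub-turn, deg (default 10)
#' @param max_gap largest merged gap, s (default 0.5)
#' @return tibble of merged segments with a `subturns` list column
#' @export
merge_gradual_turns <- function(segments, min_angle = 10, max_gap = 0.5) {
  seg <- filter(segments, abs(.data$angle_deg) > min_angle)
  if (nrow(seg) == 0) {
    return(tibble(start_s = numeric(0), end_s = numeric(0),
                  angle_deg = numeric(0), direction = character(0),
                  subturns = list()))
  }
  seg <- arrange(seg, .data$start_s)
  grp <- integer(nrow(seg)); grp[1] <- 1L
  for (k in seq_len(nrow(seg))[-1]) {
    gap <- seg$start_s[k] - seg$end_s[k - 1]
    same_dir <- seg$direction[k] == seg$direction[k - 1]
    grp[k] <- if (same_dir && gap < max_gap) grp[k - 1] else grp[k - 1] + 1L
  }
  seg$grp <- grp
  merged <- seg |>
    group_by(.data$grp) |>
    summarise(
      subturns = list(pick("start_s", "end_s", "angle_deg")),
      start_s = first(.data$start_s), end_s = last(.data$end_s),
      angle_deg = sum(.data$angle_deg), direction = first(.data$direction),
      .groups = "drop"
    ) |>
    select("start_s", "end_s", "angle_deg", "direction", "subturns",
           everything()) |>
    select(-"grp")
  merged
}

#' Detect turns at one location
#'
#' Applies zero-crossing segmentation, gradual-turn merging and the
#' per-location acceptance rule: |angle| >= 90 deg for L5, >= 30 deg for
#' HD/C7/LA/RA, with duration in [0.5, 10) s.
#'
#' @param trace a `yaw_trace`
#' @param location sensor location; defaults to the trace's own
#' @param config a [detection_config()]
#' @return a `turn_events` tibble: `location`, `start_s`, `end_s`,
#'   `angle_deg` (signed), `direction`, `n_subturns`, `subturns`,
#'   `duration_s`
#' @export
detect_turns <- function(trace, location = NULL, config = detection_config()) {
  location <- location %||% attr(trace, "location")
  if (is.null(location) || is.na(location) || !(location %in% .LOCATIONS))
    stopf("unknown location '%s'", location %||% "NULL")
  min_angle <- if (location == "L5") config$l5_min_angle else config$other_min_angle
  merged <- zero_crossing_segments(trace, config$deadband_dps) |>
    merge_gradual_turns(config$gradual_min_angle, config$gradual_max_gap)
  ev <- merged |>
    mutate(duration_s = .data$end_s - .data$start_s) |>
    filter(abs(.data$angle_deg) >= min_angle,
           .data$duration_s >= config$min_dur,
           .data$duration_s < config$max_dur) |>
    mutate(location = location,
           n_subturns = map_int(.data$subturns, nrow)) |>
    select("location", "start_s", "end_s", "angle_deg", "direction",
           "n_subturns", "subturns", "duration_s")
  as_turn_events(ev)
}

#' Map ankles to inner/outer roles for one lower-back turn
#'
#' Inner ankle = the ankle on the side the subject turns toward (right
#' ankle for a right turn, left for a left turn); outer = the other.
#'
#' @param direction `"left"` or `"right"` (or a `turn_events` row)
#' @return named character vector `c(inner =, outer =)`
#' @export
assign_inner_outer <- function(direction) {
  if (is.data.frame(direction)) direction <- direction$direction[1]
  direction <- match.arg(direction, c("left", "right"))
  if (direction == "right") c(inner = "RA", outer = "LA")
  else c(inner = "LA", outer = "RA")
}

#' Count turning steps from an ankle trace
#'
#' Within a lower-back turn window (padded symmetrically by `pad_s`), every
#' unmerged zero-crossing rotation of the ankle of at least
#' `step_min_angle` degrees in the turn's direction counts as one step.
#' Steps are deliberately counted on unmerged segments: successive steps of
#' the same foot are separated only by short stance gaps that gradual-turn
#' merging would collapse.
#'
#' @param ankle_trace `yaw_trace` of one ankle (fused)
#' @param window numeric length-2, lower-back turn `c(start_s, end_s)`
#' @param direction turn direction, `"left"` or `"right"`
#' @param pad_s symmetric window pad in seconds (default 0.5)
#' @param step_min_angle step threshold in degrees (default 30)
#' @param deadband_dps passed to [zero_crossing_segments()]
#' @return tibble of step events: `start_s`, `end_s`, `angle_deg`
#' @export
count_steps <- function(ankle_trace, window, direction, pad_s = 0.5,
                        step_min_angle = 30, deadband_dps = 5) {
  if (is.null(ankle_trace)) {
    out <- tibble(start_s = numeric(0), end_s = numeric(0),
                  angle_deg = numeric(0))
    attr(out, "ankle_missing") <- TRUE
    return(out)
  }
  lo <- window[1] - pad_s; hi <- window[2] + pad_s
  seg <- zero_crossing_segments(ankle_trace, deadband_dps)
  mid <- (seg$start_s + seg$end_s) / 2
  seg |>
    filter(mid >= lo, mid <= hi,
           abs(.data$angle_deg) >= step_min_angle,
           .data$direction == !!direction) |>
    select("start_s", "end_s", "angle_deg")
}

#' Detect turns and steps for a whole session
#'
#' Estimates yaw at every available location, detects per-location turns,
#' and for each accepted lower-back turn assigns ankle roles and counts
#' steps.
#'
#' @param session an [imu_session()]
#' @param config a [detection_config()]
#' @param static_window_s still-window length for gyro bias estimation (s)
#' @return list with elements `turns` (all locations, `turn_events`
#'   tibble), `steps` (tibble: `l5_turn`, `ankle_role`, `location`,
#'   `start_s`, `end_s`, `angle_deg`), and `yaw` (named list of
#'   `yaw_trace`s)
#' @export
detect_session_turns <- function(session, config = detection_config(),
                                 static_window_s = 2) {
  traces <- lapply(session$recordings, estimate_yaw,
                   static_window_s = static_window_s)
  turns <- imap(traces, function(tr, loc) detect_turns(tr, loc, config)) |>
    bind_rows()
  l5 <- filter(turns, .data$location == "L5") |> arrange(.data$start_s)
  steps <- list()
  if (nrow(l5)) {
    for (k in seq_len(nrow(l5))) {
      roles <- assign_inner_outer(l5$direction[k])
      for (role in names(roles)) {
        st <- count_steps(traces[[roles[[role]]]],
                          c(l5$start_s[k], l5$end_s[k]), l5$direction[k],
                          pad_s = config$pad_s,
                          step_min_angle = config$step_min_angle,
                          deadband_dps = config$deadband_dps)
        if (nrow(st))
          steps[[length(steps) + 1]] <-
            mutate(st, l5_turn = k, ankle_role = role,
                   location = roles[[role]], .before = 1)
      }
    }
  }
  steps <- if (length(steps)) bind_rows(steps) else
    tibble(l5_turn = integer(0), ankle_role = character(0),
           location = character(0), start_s = numeric(0),
           end_s = numeric(0), angle_deg = numeric(0))
  list(turns = as_turn_events(turns), steps = steps, yaw = traces)
}
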