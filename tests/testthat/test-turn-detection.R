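half_sine <- function(amp, dur, fs = fixture_fs) {
  t <- seq(0, dur, by = 1 / fs)
  amp * sin(pi * t / dur)
}

test_that("zero-crossing segmentation finds sign-consistent intervals", {
  fs <- fixture_fs
  # single positive half-sine -> one segment spanning it
  om <- c(numeric(fs), half_sine(80, 2), numeric(fs))
  seg <- zero_crossing_segments(make_trace(om), deadband_dps = 5)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$direction, "right")
  expect_equal(seg$angle_deg, pracma::trapz(seq_along(om) / fs, om),
               tolerance = 1)

  # +half-sine then -half-sine -> two opposite segments
  om2 <- c(numeric(fs), half_sine(80, 2), -half_sine(80, 2), numeric(fs))
  seg2 <- zero_crossing_segments(make_trace(om2), deadband_dps = 5)
  expect_equal(seg2$direction, c("right", "left"))
  expect_equal(seg2$angle_deg[1], -seg2$angle_deg[2], tolerance = 0.5)

  # everything inside the deadband -> no segments
  om3 <- half_sine(4, 3)
  expect_equal(nrow(zero_crossing_segments(make_trace(om3), 5)), 0L)
  # motionless trace -> no segments
  expect_equal(nrow(zero_crossing_segments(make_trace(numeric(500)), 5)), 0L)
})

test_that("deadband zero reproduces the literal zero-crossing rule", {
  om <- c(numeric(10), rep(3, 20), numeric(10), rep(-3, 20), numeric(10))
  seg <- zero_crossing_segments(make_trace(om), deadband_dps = 0)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$direction, c("right", "left"))
  # with the default deadband these 3 deg/s wiggles vanish
  expect_equal(nrow(zero_crossing_segments(make_trace(om), 5)), 0L)
})

# hand-built merged segment tables
seg_row <- function(start, end, angle) {
  tibble::tibble(start_s = start, end_s = end, i0 = NA_integer_,
                 i1 = NA_integer_, angle_deg = angle,
                 direction = ifelse(angle < 0, "left", "right"))
}

test_that("gradual-turn merging follows the gap/direction/angle rule", {
  # +60, +70, +50 with 0.3 s gaps -> one +180 turn with 3 subturns
  s <- dplyr::bind_rows(seg_row(0, 1, 60), seg_row(1.3, 2.3, 70),
                        seg_row(2.6, 3.6, 50))
  m <- merge_gradual_turns(s)
  expect_equal(nrow(m), 1L)
  expect_equal(m$angle_deg, 180)
  expect_equal(nrow(m$subturns[[1]]), 3L)
  expect_equal(sum(m$subturns[[1]]$angle_deg), m$angle_deg)

  # +60 then -60 with 0.3 s gap -> not merged (direction differs)
  s2 <- dplyr::bind_rows(seg_row(0, 1, 60), seg_row(1.3, 2.3, -60))
  expect_equal(nrow(merge_gradual_turns(s2)), 2L)

  # +60, 0.6 s gap, +60 -> not merged (gap >= 0.5 s)
  s3 <- dplyr::bind_rows(seg_row(0, 1, 60), seg_row(1.6, 2.6, 60))
  expect_equal(nrow(merge_gradual_turns(s3)), 2L)

  # sub-threshold jitter between sub-turns does not break the chain
  s4 <- dplyr::bind_rows(seg_row(0, 1, 60), seg_row(1.05, 1.1, -4),
                         seg_row(1.3, 2.3, 70))
  m4 <- merge_gradual_turns(s4)
  expect_equal(nrow(m4), 1L)
  expect_equal(m4$angle_deg, 130)
})

test_that("merging is idempotent and subturn angles sum to the merged angle", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      k <- sample(2:6, 1)
      durs <- runif(k, 0.3, 1); gaps <- runif(k, 0.05, 1.2)
      ends <- cumsum(durs + gaps)
      starts <- ends - durs
      s <- seg_row(starts, ends, runif(k, -120, 120))
      m1 <- merge_gradual_turns(s)
      m2 <- merge_gradual_turns(dplyr::select(m1, -"subturns"))
      expect_equal(dplyr::select(m1, -"subturns"),
                   dplyr::select(m2, -"subturns"))
      expect_equal(purrr::map_dbl(m1$subturns, ~ sum(.x$angle_deg)),
                   m1$angle_deg)
    }
  })
})

test_that("per-location thresholds and the duration window gate accepted turns", {
  fs <- fixture_fs
  mk <- function(angle, dur, loc) {
    om <- mj_omega(dur + 8, 4, dur, angle)
    detect_turns(make_trace(om, location = loc), config = detection_config())
  }
  expect_equal(nrow(mk(85, 2, "L5")), 0L)    # below the 90 deg L5 threshold
  expect_equal(nrow(mk(178, 3, "L5")), 1L)
  expect_equal(nrow(mk(85, 2, "HD")), 1L)    # HD threshold is 30 deg
  expect_equal(nrow(mk(-40, 1.5, "C7")), 1L)
  expect_equal(nrow(mk(25, 1.5, "C7")), 0L)
  ev <- mk(-178, 3, "L5")
  expect_equal(ev$direction, "left")
  expect_lt(ev$angle_deg, 0)

  # duration gates: a 12 s 120-degree rotation is rejected
  om_long <- mj_omega(20, 4, 12, 120)
  expect_equal(nrow(detect_turns(make_trace(om_long, location = "L5"))), 0L)

  bad <- make_trace(mj_omega(10, 4, 2, 100))
  attr(bad, "location") <- NULL
  expect_error(detect_turns(bad, location = "XX"), "unknown location")
})

test_that("inner/outer ankle mapping follows the turn direction", {
  expect_equal(assign_inner_outer("right"), c(inner = "RA", outer = "LA"))
  expect_equal(assign_inner_outer("left"), c(inner = "LA", outer = "RA"))
  # roles swap between consecutive opposite turns
  r1 <- assign_inner_outer("right"); r2 <- assign_inner_outer("left")
  expect_equal(unname(r1["inner"]), unname(r2["outer"]))
})

test_that("step counting finds discrete ankle rotations inside the window", {
  fs <- fixture_fs
  # three discrete 60 deg rotations inside a 6 s window
  om <- mj_omega(10, 2, 0.8, 60) + mj_omega(10, 3.5, 0.8, 60) +
    mj_omega(10, 5, 0.8, 60)
  tr <- make_trace(om, location = "RA")
  st <- count_steps(tr, window = c(2, 6), direction = "right")
  expect_equal(nrow(st), 3L)
  expect_equal(sum(st$angle_deg), 180, tolerance = 2)

  # motionless ankle -> no steps
  expect_equal(nrow(count_steps(make_trace(numeric(1000), location = "RA"),
                                c(2, 6), "right")), 0L)
  # one continuous 180 deg pivot -> one step
  om1 <- mj_omega(10, 3, 2, 180)
  expect_equal(nrow(count_steps(make_trace(om1, location = "LA"),
                                c(3, 5), "right")), 1L)
  # opposite-direction rotations are not counted
  expect_equal(nrow(count_steps(make_trace(om1, location = "LA"),
                                c(3, 5), "left")), 0L)
  # missing ankle recording -> empty with flag
  empty <- count_steps(NULL, c(2, 6), "right")
  expect_equal(nrow(empty), 0L)
  expect_true(attr(empty, "ankle_missing"))
})

test_that("session-level detection recovers simulated turns and steps", {
  res <- simulate_session(synth_config("control"), seed = 3)
  det <- quiet(detect_session_turns(res$session))
  l5 <- dplyr::filter(det$turns, location == "L5")
  tru <- dplyr::filter(res$truth$turns, location == "L5")
  expect_equal(nrow(l5), nrow(tru))
  expect_equal(l5$direction, tru$direction)
  expect_lt(max(abs(l5$start_s - tru$start_s)), 0.3)
  expect_lt(max(abs(l5$end_s - tru$end_s)), 0.3)
  # steps per role match the generated count
  counts <- dplyr::count(det$steps, l5_turn, ankle_role)
  expect_true(all(counts$n == rep(res$truth$k_steps, each = 2)))
})
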