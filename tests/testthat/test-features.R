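test_that("the manifest pins the 425-feature schema", {
  man <- feature_manifest()
  expect_equal(nrow(man), 425L)
  expect_equal(anyDuplicated(man$feature_id), 0L)
  counts <- dplyr::count(man, location, category)
  for (loc in c("HD", "C7", "L5")) {
    expect_equal(counts$n[counts$location == loc &
                            counts$category == "spatiotemporal"], 21L)
    expect_equal(counts$n[counts$location == loc &
                            counts$category == "signal"], 88L)
  }
  for (role in c("inner", "outer")) {
    expect_equal(counts$n[counts$location == role &
                            counts$category == "spatiotemporal"], 9L)
    expect_equal(counts$n[counts$location == role &
                            counts$category == "signal"], 40L)
  }
  expect_equal(sum(counts$n[counts$location %in% c("HD", "C7", "L5")]), 327L)
})

single_turn <- function(angle, dur, t0 = 4, total = 12, loc = "L5") {
  om <- mj_omega(total, t0, dur, angle)
  tr <- make_trace(om, location = loc)
  list(trace = tr,
       turns = detect_turns(tr, loc, detection_config(deadband_dps = 0)))
}

test_that("spatiotemporal closed forms: angular velocity, counts, variability", {
  st <- single_turn(180, 2)
  f <- extract_spatiotemporal(st$turns, st$trace, "L5")
  expect_equal(unname(f["L5_spt_turn_time_mean"]), 2, tolerance = 0.02)
  expect_equal(unname(f["L5_spt_turn_angle_mean"]), 180, tolerance = 1)
  # angular velocity = angle/time = 90 deg/s (1.571 rad/s)
  expect_equal(unname(f["L5_spt_ang_vel_mean"]), 90, tolerance = 1.5)
  expect_equal(unname(f["L5_spt_ang_vel_mean"]) * pi / 180, 1.571,
               tolerance = 0.03)
  expect_equal(unname(f["L5_spt_n_turns"]), 1)
  # peak angular frequency of a minimum-jerk 180/2s turn: 1.875 * 90 deg/s
  expect_equal(unname(f["L5_spt_peak_ang_freq_mean"]),
               1.875 * 90 * pi / 180, tolerance = 0.05)

  # two turns of opposite sign -> one left, one right
  om <- mj_omega(20, 3, 2, -170) + mj_omega(20, 9, 2, 175)
  tr <- make_trace(om, location = "L5")
  tu <- detect_turns(tr, "L5", detection_config(deadband_dps = 0))
  f2 <- extract_spatiotemporal(tu, tr, "L5")
  expect_equal(unname(f2["L5_spt_n_left"]), 1)
  expect_equal(unname(f2["L5_spt_n_right"]), 1)

  # identical repeated turns -> zero variability
  om3 <- mj_omega(30, 3, 2, 170) + mj_omega(30, 9, 2, 170) +
    mj_omega(30, 15, 2, 170)
  tr3 <- make_trace(om3, location = "HD")
  tu3 <- detect_turns(tr3, "HD", detection_config(deadband_dps = 0))
  f3 <- extract_spatiotemporal(tu3, tr3, "HD")
  expect_equal(unname(f3["HD_spt_turn_time_sd"]), 0, tolerance = 1e-9)
  expect_equal(unname(f3["HD_spt_turn_angle_sd"]), 0, tolerance = 1e-6)
  expect_equal(unname(f3["HD_spt_ang_freq_mid_sd"]), 0, tolerance = 1e-6)

  # zero turns -> all NA
  f0 <- extract_spatiotemporal(detect_turns(make_trace(numeric(1000)), "L5"),
                               NULL, "L5")
  expect_true(all(is.na(f0)))
})

test_that("signal closed forms: sine RMS, ramp jerk, constant angular velocity", {
  fs <- fixture_fs
  t <- seq(0, 12, by = 1 / fs); n <- length(t)
  A <- 0.35; fr <- 5
  acc <- cbind(A * sin(2 * pi * fr * t), 0, 0)
  gyr <- matrix(0, n, 3); gyr[, 1] <- 20     # constant omega
  rec <- imu_recording(t, acc, gyr, location = "L5", fs = fs)
  win <- tibble::tibble(start_s = 2, end_s = 10)  # whole cycles of the sine
  f <- extract_signal(rec, win, "L5")
  expect_equal(unname(f["L5_sig_acc_rms_vt_overall"]), A / sqrt(2),
               tolerance = 0.005 * A)
  # constant omega: angular acceleration RMS ~ 0 (and is exactly detrended)
  expect_equal(unname(f["L5_sig_angacc_rms_vt_overall"]), 0, tolerance = 1e-6)

  # linear ramp: jerk ~ slope everywhere, range of jerk ~ 0
  k <- 0.8   # g/s
  rec2 <- imu_recording(t, cbind(k * t, 0, 0), matrix(0, n, 3),
                        location = "C7", fs = fs)
  f2 <- extract_signal(rec2, win, "C7")
  expect_equal(unname(f2["C7_sig_jerk_max_vt_overall"]), k, tolerance = 0.01 * k)
  expect_equal(unname(f2["C7_sig_jerk_range_vt_overall"]), 0,
               tolerance = 0.01 * k)
  # detrending makes the within-window acc RMS of a pure ramp ~ 0
  expect_equal(unname(f2["C7_sig_acc_rms_vt_overall"]), 0, tolerance = 1e-6)
})

test_that("acceleration scaling propagates to acc/jerk features only", {
  res <- simulate_session(synth_config("control", n_turns = 2), seed = 17)
  rec <- res$session$recordings$L5
  det <- quiet(detect_session_turns(res$session))
  tu <- dplyr::filter(det$turns, location == "L5")
  f1 <- extract_signal(rec, tu, "L5")
  c_ <- 3.7
  rec2 <- rec
  for (col in c("acc_vt", "acc_ap", "acc_ml")) rec2[[col]] <- rec2[[col]] * c_
  f2 <- extract_signal(rec2, tu, "L5")
  acc_ids <- grep("_sig_(acc|jerk)_", names(f1), value = TRUE)
  gyr_ids <- grep("_sig_(gyr|angacc)_", names(f1), value = TRUE)
  expect_equal(unname(f2[acc_ids]), unname(c_ * f1[acc_ids]), tolerance = 1e-8)
  expect_equal(unname(f2[gyr_ids]), unname(f1[gyr_ids]), tolerance = 1e-12)
  # spatiotemporal features never see the accelerometer
  s1 <- extract_spatiotemporal(tu, det$yaw$L5, "L5")
  expect_equal(unname(s1["L5_spt_turn_time_mean"]),
               mean(tu$end_s - tu$start_s))
})

test_that("features are invariant to the session time origin", {
  res <- simulate_session(synth_config("control", n_turns = 2), seed = 19)
  f1 <- quiet(extract_features(res$session))
  shift <- 100
  recs <- lapply(res$session$recordings, function(r) {
    r$t <- r$t + shift
    r
  })
  s2 <- quiet(imu_session(recs, "shifted"))
  f2 <- quiet(extract_features(s2))
  ids <- feature_manifest()$feature_id
  expect_equal(as.numeric(f2[1, ids]), as.numeric(f1[1, ids]),
               tolerance = 1e-6)
})

test_that("the feature matrix has the manifest shape and z-scoring normalizes", {
  co <- simulate_cohort(3, 3, seed = 23)
  X <- quiet(build_feature_matrix(unname(co$sessions)))
  man <- feature_manifest()
  expect_equal(dim(X), c(6L, 3L + 425L))
  expect_identical(names(X)[-(1:3)], man$feature_id)
  # duplicated session -> identical rows
  X2 <- quiet(build_feature_matrix(list(co$sessions[[1]], co$sessions[[1]])))
  expect_equal(as.numeric(X2[1, man$feature_id]),
               as.numeric(X2[2, man$feature_id]))
  # z-scored: non-constant columns have mean 0, sd 1
  Z <- standardize_features(X)
  v <- vapply(man$feature_id, function(f) sd(X[[f]], na.rm = TRUE), 1)
  nc <- man$feature_id[!is.na(v) & v > 0]
  mus <- vapply(nc, function(f) mean(Z[[f]]), 1)
  sds <- vapply(nc, function(f) sd(Z[[f]]), 1)
  expect_lt(max(abs(mus)), 1e-9)
  expect_lt(max(abs(sds - 1)), 1e-9)
})
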