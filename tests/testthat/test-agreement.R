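# Independent ICC(2,1) oracle: explicit two-way ANOVA sums of squares.
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  sse <- sum((m - outer(rowMeans(m), rep(1, k)) -
                outer(rep(1, n), colMeans(m)) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

test_that("ICC(2,1) matches the ANOVA mean-squares oracle exactly", {
  withr::with_seed(41, {
    for (rep in 1:5) {
      m <- matrix(rnorm(16, 10, 2), 8, 2)
      expect_equal(icc_2_1(m), icc_oracle(m), tolerance = 1e-10)
    }
  })
  # identical columns with between-subject variance -> 1
  x <- c(3, 7, 12, 5, 9, 1)
  expect_equal(icc_2_1(cbind(x, x)), 1)
  # the oracle can also be cross-checked against aov() mean squares
  withr::with_seed(42, {
    m <- matrix(rnorm(12, 5, 3), 6, 2)
    df <- data.frame(y = as.vector(m),
                     subj = factor(rep(1:6, 2)),
                     rater = factor(rep(1:2, each = 6)))
    ms <- summary(stats::aov(y ~ subj + rater, df))[[1]][["Mean Sq"]]
    icc_aov <- (ms[1] - ms[3]) / (ms[1] + ms[3] + (2 / 6) * (ms[2] - ms[3]))
    expect_equal(icc_2_1(m), icc_aov, tolerance = 1e-10)
  })
})

test_that("a constant offset hurts absolute agreement but not rank agreement", {
  x <- c(3, 7, 12, 5, 9, 1)
  m <- cbind(x, x + 10)
  expect_lt(icc_2_1(m), 0.5)
  expect_equal(suppressWarnings(cor(m[, 1], m[, 2], method = "spearman")), 1)
  # symmetric in the two raters
  expect_equal(icc_2_1(m), icc_2_1(m[, 2:1]), tolerance = 1e-12)
})

test_that("ICC degenerate inputs are handled", {
  expect_warning(v <- icc_2_1(cbind(rep(2, 5), rep(2, 5))), "variance")
  expect_true(is.nan(v))
  expect_error(icc_2_1(cbind(1:2, 1:2)), "at least 3")
})

test_that("limits of agreement match hand arithmetic and a sampling check", {
  # a=(10,12,14), b=(9,12,15): d=(1,0,-1), bias 0, LOA = 1.96*sd = 1.96
  loa <- limits_of_agreement(c(10, 12, 14), c(9, 12, 15))
  expect_equal(loa$bias, 0)
  expect_equal(loa$loa_abs, 1.96, tolerance = 1e-12)
  expect_equal(loa$loa_pct, 100 * 1.96 / 12, tolerance = 1e-10)

  # identical series
  loa0 <- limits_of_agreement(1:5, 1:5)
  expect_equal(loa0$loa_abs, 0); expect_equal(loa0$bias, 0)

  # d ~ N(0, 0.25^2): LOA ~ 1.96 * 0.25 = 0.49
  withr::with_seed(43, {
    a <- runif(200, 5, 15)
    b <- a - rnorm(200, 0, 0.25)
    loa2 <- limits_of_agreement(a, b)
    expect_lt(abs(loa2$loa_abs - 0.49), 0.05)
  })

  expect_warning(limits_of_agreement(c(1, -1), c(-1, 1)), "grand mean")
})

test_that("event-series comparison matches, reports, and counts unmatched", {
  ref <- tibble::tibble(start_s = seq(10, 100, by = 10),
                        end_s = seq(10, 100, by = 10) + 2)
  # identical series -> perfect agreement
  r0 <- compare_event_series(ref, ref)
  expect_equal(r0$icc21, c(1, 1))
  expect_equal(r0$rmse, c(0, 0))

  # jittered boundaries: RMSE ~ jitter SD
  withr::with_seed(44, {
    nref <- tibble::tibble(start_s = seq(10, 500, by = 10))
    nref$end_s <- nref$start_s + 2
    test <- tibble::tibble(start_s = nref$start_s + rnorm(50, 0, 0.3),
                           end_s = nref$end_s + rnorm(50, 0, 0.3))
    r1 <- compare_event_series(nref, test)
    expect_lt(abs(r1$rmse[r1$boundary == "start"] - 0.3), 0.05)
    expect_gt(min(r1$icc21), 0.99)
  })

  # one missing event -> 9 matched pairs, 1 unmatched reported
  r2 <- compare_event_series(ref, ref[-4, ])
  expect_equal(r2$n[1], 9L)
  expect_equal(attr(r2, "n_unmatched_ref"), 1L)
  expect_error(compare_event_series(ref[1:4, ], ref[1:4, ] |>
                                      dplyr::mutate(start_s = start_s + 50)),
               "matched")
})

test_that("group comparison routes tests by normality and flags constants", {
  withr::with_seed(55, {
    fa <- tibble::tibble(f_norm = rnorm(30, 2), f_skew = rexp(30) + 2,
                         f_const = rep(1, 30))
    fb <- tibble::tibble(f_norm = rnorm(30, 0), f_skew = rexp(30),
                         f_const = rep(1, 30))
    res <- compare_groups(fa, fb)
    expect_equal(res$test[res$feature_id == "f_norm"], "t")
    expect_equal(res$test[res$feature_id == "f_skew"], "mann-whitney")
    expect_equal(res$test[res$feature_id == "f_const"], "skipped")
    expect_true(res$skipped[res$feature_id == "f_const"])
    # a 2 SD shift at n=30/30 is significant
    expect_true(all(res$significant[res$feature_id != "f_const"]))
    # z-scores against the pooled distribution mirror for equal group sizes
    ok <- !res$skipped
    expect_equal(res$z_a[ok] + res$z_b[ok], rep(0, sum(ok)), tolerance = 1e-9)
  })
})

test_that("RMSE dominates |bias| with equality only for constant differences", {
  a <- c(5, 6, 9, 11); b <- c(4, 5, 8, 10)   # constant difference 1
  st <- agreement_stats(a, b)
  expect_equal(st$rmse, abs(st$bias))
  withr::with_seed(46, {
    a2 <- rnorm(20, 10); b2 <- a2 + rnorm(20, 0.5, 0.4)
    st2 <- agreement_stats(a2, b2)
    expect_gt(st2$rmse, abs(st2$bias))
  })
})
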