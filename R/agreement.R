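# Agreement statistics between two time-event series (rater vs rater or
# rater vs algorithm): ICC(2,1), Spearman's rho, RMSE and Bland-Altman
# limits of agreement, plus per-feature two-group comparisons.

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measures:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, computed from the
#' two-way ANOVA mean squares of the n x k table (k raters).
#'
#' @param pairs n x k numeric matrix or data frame (k = 2 raters usually)
#' @return scalar ICC in `[-1, 1]`; `NaN` with a warning when the table
#'   has zero total variance
#' @export
icc_2_1 <- function(pairs) {
  m <- as.matrix(pairs)
  n <- nrow(m); k <- ncol(m)
  if (n < 3) stopf("need at least 3 subjects for ICC(2,1)")
  if (anyNA(m)) stopf("ICC table contains missing values")
  grand <- mean(m)
  ss_tot <- sum((m - grand)^2)
  if (ss_tot == 0) {
    warnf("zero total variance; ICC undefined")
    return(NaN)
  }
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- ss_tot - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Bland-Altman limits of agreement
#'
#' Differences `d = a - b`: bias = mean(d), absolute LOA = 1.96 * SD(d),
#' and LOA as a percentage of the grand mean of the pairwise averages.
#'
#' @param a,b equal-length numeric series
#' @return one-row tibble: `bias`, `loa_abs`, `loa_pct`, `n`
#' @export
limits_of_agreement <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  bias <- mean(d)
  loa_abs <- 1.96 * sd(d)
  gm <- mean((a + b) / 2)
  loa_pct <- if (gm == 0) {
    warnf("grand mean is zero; LOA%% undefined")
    NaN
  } else 100 * loa_abs / gm
  tibble(bias = bias, loa_abs = loa_abs, loa_pct = loa_pct, n = length(a))
}

#' Agreement statistics for one set of already-paired measurements
#'
#' @param a,b equal-length paired series (e.g. rater vs algorithm times)
#' @return one-row tibble: `icc21`, `rho`, `rmse`, `bias`, `loa_abs`,
#'   `loa_pct`, `n`, and a `bland_altman` list column
#' @export
agreement_stats <- function(a, b) {
  loa <- limits_of_agreement(a, b)
  tibble(
    icc21 = icc_2_1(cbind(a, b)),
    rho = suppressWarnings(cor(a, b, method = "spearman")),
    rmse = sqrt(mean((a - b)^2)),
    bias = loa$bias, loa_abs = loa$loa_abs, loa_pct = loa$loa_pct,
    n = loa$n,
    bland_altman = list(tibble(mean = (a + b) / 2, difference = a - b))
  )
}

# Greedy nearest-start 1:1 matching of test events to reference events.
match_events <- function(ref, test, match_tol_s) {
  used <- logical(nrow(test))
  idx <- rep(NA_integer_, nrow(ref))
  for (i in order(ref$start_s)) {
    d <- abs(test$start_s - ref$start_s[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= match_tol_s) {
      idx[i] <- j; used[j] <- TRUE
    }
  }
  idx
}

#' Agreement between two event series, per boundary
#'
#' Events are matched 1:1 by nearest start time within `match_tol_s`;
#' unmatched events are excluded and counted. For the matched pairs,
#' start and end boundaries are compared separately with ICC(2,1),
#' Spearman's rho, RMSE and Bland-Altman LOA.
#'
#' @param ref reference events (tibble with `start_s`, `end_s`)
#' @param test comparison events (same schema)
#' @param match_tol_s matching tolerance in seconds (default 2)
#' @return an `agreement_report`: tibble with one row per boundary
#'   (`start`, `end`) and columns `icc21`, `rho`, `rmse`, `bias`,
#'   `loa_abs`, `loa_pct`, `n`, a `bland_altman` list column of
#'   (mean, difference) pairs, plus attributes `n_unmatched_ref` and
#'   `n_unmatched_test`
#' @export
compare_event_series <- function(ref, test, match_tol_s = 2) {
  idx <- match_events(ref, test, match_tol_s)
  ok <- !is.na(idx)
  if (sum(ok) < 3)
    stopf("only %d matched event pair(s); need at least 3", sum(ok))
  rows <- lapply(c(start = "start_s", end = "end_s"), function(col)
    agreement_stats(ref[[col]][ok], test[[col]][idx[ok]]))
  out <- bind_rows(rows, .id = "boundary")
  structure(out, n_unmatched_ref = sum(!ok),
            n_unmatched_test = nrow(test) - sum(ok),
            class = c("agreement_report", class(out)))
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d matched pair(s); %d/%d unmatched ref/test\n",
              x$n[1], attr(x, "n_unmatched_ref"), attr(x, "n_unmatched_test")))
  NextMethod()
}

#' @rdname glance.plsda
#' @export
glance.agreement_report <- function(x, ...) {
  as_tibble(x) |> select(-"bland_altman")
}

#' Bland-Altman plot of an agreement report
#'
#' @param object an `agreement_report`
#' @param ... unused
#' @return a ggplot object, facetted by boundary
#' @method autoplot agreement_report
#' @export
autoplot.agreement_report <- function(object, ...) {
  df <- as_tibble(object) |>
    select("boundary", "bias", "loa_abs", "bland_altman") |>
    tidyr::unnest("bland_altman")
  ggplot(df, aes(x = .data$mean, y = .data$difference)) +
    geom_point(alpha = 0.6) +
    geom_hline(aes(yintercept = .data$bias), linetype = 1) +
    geom_hline(aes(yintercept = .data$bias + .data$loa_abs), linetype = 2) +
    geom_hline(aes(yintercept = .data$bias - .data$loa_abs), linetype = 2) +
    facet_wrap(~boundary, scales = "free") +
    labs(x = "mean of pair (s)", y = "difference (s)",
         title = "Bland-Altman agreement") +
    theme_minimal()
}

#' Per-feature two-group comparison
#'
#' For every feature column: Shapiro-Wilk normality check in each group;
#' if both groups are compatible with normality (p > 0.05) a Student
#' t-test (equal variances) is used, otherwise a Mann-Whitney U test.
#' Group means are also expressed as z-scores against the pooled
#' mean/SD. Constant features are skipped and flagged.
#'
#' @param features_a,features_b feature tibbles (one row per subject) for
#'   the two groups; non-numeric columns are ignored
#' @param alpha significance level (default 0.05)
#' @param p_adjust multiple-testing correction passed to
#'   [stats::p.adjust()] (default `"none"`)
#' @return tibble: `feature_id`, `test`, `p_value`, `significant`,
#'   `z_a`, `z_b`, `mean_a`, `mean_b`, `skipped`
#' @export
compare_groups <- function(features_a, features_b, alpha = 0.05,
                           p_adjust = "none") {
  num_cols <- intersect(
    names(features_a)[vapply(features_a, is.numeric, logical(1))],
    names(features_b)[vapply(features_b, is.numeric, logical(1))]
  )
  num_cols <- setdiff(num_cols, "n_turns_used")
  rows <- lapply(num_cols, function(f) {
    a <- features_a[[f]]; b <- features_b[[f]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 3 || length(b) < 3 || (sd(a) == 0 && sd(b) == 0)) {
      return(tibble(feature_id = f, test = "skipped", p_value = NA_real_,
                    z_a = NA_real_, z_b = NA_real_,
                    mean_a = mean(a), mean_b = mean(b), skipped = TRUE))
    }
    normal <- function(x) {
      if (sd(x) == 0) return(FALSE)
      stats::shapiro.test(x)$p.value > 0.05
    }
    if (normal(a) && normal(b)) {
      p <- stats::t.test(a, b, var.equal = TRUE)$p.value
      test <- "t"
    } else {
      p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
      test <- "mann-whitney"
    }
    pooled <- c(a, b)
    ps <- sd(pooled)
    tibble(feature_id = f, test = test, p_value = p,
           z_a = (mean(a) - mean(pooled)) / ps,
           z_b = (mean(b) - mean(pooled)) / ps,
           mean_a = mean(a), mean_b = mean(b), skipped = FALSE)
  })
  out <- bind_rows(rows)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  relocate(out, "significant", .after = "p_value")
}
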