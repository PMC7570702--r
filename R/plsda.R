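# PLS-DA: partial least squares regression on a dummy-coded (+1/-1) class
# label, used as a two-group discriminant classifier. Components are
# selected with the cross-validated predictive index Q^2 (leave-one-out
# PRESS): keep adding components while cumulated Q^2 keeps increasing and
# stays > 0. Feature importance is the standard VIP score,
#   VIP_j = sqrt( p * sum_k SSY_k w_jk^2 / sum_k SSY_k ),
# whose squared values average to 1 across features.

# NIPALS PLS1 core on a centered/scaled X and centered y.
pls1_core <- function(Xs, yc, K) {
  n <- nrow(Xs); p <- ncol(Xs)
  K <- min(K, n - 1, p)
  W <- matrix(0, p, K); P <- matrix(0, p, K); Tm <- matrix(0, n, K)
  q <- numeric(K)
  E <- Xs; f <- yc
  ssx0 <- sum(Xs^2); ssy0 <- sum(yc^2)
  r2x <- numeric(K); r2y <- numeric(K); ssy_comp <- numeric(K)
  for (k in seq_len(K)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { K <- k - 1; break }
    w <- w / nw
    tt <- drop(E %*% w)
    tt2 <- sum(tt^2)
    pk <- drop(crossprod(E, tt)) / tt2
    qk <- sum(f * tt) / tt2
    E <- E - tcrossprod(tt, pk)
    f <- f - qk * tt
    W[, k] <- w; P[, k] <- pk; Tm[, k] <- tt; q[k] <- qk
    r2x[k] <- 1 - sum(E^2) / ssx0
    r2y[k] <- 1 - sum(f^2) / ssy0
    ssy_comp[k] <- qk^2 * tt2
  }
  if (K == 0) stopf("X carries no covariance with y; cannot fit")
  idx <- seq_len(K)
  list(W = W[, idx, drop = FALSE], P = P[, idx, drop = FALSE],
       Tm = Tm[, idx, drop = FALSE], q = q[idx],
       r2x_cum = r2x[idx], r2y_cum = r2y[idx], ssy_comp = ssy_comp[idx])
}

# Regression coefficients for the first k components: b = W (P'W)^-1 q
pls1_coef <- function(fit, k) {
  Wk <- fit$W[, seq_len(k), drop = FALSE]
  Pk <- fit$P[, seq_len(k), drop = FALSE]
  qk <- fit$q[seq_len(k)]
  drop(Wk %*% solve(crossprod(Pk, Wk), qk))
}

code_labels <- function(y, positive = NULL) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2) stopf("y must contain exactly two classes")
  if (is.null(positive)) {
    positive <- if ("PD" %in% classes) "PD" else {
      tabs <- table(y)
      names(tabs)[which.min(tabs)]   # minority class is the positive one
    }
  }
  if (!positive %in% classes) stopf("positive class '%s' not in labels", positive)
  list(num = ifelse(y == positive, 1, -1), positive = positive,
       negative = setdiff(classes, positive))
}

scale_train <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1    # fold-constant columns contribute 0
  list(Xs = sweep(sweep(X, 2, mu), 2, sdv, "/"), mu = mu, sd = sdv)
}

#' Fit a PLS-DA model
#'
#' Fits NIPALS PLS1 regression of the dummy-coded labels (+1 for the
#' positive class, -1 otherwise) on column-standardized features.
#' Cumulated Q^2 is computed at each component count by leave-one-out
#' cross-validation (standardization redone inside every training fold);
#' the retained component count is the largest k at which cumulated Q^2 is
#' still increasing and positive. If no component achieves Q^2 > 0, a
#' one-component model is returned with `flagged = TRUE`.
#'
#' @param X feature table: numeric matrix/data frame, or a tibble from
#'   [build_feature_matrix()] (non-feature columns are dropped)
#' @param y class labels, two levels; `"PD"` (if present) or else the
#'   minority class is coded +1
#' @param max_components largest component count examined (default 10)
#' @param positive positive-class label override
#' @param compute_q2 set `FALSE` to skip the LOO Q^2 pass (then
#'   `n_components = max_components`)
#' @return an object of class `plsda`: weights, loadings, scores,
#'   `r2x_cum`, `r2y_cum`, `q2_cum`, selected `n_components`, `vip`
#' @export
fit_plsda <- function(X, y, max_components = 10, positive = NULL,
                      compute_q2 = TRUE) {
  Xm <- as_feature_matrix(X)
  if (nrow(Xm) < 4) stopf("need at least 4 subjects")
  if (nrow(Xm) != length(y)) stopf("nrow(X) != length(y)")
  keep <- apply(Xm, 2, function(v) !anyNA(v) && sd(v) > 0)
  if (any(!keep))
    warnf("dropping %d constant or incomplete feature column(s)", sum(!keep))
  if (!any(keep)) stopf("no usable feature columns")
  Xm <- Xm[, keep, drop = FALSE]
  cl <- code_labels(y, positive)
  yc <- cl$num - mean(cl$num)
  sc <- scale_train(Xm)
  K <- min(max_components, nrow(Xm) - 1, ncol(Xm))
  fit <- pls1_core(sc$Xs, yc, K)
  K <- length(fit$q)

  q2_cum <- rep(NA_real_, K)
  flagged <- FALSE
  if (compute_q2) {
    n <- nrow(Xm)
    press <- matrix(NA_real_, n, K)
    ss <- sum((cl$num - mean(cl$num))^2)
    for (i in seq_len(n)) {
      Xi <- Xm[-i, , drop = FALSE]; yi <- cl$num[-i]
      sci <- scale_train(Xi)
      fi <- pls1_core(sci$Xs, yi - mean(yi), K)
      xs <- (Xm[i, ] - sci$mu) / sci$sd
      for (k in seq_len(length(fi$q))) {
        pred <- sum(xs * pls1_coef(fi, k)) + mean(yi)
        press[i, k] <- (cl$num[i] - pred)^2
      }
    }
    q2_cum <- 1 - colSums(press) / ss
    ncomp <- 0
    for (k in seq_len(K)) {
      increasing <- if (k == 1) TRUE else q2_cum[k] > q2_cum[k - 1]
      if (!is.na(q2_cum[k]) && q2_cum[k] > 0 && increasing) ncomp <- k
      else break
    }
    if (ncomp == 0) { ncomp <- 1; flagged <- TRUE }
  } else {
    ncomp <- K
  }

  model <- structure(list(
    n_components = ncomp, max_components = K,
    x_weights = fit$W, x_loadings = fit$P, y_loadings = fit$q,
    scores = fit$Tm,
    r2x_cum = fit$r2x_cum, r2y_cum = fit$r2y_cum, q2_cum = q2_cum,
    ssy_comp = fit$ssy_comp,
    feature_ids = colnames(Xm) %||% paste0("x", seq_len(ncol(Xm))),
    center = sc$mu, scale = sc$sd, y_mean = mean(cl$num),
    positive = cl$positive, negative = cl$negative,
    class_threshold = 0, flagged = flagged, n = nrow(Xm)
  ), class = "plsda")
  model$vip <- vip_scores(model)
  model
}

as_feature_matrix <- function(X) {
  if (is.matrix(X)) return(X)
  X <- as.data.frame(X)
  drop_cols <- intersect(c("subject_id", "group_label", "n_turns_used"),
                         names(X))
  X <- X[, setdiff(names(X), drop_cols), drop = FALSE]
  as.matrix(X)
}

#' VIP scores of a fitted PLS-DA model
#'
#' Variable importance in projection over the selected components; with
#' `per_component = TRUE` returns the per-component VIP matrix (VIP of
#' each feature computed from single components), useful for screening
#' features influential in any one component.
#'
#' @param model a fitted `plsda`
#' @param n_components use this many components (default: the model's
#'   selected count)
#' @param per_component return a features x components matrix instead
#' @return named numeric vector (or matrix) of VIP scores
#' @export
vip_scores <- function(model, n_components = NULL, per_component = FALSE) {
  k <- n_components %||% model$n_components
  W <- model$x_weights[, seq_len(k), drop = FALSE]
  ssy <- model$ssy_comp[seq_len(k)]
  p <- nrow(W)
  if (per_component) {
    out <- sqrt(p) * abs(W)
    dimnames(out) <- list(model$feature_ids,
                          paste0("comp", seq_len(k)))
    return(out)
  }
  v <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  names(v) <- model$feature_ids
  v
}

#' Predict classes from a fitted PLS-DA model
#'
#' @param object a `plsda`
#' @param newdata feature table with the model's feature columns
#' @param type `"class"` or `"score"` (the raw regression response)
#' @param ... unused
#' @return character vector of classes or numeric scores
#' @export
predict.plsda <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  Xm <- as_feature_matrix(newdata)
  Xm <- Xm[, object$feature_ids, drop = FALSE]
  Xs <- sweep(sweep(Xm, 2, object$center), 2, object$scale, "/")
  b <- pls1_coef(list(W = object$x_weights, P = object$x_loadings,
                      q = object$y_loadings), object$n_components)
  score <- drop(Xs %*% b) + object$y_mean
  if (type == "score") return(score)
  # exact-threshold ties go to the negative (control) class
  ifelse(score > object$class_threshold, object$positive, object$negative)
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("<plsda> %d subject(s), %d feature(s), %d component(s)%s\n",
              x$n, length(x$feature_ids), x$n_components,
              if (x$flagged) " [flagged: no component reached Q2 > 0]" else ""))
  cat(sprintf("  R2X %.3f  R2Y %.3f  Q2 %.3f (cumulated at k = %d)\n",
              x$r2x_cum[x$n_components], x$r2y_cum[x$n_components],
              x$q2_cum[x$n_components], x$n_components))
  invisible(x)
}

#' Tidy a PLS-DA model: per-feature weights, loadings and VIP
#'
#' @param x a `plsda`
#' @param ... unused
#' @return tibble with one row per feature
#' @export
tidy.plsda <- function(x, ...) {
  k <- x$n_components
  tibble(
    feature_id = x$feature_ids,
    weight_1 = x$x_weights[, 1],
    loading_1 = x$x_loadings[, 1],
    vip = unname(x$vip)
  ) |> arrange(desc(.data$vip))
}

#' One-row summary of a PLS-DA model
#'
#' @param x a `plsda`
#' @param ... unused
#' @return one-row tibble: components, R2X, R2Y, Q2, flag
#' @export
glance.plsda <- function(x, ...) {
  k <- x$n_components
  tibble(n = x$n, n_features = length(x$feature_ids), n_components = k,
         r2x_cum = x$r2x_cum[k], r2y_cum = x$r2y_cum[k],
         q2_cum = x$q2_cum[k], flagged = x$flagged)
}

#' VIP bar plot for a fitted PLS-DA model
#'
#' @param object a `plsda`
#' @param top show this many top-ranked features (default 20)
#' @param ... unused
#' @return a ggplot object
#' @method autoplot plsda
#' @export
autoplot.plsda <- function(object, top = 20, ...) {
  df <- tidy(object) |> slice_head(n = top)
  ggplot(df, aes(x = .data$vip,
                 y = stats::reorder(.data$feature_id, .data$vip))) +
    geom_col(fill = "steelblue") +
    geom_vline(xintercept = 1, linetype = 2) +
    labs(x = "VIP", y = NULL, title = "Variable importance in projection") +
    theme_minimal()
}

#' Leave-one-out evaluation of a PLS-DA model specification
#'
#' For every subject, the model is refit on the remaining n - 1 (feature
#' standardization redone inside the fold) and the held-out subject is
#' predicted. The component count is fixed across folds: either supplied,
#' or selected once on the full data by the Q^2 rule.
#'
#' @param X feature table
#' @param y class labels (two levels)
#' @param n_components component count; `NULL` selects via [fit_plsda()]
#' @param positive positive-class label (default as in [fit_plsda()])
#' @return a `classification_report` list: accuracy / sensitivity /
#'   specificity in percent, confusion counts, per-subject predictions
#' @export
evaluate_loo <- function(X, y, n_components = NULL, positive = NULL) {
  Xm <- as_feature_matrix(X)
  y <- as.character(y)
  if (is.null(n_components)) {
    full <- fit_plsda(Xm, y, positive = positive)
    n_components <- full$n_components
    positive <- positive %||% full$positive
  }
  n <- nrow(Xm)
  preds <- character(n)
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (length(unique(yi)) < 2)
      stopf("LOO fold %d has a single-class training set", i)
    m <- fit_plsda(Xm[-i, , drop = FALSE], yi,
                   max_components = n_components,
                   positive = positive, compute_q2 = FALSE)
    preds[i] <- predict(m, Xm[i, , drop = FALSE])
  }
  pos <- positive %||% code_labels(y)$positive
  classification_report(truth = y, pred = preds, positive = pos)
}

#' Build a classification report from truth/prediction vectors
#'
#' @param truth true class labels
#' @param pred predicted class labels
#' @param positive the positive class (sensitivity numerator)
#' @return a `classification_report`: `accuracy`, `sensitivity`,
#'   `specificity` (percent), `tp`/`fn`/`tn`/`fp`, `predictions` tibble
#' @export
classification_report <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  structure(list(
    accuracy = 100 * (tp + tn) / length(truth),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    tp = tp, fn = fn, tn = tn, fp = fp, n = length(truth),
    positive = positive,
    predictions = tibble(truth = truth, pred = pred)
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> n = %d, accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%% (positive: %s)\n",
    x$n, x$accuracy, x$sensitivity, x$specificity, x$positive))
  invisible(x)
}

#' @rdname glance.plsda
#' @export
glance.classification_report <- function(x, ...) {
  tibble(n = x$n, accuracy = x$accuracy, sensitivity = x$sensitivity,
         specificity = x$specificity, tp = x$tp, fn = x$fn, tn = x$tn,
         fp = x$fp)
}

#' @export
tidy.classification_report <- function(x, ...) x$predictions

# broom-style generics re-exported so methods dispatch without broom
#' @export
tidy <- function(x, ...) UseMethod("tidy")
#' @export
glance <- function(x, ...) UseMethod("glance")
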