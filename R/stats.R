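#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with
#' `U = sum over pairs of [x > y] + 0.5 [x == y]`. The p-value is exact
#' (full enumeration) when the combined sample size is at most 16 and
#' there are no ties, otherwise a normal approximation with tie-corrected
#' variance and continuity correction is used. Identical pooled values
#' give `p = 1`.
#'
#' @param x,y numeric samples for the two groups.
#' @return List with `U` and `p` (two-sided).
#' @export
mann_whitney <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty", call. = FALSE)
  if (length(unique(c(x, y))) == 1L)
    return(list(U = length(x) * length(y) / 2, p = 1))
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y)) <= 16L && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE, alternative = "two.sided"))
  list(U = unname(wt$statistic), p = min(1, wt$p.value))
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m`, the family-wise threshold applied to the univariate
#' screen. In the motivating design `m` counts the unique features from
#' the two reduction methods plus the age and sex covariates.
#'
#' @param alpha nominal level (default 0.05).
#' @param m number of comparisons.
#' @return The corrected threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  alpha / m
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Characterizes a continuous score against two-class labels. The AUC is
#' computed by the rank (Mann-Whitney) formulation; its standard error
#' and the p-value against AUC = 0.5 use DeLong's placement-variance
#' method, and a binomial-exact (Clopper-Pearson style on the combined
#' sample size) 95% CI is reported alongside. The operating point is the
#' observed criterion value maximizing the Youden index
#' `J = Se + Sp - 1` (lowest criterion on ties); sensitivity and
#' specificity carry Clopper-Pearson exact 95% CIs. When the raw score
#' discriminates in the "lesser is positive" direction the score is
#' negated internally so the reported AUC is always >= 0.5, and the
#' direction is recorded (`>` vs `<=` criterion).
#'
#' @param scores numeric predictor values.
#' @param labels class labels (logical or two-level; `TRUE`/second level
#'   = positive).
#' @param direction `"auto"` (choose so AUC >= 0.5),
#'   `"greater_is_positive"` or `"lesser_is_positive"`.
#' @return An object of class `roc_result`: `auc`, `auc_ci`, `se_delong`,
#'   `p_vs_half`, `youden`, `cutoff`, `criterion` (printable form),
#'   `sensitivity`, `sens_ci`, `specificity`, `spec_ci`, `direction`,
#'   `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels,
                         direction = c("auto", "greater_is_positive",
                                       "lesser_is_positive")) {
  direction <- match.arg(direction)
  g <- as.logical_labels(labels)
  ok <- is.finite(scores) & !is.na(g)
  scores <- scores[ok]; g <- g[ok]
  n1 <- sum(g); n0 <- sum(!g)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)

  auc_raw <- auc_rank(scores, g)
  flip <- switch(direction,
                 auto = auc_raw < 0.5,
                 greater_is_positive = FALSE,
                 lesser_is_positive = TRUE)
  s <- if (flip) -scores else scores
  auc <- auc_rank(s, g)

  # DeLong placements
  v10 <- vapply(s[g], function(xi) mean((xi > s[!g]) + 0.5 * (xi == s[!g])), numeric(1))
  v01 <- vapply(s[!g], function(yj) mean((s[g] > yj) + 0.5 * (s[g] == yj)), numeric(1))
  var_auc <- stats::var(v10) / n1 + stats::var(v01) / n0
  se <- sqrt(var_auc)
  z <- if (se > 0) (auc - 0.5) / se else Inf
  p <- if (is.finite(z)) 2 * stats::pnorm(-abs(z)) else 0

  # binomial exact CI on the combined sample size (continuous beta version)
  n <- n1 + n0
  x_eff <- auc * n
  ci <- c(if (x_eff <= 0) 0 else stats::qbeta(0.025, x_eff, n - x_eff + 1),
          if (x_eff >= n) 1 else stats::qbeta(0.975, x_eff + 1, n - x_eff))

  # Youden scan over observed criteria ("positive if s > c")
  cand <- sort(unique(s))
  sesp <- vapply(cand, function(cv) {
    c(mean(s[g] > cv), mean(s[!g] <= cv))
  }, numeric(2))
  jj <- sesp[1, ] + sesp[2, ] - 1
  best <- which(jj == max(jj))[1] # lowest criterion on ties (cand sorted)
  cutoff_internal <- cand[best]
  sens <- sesp[1, best]; spec <- sesp[2, best]
  sens_ci <- clopper_pearson(round(sens * n1), n1)
  spec_ci <- clopper_pearson(round(spec * n0), n0)

  cutoff <- if (flip) -cutoff_internal else cutoff_internal
  criterion <- if (flip) sprintf("<=%.6g", cutoff) else sprintf(">%.6g", cutoff)

  structure(list(auc = auc, auc_ci = ci, se_delong = se, p_vs_half = p,
                 youden = max(jj), cutoff = cutoff, criterion = criterion,
                 sensitivity = sens, sens_ci = sens_ci,
                 specificity = spec, spec_ci = spec_ci,
                 direction = if (flip) "lesser_is_positive" else "greater_is_positive",
                 n_pos = n1, n_neg = n0),
            class = "roc_result")
}

# AUC by the rank (Mann-Whitney) identity, midranks for ties
auc_rank <- function(s, g) {
  r <- rank(s)
  n1 <- sum(g); n0 <- sum(!g)
  (sum(r[g]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  c(if (x == 0) 0 else stats::qbeta(a, x, n - x + 1),
    if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x))
}

#' @export
print.roc_result <- function(x, digits = 4, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f), DeLong p vs 0.5 = %.4g\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$p_vs_half))
  cat(sprintf("  Youden J = %.4f at criterion %s (direction: %s)\n",
              x$youden, x$criterion, x$direction))
  cat(sprintf("  Se %.2f%% (%.1f-%.1f), Sp %.2f%% (%.1f-%.1f)  [n+ = %d, n- = %d]\n",
              100 * x$sensitivity, 100 * x$sens_ci[1], 100 * x$sens_ci[2],
              100 * x$specificity, 100 * x$spec_ci[1], 100 * x$spec_ci[2],
              x$n_pos, x$n_neg))
  invisible(x)
}

#' ROC curve coordinates
#'
#' @param scores,labels as in [roc_analysis()].
#' @return data.frame of (criterion, sensitivity, specificity) over all
#'   observed thresholds, for plotting or export.
#' @export
roc_points <- function(scores, labels) {
  g <- as.logical_labels(labels)
  ok <- is.finite(scores); scores <- scores[ok]; g <- g[ok]
  cand <- c(-Inf, sort(unique(scores)))
  data.frame(criterion = cand,
             sensitivity = vapply(cand, function(cv) mean(scores[g] > cv), numeric(1)),
             specificity = vapply(cand, function(cv) mean(scores[!g] <= cv), numeric(1)))
}

#' Enter-method multiple regression of a two-class outcome
#'
#' Ordinary least squares of the 0/1 outcome on all predictors entered
#' simultaneously (the "enter" input model; a linear probability model,
#' matching the coefficient scale and 0-1 fitted-value criterion of the
#' motivating analysis). Reports per-predictor coefficient, standard
#' error, t-based p-value, partial correlation `t / sqrt(t^2 + df)`,
#' semipartial correlation `t * sqrt((1 - R^2) / df)`, and the variance
#' inflation factor `VIF_j = 1 / (1 - R_j^2)` from regressing predictor
#' `j` on the others. `R^2`, adjusted `R^2` and the multiple correlation
#' coefficient `MCC = sqrt(R^2)` summarize the fit; fitted values feed
#' the downstream prediction ROC.
#'
#' @param M a [feature_matrix] restricted to the predictors of interest
#'   (or a numeric matrix plus `labels`).
#' @param labels outcome labels when `M` is a bare matrix.
#' @param features optional character vector selecting predictor columns.
#' @return An object of class `enter_model`: `coefficients` (data.frame),
#'   `r2`, `r2_adjusted`, `mcc`, `fitted`, `labels`, `lm` (the underlying
#'   [stats::lm] fit).
#' @export
fit_enter_model <- function(M, labels = NULL, features = NULL) {
  if (inherits(M, "feature_matrix")) {
    X <- M$values; y <- as.numeric(M$labels)
  } else {
    X <- as.matrix(M)
    if (is.null(labels)) stop("labels required for a bare matrix", call. = FALSE)
    y <- as.numeric(as.logical_labels(labels))
  }
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(X))
    if (length(missing)) stop("unknown predictors: ",
                              paste(missing, collapse = ", "), call. = FALSE)
    X <- X[, features, drop = FALSE]
  }
  p <- ncol(X); n <- nrow(X)
  if (n <= p + 1L) stop("need more subjects than predictors + 1", call. = FALSE)
  dat <- data.frame(.outcome = y, X, check.names = FALSE)
  fit <- stats::lm(.outcome ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    dep <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("exact collinearity among predictors: ", paste(dep, collapse = ", "),
         call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients[-1, , drop = FALSE] # drop intercept
  df <- fit$df.residual
  r2 <- sm$r.squared
  tval <- ct[, "t value"]
  r_partial <- tval / sqrt(tval^2 + df)
  r_semipartial <- tval * sqrt((1 - r2) / df)
  vif <- vif_values(X)
  coefs <- data.frame(predictor = rownames(ct),
                      coefficient = ct[, "Estimate"],
                      std_error = ct[, "Std. Error"],
                      p = ct[, "Pr(>|t|)"],
                      r_partial = r_partial,
                      r_semipartial = abs(r_semipartial),
                      vif = vif[rownames(ct)],
                      row.names = NULL)
  structure(list(coefficients = coefs, r2 = r2,
                 r2_adjusted = sm$adj.r.squared, mcc = sqrt(r2),
                 fitted = unname(stats::fitted(fit)), labels = y == 1,
                 lm = fit),
            class = "enter_model")
}

# VIF_j = 1 / (1 - R_j^2); Inf flagged (not dropped) on near-singularity
vif_values <- function(X) {
  p <- ncol(X)
  if (p == 1L) return(stats::setNames(1, colnames(X)))
  out <- numeric(p)
  for (j in seq_len(p)) {
    fitj <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    ssr <- sum(fitj$residuals^2)
    sst <- sum((X[, j] - mean(X[, j]))^2)
    r2j <- 1 - ssr / sst
    out[j] <- if (r2j >= 1 - 1e-12) Inf else 1 / (1 - r2j)
  }
  stats::setNames(out, colnames(X))
}

#' @export
print.enter_model <- function(x, digits = 4, ...) {
  cat(sprintf("<enter_model> %d predictors, n = %d\n", nrow(x$coefficients),
              length(x$fitted)))
  cat(sprintf("  R2 = %.4f, adjusted R2 = %.4f, MCC = %.4f\n",
              x$r2, x$r2_adjusted, x$mcc))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' ROC of the prediction model's fitted values
#'
#' Applies [roc_analysis()] to the fitted values of an [fit_enter_model()]
#' fit, quantifying the combined discriminative ability of all predictors.
#'
#' @param model an `enter_model`.
#' @param labels optional labels (defaults to those stored in the model).
#' @return A `roc_result`.
#' @export
prediction_roc <- function(model, labels = NULL) {
  stopifnot(inherits(model, "enter_model"))
  if (is.null(labels)) labels <- model$labels
  roc_analysis(model$fitted, labels)
}
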