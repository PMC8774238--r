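#' Fit the full peritumoral-zone texture study
#'
#' The study-level estimator: from a subjects-by-features matrix with
#' two-class labels it runs the complete analysis chain of the
#' motivating design —
#' \enumerate{
#'   \item feature reduction by Fisher coefficient and by POE+ACC
#'     (`k` features each), pooled into a unique list with its overlap;
#'   \item univariate Mann-Whitney screening of the pooled features with
#'     a Bonferroni threshold `alpha / m`, where `m` is the number of
#'     pooled features plus the number of clinical covariates carried
#'     (age and sex, i.e. +2, by default);
#'   \item per-feature ROC characterization of the significant features
#'     (Youden-optimal cutoffs, DeLong inference);
#'   \item an enter-method linear probability model on the significant
#'     features with collinearity diagnostics;
#'   \item ROC of the model's fitted values (the prediction ROC).
#' }
#' When no feature survives the screen the study stops after the
#' univariate stage with `status = "no_significant_features"`.
#'
#' @param M a [feature_matrix] (or numeric matrix plus `labels`).
#' @param labels outcome labels when `M` is a bare matrix.
#' @param covariates optional data.frame of clinical covariates; its
#'   column count enters the Bonferroni `m` (a `NULL` value still adds
#'   `n_covariates` to mirror designs where age/sex are tested
#'   alongside).
#' @param k shortlist size per reduction method (default 10).
#' @param alpha nominal significance level (default 0.05).
#' @param n_covariates covariate count added to `m` when `covariates` is
#'   `NULL` (default 2: age and sex).
#' @param omit_p optional post-hoc flagging threshold for the
#'   multivariate stage: predictors with multivariate `p` above it are
#'   flagged (never silently dropped); `NULL` (default) flags nothing.
#' @return An object of class `pz_study`; see
#'   [print.pz_study()], [summary.pz_study()], [coef.pz_study()],
#'   [predict.pz_study()], [plot.pz_study()].
#' @examples
#' set.seed(1)
#' M <- synthetic_feature_matrix(n_pos = 17, n_neg = 19, n_features = 30,
#'                               n_effect = 5, effect_size = 2)
#' fit <- pz_study(M)
#' fit
#' @export
pz_study <- function(M, labels = NULL, covariates = NULL, k = 10L,
                     alpha = 0.05, n_covariates = 2L, omit_p = NULL) {
  if (!inherits(M, "feature_matrix")) M <- feature_matrix(M, labels)
  sel_f <- select_fisher(M, k = k)
  sel_p <- select_poe_acc(M, k = k)
  merged <- merge_selections(sel_f, sel_p)
  n_cov <- if (!is.null(covariates)) ncol(as.data.frame(covariates)) else n_covariates
  m <- length(merged$unique) + n_cov
  thr <- bonferroni_threshold(alpha, m)

  pos <- M$labels
  uni <- do.call(rbind, lapply(merged$unique, function(f) {
    x <- M$values[pos, f]; y <- M$values[!pos, f]
    mw <- mann_whitney(x, y)
    data.frame(feature = f, p_value = mw$p, U = mw$U,
               median_pos = stats::median(x, na.rm = TRUE),
               iqr_pos_lo = unname(stats::quantile(x, 0.25, na.rm = TRUE)),
               iqr_pos_hi = unname(stats::quantile(x, 0.75, na.rm = TRUE)),
               median_neg = stats::median(y, na.rm = TRUE),
               iqr_neg_lo = unname(stats::quantile(y, 0.25, na.rm = TRUE)),
               iqr_neg_hi = unname(stats::quantile(y, 0.75, na.rm = TRUE)))
  }))
  uni$significant <- uni$p_value < thr

  out <- list(selection = list(fisher = sel_f, poe_acc = sel_p,
                               unique = merged$unique, overlap = merged$overlap),
              univariate = uni, alpha = alpha, m = m, threshold = thr,
              positive = M$positive, n_pos = sum(pos), n_neg = sum(!pos),
              roc = NULL, model = NULL, prediction = NULL,
              status = "complete")

  sig <- uni$feature[uni$significant]
  if (length(sig) == 0L) {
    out$status <- "no_significant_features"
    return(structure(out, class = "pz_study"))
  }
  out$roc <- stats::setNames(
    lapply(sig, function(f) roc_analysis(M$values[, f], pos)), sig)

  if (nrow(M$values) > length(sig) + 1L) {
    out$model <- tryCatch(fit_enter_model(M, features = sig),
                          error = function(e) e)
    if (inherits(out$model, "error")) {
      out$status <- paste0("model_failed: ", conditionMessage(out$model))
      out$model <- NULL
    } else {
      if (!is.null(omit_p))
        out$model$coefficients$flagged <- out$model$coefficients$p > omit_p
      out$prediction <- prediction_roc(out$model)
    }
  } else {
    out$status <- "too_few_subjects_for_model"
  }
  structure(out, class = "pz_study")
}

#' @export
print.pz_study <- function(x, ...) {
  cat(sprintf("<pz_study> %d '%s' positive vs %d negative subjects\n",
              x$n_pos, x$positive, x$n_neg))
  cat(sprintf("  pooled features: %d unique (%d in both shortlists)\n",
              length(x$selection$unique), length(x$selection$overlap)))
  cat(sprintf("  Bonferroni threshold: %.3g = %.2g / %d; %d significant\n",
              x$threshold, x$alpha, x$m, sum(x$univariate$significant)))
  if (!is.null(x$model))
    cat(sprintf("  enter model: R2 = %.4f, prediction AUC = %.3f (Youden %.2f at %s)\n",
                x$model$r2, x$prediction$auc, x$prediction$youden,
                x$prediction$criterion))
  if (x$status != "complete") cat("  status:", x$status, "\n")
  invisible(x)
}

#' Summarize a fitted peritumoral-zone study
#'
#' @param object a [pz_study()] fit.
#' @param ... unused.
#' @return Invisibly, a list of the three study tables: `univariate`
#'   (selection + Mann-Whitney results), `roc` (per-feature ROC) and
#'   `regression` (enter-model coefficients), each a data.frame.
#' @export
summary.pz_study <- function(object, ...) {
  print(object)
  cat("\nUnivariate screen:\n")
  uni <- object$univariate
  uni_fmt <- data.frame(feature = uni$feature,
                        p = signif(uni$p_value, 3),
                        median_pos = signif(uni$median_pos, 4),
                        median_neg = signif(uni$median_neg, 4),
                        significant = uni$significant)
  print(uni_fmt, row.names = FALSE)
  roc_tab <- roc_table(object)
  if (!is.null(roc_tab)) { cat("\nPer-feature ROC:\n"); print(roc_tab, row.names = FALSE) }
  if (!is.null(object$model)) {
    cat("\nEnter model:\n"); print(object$model)
  }
  invisible(list(univariate = uni, roc = roc_tab,
                 regression = if (!is.null(object$model)) object$model$coefficients))
}

roc_table <- function(x) {
  if (is.null(x$roc)) return(NULL)
  do.call(rbind, lapply(names(x$roc), function(f) {
    r <- x$roc[[f]]
    data.frame(feature = f, auc = round(r$auc, 3),
               auc_lo = round(r$auc_ci[1], 3), auc_hi = round(r$auc_ci[2], 3),
               p = signif(r$p_vs_half, 3), youden = round(r$youden, 4),
               criterion = r$criterion,
               se_pct = round(100 * r$sensitivity, 2),
               sp_pct = round(100 * r$specificity, 2))
  }))
}

#' @export
coef.pz_study <- function(object, ...) {
  if (is.null(object$model)) return(NULL)
  stats::setNames(object$model$coefficients$coefficient,
                  object$model$coefficients$predictor)
}

#' @export
fitted.pz_study <- function(object, ...) {
  if (is.null(object$model)) return(NULL)
  object$model$fitted
}

#' Predict from a fitted study
#'
#' Applies the enter model to new subjects and (optionally) dichotomizes
#' at the Youden-optimal criterion of the prediction ROC.
#'
#' @param object a [pz_study()] fit with a prediction model.
#' @param newdata matrix/data.frame containing the model's predictor
#'   columns; omitted = training fitted values.
#' @param type `"response"` (continuous 0-1 score) or `"class"`
#'   (thresholded at the Youden criterion).
#' @param ... unused.
#' @export
predict.pz_study <- function(object, newdata = NULL,
                             type = c("response", "class"), ...) {
  type <- match.arg(type)
  if (is.null(object$model)) stop("study has no prediction model", call. = FALSE)
  score <- if (is.null(newdata)) object$model$fitted
           else stats::predict(object$model$lm, newdata = as.data.frame(newdata))
  if (type == "response") return(score)
  cut <- object$prediction$cutoff
  if (object$prediction$direction == "greater_is_positive") score > cut else score <= cut
}

#' Plot the prediction-model ROC curve
#'
#' @param x a [pz_study()] fit with a prediction model.
#' @param ... passed to [graphics::plot].
#' @export
plot.pz_study <- function(x, ...) {
  if (is.null(x$model)) stop("study has no prediction model", call. = FALSE)
  pts <- roc_points(x$model$fitted, x$model$labels)
  graphics::plot(1 - pts$specificity, pts$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("Prediction model ROC (AUC %.3f)", x$prediction$auc),
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
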