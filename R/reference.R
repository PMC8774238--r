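# Published values of the reference clinical study whose design this
# package implements. They are inputs (screening lists, p-values and
# operating points printed in that study's result tables), shipped as
# plain CSVs under inst/extdata/ so the worked-number checks run without
# any external data.

#' Published screening table of the reference study
#'
#' The two reduction-method shortlists (10 features each, identified by
#' their legacy software codes) with the published Mann-Whitney p-values
#' and per-class medians/IQRs. The three features selected by both
#' methods appear under both method labels.
#'
#' @return data.frame with columns method, feature, p_value (character;
#'   censored values like `"<0.001"` are preserved), medians and IQR
#'   bounds per class, plus `p_numeric` (censored values replaced by
#'   their upper bound) and `direction` (`"positive_higher"` /
#'   `"negative_higher"` from the class medians).
#' @export
reference_screening_table <- function() {
  tab <- utils::read.csv(system.file("extdata", "screening_table.csv",
                                     package = "peritex"),
                         stringsAsFactors = FALSE)
  tab$p_numeric <- as.numeric(sub("^<", "", tab$p_value))
  tab$direction <- ifelse(tab$median_pos > tab$median_neg,
                          "positive_higher", "negative_higher")
  tab
}

#' Published exclusion cascade of the reference study
#'
#' The stepwise record exclusions from the initial keyword search (686
#' reports) down to the final cohort, grouped in three stages
#' (report-level, record-level, image-review-level).
#'
#' @return data.frame with columns stage, label, count.
#' @export
reference_exclusion_cascade <- function() {
  utils::read.csv(system.file("extdata", "exclusion_cascade.csv",
                              package = "peritex"),
                  stringsAsFactors = FALSE)
}

#' Published combined prediction-model operating point
#'
#' Sensitivity/specificity at the published fitted-value criterion,
#' AUC with its binomial-exact CI, and the fit statistics of the
#' reference study's multivariate model.
#'
#' @return Named numeric vector.
#' @export
reference_combined_model <- function() {
  tab <- utils::read.csv(system.file("extdata", "combined_model.csv",
                                     package = "peritex"),
                         stringsAsFactors = FALSE)
  stats::setNames(tab$value, tab$quantity)
}
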