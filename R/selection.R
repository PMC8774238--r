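#' Subjects-by-features matrix with two-class labels
#'
#' The substrate of feature selection and statistics: a numeric matrix of
#' subjects (rows) by named features (columns), plus a two-class label
#' per subject. The positive class is the one the downstream prediction
#' model targets (high-grade glioma in the motivating application).
#'
#' Features that are constant across all subjects carry no class
#' information and are dropped with a warning before selection.
#'
#' @param values numeric matrix, rownames = subject ids, colnames =
#'   feature names.
#' @param labels vector coercible to a two-level factor.
#' @param positive which label value is the positive class (default: the
#'   second factor level).
#' @param drop_constant drop all-constant features (default TRUE).
#' @return An object of class `feature_matrix`: `values`, `labels`
#'   (logical, `TRUE` = positive), `positive` (label name), `subjects`.
#' @export
feature_matrix <- function(values, labels, positive = NULL, drop_constant = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    colnames(values) <- paste0("feature_", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("subject_", seq_len(nrow(values)))
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two classes", call. = FALSE)
  if (length(labels) != nrow(values))
    stop("one label per subject required", call. = FALSE)
  if (is.null(positive)) positive <- levels(labels)[2]
  if (!positive %in% levels(labels)) stop("positive class not among labels", call. = FALSE)
  pos <- labels == positive
  if (sum(pos) < 2L || sum(!pos) < 2L)
    stop("need at least 2 subjects per class", call. = FALSE)
  if (drop_constant) {
    keep <- apply(values, 2, function(v) {
      v <- v[is.finite(v)]
      length(v) >= 1L && stats::var(v) > 0
    })
    if (any(!keep)) {
      warning(sprintf("dropping %d constant/empty feature(s): %s",
                      sum(!keep), paste(utils::head(colnames(values)[!keep], 5),
                                        collapse = ", ")), call. = FALSE)
      values <- values[, keep, drop = FALSE]
    }
  }
  structure(list(values = values, labels = pos, positive = positive,
                 subjects = rownames(values)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d subjects (%d '%s' positive / %d negative), %d features\n",
              nrow(x$values), sum(x$labels), x$positive, sum(!x$labels),
              ncol(x$values)))
  invisible(x)
}

#' Fisher coefficient of class separability
#'
#' Ratio of between-class to within-class variance of a single feature:
#' `F = sum_k P_k (mu_k - mu)^2 / sum_k P_k sigma_k^2` with class
#' proportions `P_k` and population within-class variances. `F` is
#' invariant to affine rescaling of the feature. A zero denominator gives
#' `Inf` when the class means differ and 0 when they coincide.
#'
#' @param x numeric vector of per-subject feature values.
#' @param labels logical (or two-level) class labels.
#' @return Non-negative scalar (possibly `Inf`).
#' @export
fisher_score <- function(x, labels) {
  g <- as.logical_labels(labels)
  ok <- is.finite(x)
  x <- x[ok]; g <- g[ok]
  if (!any(g) || !any(!g)) stop("both classes must be non-empty", call. = FALSE)
  n <- length(x)
  mu <- mean(x)
  between <- 0; within <- 0
  for (cl in c(TRUE, FALSE)) {
    xi <- x[g == cl]
    p <- length(xi) / n
    between <- between + p * (mean(xi) - mu)^2
    within <- within + p * mean((xi - mean(xi))^2)
  }
  if (within == 0) return(if (between > 0) Inf else 0)
  between / within
}

as.logical_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  f <- as.factor(labels)
  if (nlevels(f) != 2L) stop("labels must have exactly two classes", call. = FALSE)
  f == levels(f)[2]
}

#' Rank features by Fisher coefficient
#'
#' @param M a [feature_matrix].
#' @param k number of features to retain (default 10).
#' @return An object of class `selection_result`: `method`, `ranked`
#'   (data.frame of feature, score) and `k`. Ties are broken by
#'   lexicographic feature name for reproducibility.
#' @export
select_fisher <- function(M, k = 10L) {
  stopifnot(inherits(M, "feature_matrix"))
  scores <- apply(M$values, 2, fisher_score, labels = M$labels)
  ord <- order(-scores, colnames(M$values))
  ranked <- data.frame(feature = colnames(M$values)[ord],
                       score = unname(scores[ord]))[seq_len(min(k, length(scores))), ]
  structure(list(method = "fisher", ranked = ranked, k = as.integer(k)),
            class = "selection_result")
}

#' Probability of classification error of a single-threshold rule
#'
#' Minimal empirical misclassification fraction over all threshold
#' placements and both polarities of the rule "positive if x > t" — the
#' error a one-feature classifier would make on the data at hand.
#'
#' @param x numeric feature values.
#' @param labels class labels.
#' @return Error fraction in `[0, 0.5]`.
#' @export
poe <- function(x, labels) {
  g <- as.logical_labels(labels)
  ok <- is.finite(x); x <- x[ok]; g <- g[ok]
  n <- length(x)
  thr <- c(-Inf, sort(unique(x)))
  err <- vapply(thr, function(t) {
    pred <- x > t
    min(mean(pred != g), mean(pred == g))
  }, numeric(1))
  min(err)
}

#' Greedy POE+ACC feature selection
#'
#' Forward selection minimizing the probability of classification error
#' plus the average absolute correlation with already-selected features.
#' Features are standardized first; the first pick minimizes POE alone,
#' every subsequent pick minimizes `POE(f) + mean_{s in S} |r(f, s)|`,
#' penalizing redundant (correlated) features. Ties break
#' lexicographically.
#'
#' @param M a [feature_matrix].
#' @param k number of features to select (default 10); when fewer
#'   eligible features exist, all are returned with a warning.
#' @return A `selection_result` with per-step POE+ACC scores.
#' @export
select_poe_acc <- function(M, k = 10L) {
  stopifnot(inherits(M, "feature_matrix"))
  V <- scale(M$values)
  feats <- colnames(V)
  if (length(feats) < k) {
    warning(sprintf("only %d eligible features (< k = %d)", length(feats), k),
            call. = FALSE)
    k <- length(feats)
  }
  poes <- apply(V, 2, poe, labels = M$labels)
  selected <- character(0); scores <- numeric(0)
  remaining <- feats
  while (length(selected) < k) {
    if (length(selected) == 0) {
      crit <- poes[remaining]
    } else {
      S <- V[, selected, drop = FALSE]
      acc <- vapply(remaining, function(f)
        mean(abs(suppressWarnings(stats::cor(V[, f], S)))), numeric(1))
      acc[is.na(acc)] <- 1 # degenerate correlation treated as fully redundant
      crit <- poes[remaining] + acc
    }
    pick <- remaining[order(crit, remaining)][1]
    selected <- c(selected, pick)
    scores <- c(scores, unname(crit[pick]))
    remaining <- setdiff(remaining, pick)
  }
  structure(list(method = "poe_acc",
                 ranked = data.frame(feature = selected, score = scores),
                 k = as.integer(k)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method '%s', %d features:\n", x$method,
              nrow(x$ranked)))
  print(x$ranked, row.names = FALSE)
  invisible(x)
}

#' Merge two selection shortlists
#'
#' Union of the two ranked lists preserving first-seen order, plus their
#' overlap — the pooling step that feeds univariate screening.
#'
#' @param a,b `selection_result` objects (or character vectors).
#' @return List with `unique` (character, first-seen order) and `overlap`
#'   (features present in both).
#' @export
merge_selections <- function(a, b) {
  fa <- if (inherits(a, "selection_result")) a$ranked$feature else as.character(a)
  fb <- if (inherits(b, "selection_result")) b$ranked$feature else as.character(b)
  list(unique = unique(c(fa, fb)), overlap = intersect(fa, fb))
}
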