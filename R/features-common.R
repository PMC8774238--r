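# Shared helpers for the texture-feature families.
#
# A "feature vector" is a named numeric vector; values that cannot be
# computed are NA with the reason recorded in attr(x, "undefined")
# (a named character vector), so batch extraction can proceed and report.

fv <- function(values, undefined = character(0)) {
  attr(values, "undefined") <- undefined
  values
}

fv_concat <- function(...) {
  parts <- unname(list(...))
  out <- unlist(lapply(parts, function(p) { attributes(p)$undefined <- NULL; p }))
  und <- unlist(lapply(parts, attr, "undefined"))
  if (is.null(und)) und <- character(0)
  fv(out, und)
}

#' List reasons for undefined feature values
#'
#' @param x a feature vector returned by any `*_features()` function or
#'   [extract_features()].
#' @return Named character vector mapping feature names to the reason the
#'   value is `NA`; empty when everything was computable.
#' @export
undefined_reasons <- function(x) {
  und <- attr(x, "undefined")
  if (is.null(und)) character(0) else und
}

# population central moments; kurtosis reported as excess (normal -> 0)
moment_stats <- function(v, names4 = c("Mean", "Variance", "Skewness", "Kurtosis")) {
  mu <- mean(v)
  va <- mean((v - mu)^2)
  out <- c(mu, va, NA_real_, NA_real_)
  und <- character(0)
  if (va > 0) {
    s <- sqrt(va)
    out[3] <- mean((v - mu)^3) / s^3
    out[4] <- mean((v - mu)^4) / s^4 - 3
  } else {
    und <- c("zero variance", "zero variance")
    names(und) <- names4[3:4]
  }
  names(out) <- names4
  fv(out, und)
}

# the four offsets of the feature set: H=(0,1), V=(1,0), N=(1,1), Z=(1,-1)
DIRECTION_OFFSETS <- list(H = c(0L, 1L), V = c(1L, 0L),
                          N = c(1L, 1L), Z = c(1L, -1L))

check_quantized <- function(q) {
  if (!inherits(q, "quantized_roi"))
    stop("expected a quantized_roi (see normalize_quantize())", call. = FALSE)
  invisible(TRUE)
}
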