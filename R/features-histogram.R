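#' First-order (histogram) features of a quantized ROI
#'
#' Moments and percentiles of the in-ROI gray-level histogram. `Mean` and
#' `Variance` are the population mean and variance of the levels,
#' `Skewness` and `Kurtosis` the standardized third and fourth central
#' moments (kurtosis as excess, normal = 0). `Perc_n` is the smallest
#' level `v` such that at least `n`% of in-ROI pixels have level `<= v`
#' (the point at which n% of the histogram mass lies to the left).
#'
#' @param q a [normalize_quantize()] result.
#' @param percentiles integer percentile indices in `(0, 100]`
#'   (default 10, the profile that keeps the full set at 275 features).
#' @return Named feature vector `HIST_Mean`, `HIST_Variance`,
#'   `HIST_Skewness`, `HIST_Kurtosis`, `HIST_Perc<n>...`; skewness and
#'   kurtosis are `NA` (with reason) for a constant ROI.
#' @export
histogram_features <- function(q, percentiles = 10) {
  check_quantized(q)
  v <- q$levels[q$mask]
  mom <- moment_stats(v)
  names(mom) <- paste0("HIST_", names(mom))
  und <- attr(mom, "undefined")
  if (length(und)) names(und) <- paste0("HIST_", names(und))

  sv <- sort(v)
  n <- length(sv)
  pv <- vapply(percentiles, function(p) {
    # smallest level with cumulative fraction >= p%
    sv[max(1L, ceiling(n * p / 100))]
  }, numeric(1))
  names(pv) <- paste0("HIST_Perc", percentiles)
  fv_concat(fv(unclass(mom), und), pv)
}
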