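#' Absolute gradient features
#'
#' The image is first quantized to 4 bits over the ROI (the gradient
#' family's own gray-level depth), then the gradient magnitude
#' `G = sqrt(drow^2 + dcol^2)` is computed by central differences on the
#' level grid at every pixel whose 4-neighbourhood lies inside the ROI.
#' Features are the population mean, variance, skewness and excess
#' kurtosis of `G`, plus `GrNonZeros`, the fraction of eligible pixels
#' with `G > 0`.
#'
#' @param image a [gray_image].
#' @param roi a congruent [roi_mask].
#' @param bits gray-level depth for this family (default 4).
#' @param mode normalization mode passed to [normalize_quantize()].
#' @return Named feature vector `GRAD_{GrMean, GrVariance, GrSkewness,
#'   GrKurtosis, GrNonZeros}`; all `NA` (with reason) when no pixel has a
#'   full in-ROI neighbourhood.
#' @export
gradient_features <- function(image, roi, bits = 4, mode = "mu3sigma") {
  q <- normalize_quantize(image, roi, bits = bits, mode = mode)
  L <- q$levels
  m <- q$mask
  nr <- nrow(L); nc <- ncol(L)
  nm <- paste0("GRAD_", c("GrMean", "GrVariance", "GrSkewness", "GrKurtosis", "GrNonZeros"))
  # eligible: interior pixels whose 4 neighbours are all in-mask
  if (nr < 3L || nc < 3L) {
    und <- rep("ROI too small for gradient neighbourhood", 5); names(und) <- nm
    return(fv(stats::setNames(rep(NA_real_, 5), nm), und))
  }
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  elig <- m[ri, ci] & m[ri - 1, ci] & m[ri + 1, ci] & m[ri, ci - 1] & m[ri, ci + 1]
  if (!any(elig)) {
    und <- rep("no pixel with full in-ROI 4-neighbourhood", 5); names(und) <- nm
    return(fv(stats::setNames(rep(NA_real_, 5), nm), und))
  }
  dr <- (L[ri + 1, ci] - L[ri - 1, ci]) / 2
  dc <- (L[ri, ci + 1] - L[ri, ci - 1]) / 2
  g <- sqrt(dr[elig]^2 + dc[elig]^2)
  mom <- moment_stats(g, names4 = c("GrMean", "GrVariance", "GrSkewness", "GrKurtosis"))
  und <- attr(mom, "undefined")
  names(mom) <- paste0("GRAD_", names(mom))
  if (length(und)) names(und) <- paste0("GRAD_", names(und))
  fv_concat(fv(unclass(mom), und),
            c(GRAD_GrNonZeros = mean(g > 0)))
}
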