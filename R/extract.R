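#' Extraction profile for the full texture-feature set
#'
#' Bundles the per-family computation settings. The default profile
#' reproduces the canonical 275-parameter set:
#' \itemize{
#'   \item 220 co-occurrence features (11 statistics x 5 distances x 4
#'     directions, 6 bits/pixel),
#'   \item 20 run-length features (5 statistics x 4 directions, 6
#'     bits/pixel),
#'   \item 20 wavelet energies (4 subbands x 5 scales),
#'   \item 5 histogram features (mean, variance, skewness, kurtosis and
#'     the 10th percentile),
#'   \item 5 absolute-gradient features (4 bits/pixel),
#'   \item 5 autoregressive parameters (Teta1-4, Sigma).
#' }
#' The `extended` histogram profile adds percentiles 1/50/90/99 (and so
#' no longer totals 275).
#'
#' @param glcm_bits,rlm_bits,gradient_bits gray-level depths per family.
#' @param glcm_distances integer vector of co-occurrence distances.
#' @param wavelet_scales number of dyadic scales.
#' @param histogram_percentiles percentile indices for the histogram
#'   family.
#' @return An object of class `extraction_profile`.
#' @export
extraction_profile <- function(glcm_bits = 6, glcm_distances = 1:5,
                               rlm_bits = 6, gradient_bits = 4,
                               wavelet_scales = 5,
                               histogram_percentiles = 10) {
  structure(list(glcm_bits = glcm_bits, glcm_distances = as.integer(glcm_distances),
                 rlm_bits = rlm_bits, gradient_bits = gradient_bits,
                 wavelet_scales = as.integer(wavelet_scales),
                 histogram_percentiles = histogram_percentiles),
            class = "extraction_profile")
}

#' @export
print.extraction_profile <- function(x, ...) {
  cat(sprintf(paste0("<extraction_profile> GLCM %d bits, d={%s}; RLM %d bits; ",
                     "gradient %d bits; %d wavelet scales; percentiles {%s}\n"),
              x$glcm_bits, paste(x$glcm_distances, collapse = ","), x$rlm_bits,
              x$gradient_bits, x$wavelet_scales,
              paste(x$histogram_percentiles, collapse = ",")))
  invisible(x)
}

#' Extract the full texture-feature set from one ROI
#'
#' Runs every feature family on the given image/ROI pair under an
#' [extraction_profile]. Families that cannot be computed (e.g. an ROI
#' too small for a deep wavelet scale) contribute `NA` values with
#' recorded reasons rather than aborting the extraction.
#'
#' @param image a [gray_image].
#' @param roi a congruent [roi_mask].
#' @param profile an [extraction_profile].
#' @return Named feature vector (275 values under the default profile);
#'   see [undefined_reasons()] for any `NA` entries.
#' @examples
#' img <- gray_image(matrix(rnorm(64 * 64, 30, 6), 64, 64))
#' roi <- roi_mask(matrix(TRUE, 64, 64))
#' f <- extract_features(img, roi)
#' length(f) # 275
#' @export
extract_features <- function(image, roi, profile = extraction_profile()) {
  check_congruent(image, roi)
  stopifnot(inherits(profile, "extraction_profile"))
  q6 <- normalize_quantize(image, roi, bits = profile$glcm_bits)
  hist_f <- histogram_features(q6, percentiles = profile$histogram_percentiles)
  grad_f <- gradient_features(image, roi, bits = profile$gradient_bits)
  ar_f <- ar_features(q6)
  glcm_f <- glcm_all_features(q6, distances = profile$glcm_distances)
  qr <- if (profile$rlm_bits == profile$glcm_bits) q6 else
    normalize_quantize(image, roi, bits = profile$rlm_bits)
  rlm_f <- do.call(fv_concat, lapply(names(DIRECTION_OFFSETS),
                                     function(d) rlm_features(qr, d)))
  wav_f <- wavelet_energies(q6, scales = profile$wavelet_scales)
  fv_concat(hist_f, grad_f, ar_f, glcm_f, rlm_f, wav_f)
}

#' Canonical names of the default feature set
#'
#' @param profile an [extraction_profile].
#' @return Character vector of the feature names [extract_features()]
#'   emits, in order.
#' @export
feature_names <- function(profile = extraction_profile()) {
  c(paste0("HIST_", c("Mean", "Variance", "Skewness", "Kurtosis",
                      paste0("Perc", profile$histogram_percentiles))),
    paste0("GRAD_", c("GrMean", "GrVariance", "GrSkewness", "GrKurtosis", "GrNonZeros")),
    c(paste0("AR_Teta", 1:4), "AR_Sigma"),
    as.vector(vapply(names(DIRECTION_OFFSETS), function(dir)
      as.vector(vapply(profile$glcm_distances, function(d)
        sprintf("GLCM_%s_d%d_%s", dir, d, GLCM_FEATURE_NAMES),
        character(length(GLCM_FEATURE_NAMES)))),
      character(length(profile$glcm_distances) * length(GLCM_FEATURE_NAMES)))),
    as.vector(vapply(names(DIRECTION_OFFSETS), function(dir)
      sprintf("RLM_%s_%s", dir, c("ShrtREmp", "LngREmph", "GLevNonU",
                                  "RLNonUni", "Fraction")), character(5))),
    sort_waven_names(profile$wavelet_scales))
}

#' Aliases for the legacy MaZda codes of the significant parameters
#'
#' Maps the seven legacy software codes that appear in the reference
#' screening table to canonical names of this package. The legacy
#' encoding is only partially documented (C = co-occurrence, a direction
#' letter, D = distance, s = scale); the mapping is a best-effort reading
#' and the embedded extra digits are treated as opaque.
#'
#' @return Named character vector: legacy code -> canonical name.
#' @export
mazda_aliases <- function() {
  c("Perc10"        = "HIST_Perc10",
    "WavEnHH_s-2"   = "WavEn_HH_s2",
    "WavEnHL_s-3"   = "WavEn_HL_s3",
    "CN6D4Contrast" = "GLCM_N_d4_Contrast",
    "CH5D4DifVarnc" = "GLCM_H_d4_DifVarnc",
    "CZ2D4DifVarnc" = "GLCM_Z_d4_DifVarnc",
    "RZD5GLevNonU"  = "RLM_Z_GLevNonU")
}

#' Per-pixel texture feature map
#'
#' Computes one named feature on a sliding square window centred at each
#' pixel (the window treated as a fully masked ROI), producing the
#' feature-distribution maps used to visualize where a texture statistic
#' concentrates. A border margin of `(window_px - 1) / 2` pixels is left
#' `NA`.
#'
#' @param image a [gray_image].
#' @param window_px odd window side length, at most the image extent.
#' @param feature_name a canonical feature name (see [feature_names()]).
#' @param bits gray-level depth for the window quantization (4 for the
#'   gradient family, 6 otherwise, by default).
#' @param step compute every `step`-th pixel (others interpolated by
#'   nearest computed value); `step = 1` is exact and slow.
#' @return A [gray_image] of feature values (`NA` margins and skipped
#'   pixels filled by nearest neighbour when `step > 1`).
#' @export
feature_map <- function(image, window_px, feature_name, bits = NULL, step = 1L) {
  stopifnot(inherits(image, "gray_image"))
  window_px <- as.integer(window_px)
  if (window_px %% 2L != 1L) stop("window_px must be odd", call. = FALSE)
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  if (window_px > nr || window_px > nc) stop("window larger than image", call. = FALSE)
  h <- (window_px - 1L) %/% 2L
  fspec <- parse_feature_name(feature_name)
  if (is.null(bits)) bits <- if (fspec$family == "GRAD") 4L else 6L
  full <- roi_mask(matrix(TRUE, window_px, window_px))
  out <- matrix(NA_real_, nr, nc)
  centers_r <- seq(1L + h, nr - h, by = step)
  centers_c <- seq(1L + h, nc - h, by = step)
  for (r in centers_r) {
    for (cc in centers_c) {
      win <- gray_image(image$pixels[(r - h):(r + h), (cc - h):(cc + h)],
                        spacing = image$spacing)
      out[r, cc] <- tryCatch(
        single_feature(win, full, fspec, bits = bits),
        error = function(e) NA_real_)
    }
  }
  if (step > 1L) { # nearest computed value for skipped interior pixels
    rr <- (1L + h):(nr - h); ccs <- (1L + h):(nc - h)
    near <- function(v, grid) grid[pmax(1L, pmin(length(grid), round((v - grid[1]) / step) + 1L))]
    out[rr, ccs] <- out[near(rr, centers_r), near(ccs, centers_c)]
  }
  # maps keep NA margins, so bypass the all-finite gray_image validation
  structure(list(pixels = out, spacing = image$spacing,
                 id = paste0(image$id, ":", feature_name)),
            class = "gray_image")
}

parse_feature_name <- function(name) {
  if (grepl("^HIST_", name)) return(list(family = "HIST", name = name))
  if (grepl("^GRAD_", name)) return(list(family = "GRAD", name = name))
  if (grepl("^AR_", name)) return(list(family = "AR", name = name))
  m <- regmatches(name, regexec("^GLCM_([HVNZ])_d([0-9]+)_([A-Za-z]+)$", name))[[1]]
  if (length(m)) return(list(family = "GLCM", direction = m[2],
                             distance = as.integer(m[3]), stat = m[4], name = name))
  m <- regmatches(name, regexec("^RLM_([HVNZ])_([A-Za-z]+)$", name))[[1]]
  if (length(m)) return(list(family = "RLM", direction = m[2], stat = m[3], name = name))
  m <- regmatches(name, regexec("^WavEn_(LL|LH|HL|HH)_s([0-9]+)$", name))[[1]]
  if (length(m)) return(list(family = "WAV", band = m[2],
                             scale = as.integer(m[3]), name = name))
  stop("unknown feature name: ", name, call. = FALSE)
}

# compute exactly one feature on an image+mask (used by feature_map and
# targeted extraction in simulations)
single_feature <- function(image, roi, fspec, bits = 6L) {
  if (is.character(fspec)) fspec <- parse_feature_name(fspec)
  if (fspec$family == "GRAD") {
    f <- gradient_features(image, roi, bits = bits)
    return(unname(f[fspec$name]))
  }
  q <- normalize_quantize(image, roi, bits = bits)
  val <- switch(fspec$family,
    HIST = {
      p <- if (grepl("^HIST_Perc", fspec$name))
        as.integer(sub("^HIST_Perc", "", fspec$name)) else 10
      histogram_features(q, percentiles = p)[fspec$name]
    },
    AR = ar_features(q)[fspec$name],
    GLCM = glcm_features(glcm(q, fspec$direction, fspec$distance),
                         prefix = sprintf("GLCM_%s_d%d_", fspec$direction,
                                          fspec$distance))[fspec$name],
    RLM = rlm_features(q, fspec$direction)[fspec$name],
    WAV = wavelet_energies(q, scales = fspec$scale)[fspec$name])
  unname(val)
}
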