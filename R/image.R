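#' Construct a grayscale image
#'
#' A `gray_image` holds a single 2D grid of real-valued intensities
#' (Hounsfield units for CT slices) together with the physical pixel
#' spacing in millimetres. It is the substrate of every downstream
#' operation: segmentation, normalization and texture extraction.
#'
#' @param pixels numeric matrix of intensities, at least 2x2, all finite.
#' @param spacing numeric length-2 vector `(row_mm, col_mm)`, both > 0.
#' @param id character identifier for the slice/subject.
#' @return An object of class `gray_image` with elements `pixels`,
#'   `spacing` and `id`.
#' @examples
#' img <- gray_image(matrix(0:15, 4, 4), spacing = c(1, 1), id = "ramp")
#' dim(img$pixels)
#' @export
gray_image <- function(pixels, spacing = c(1, 1), id = "image") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("gray_image requires at least 2x2 pixels", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("gray_image intensities must all be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be two positive values (row_mm, col_mm)", call. = FALSE)
  structure(list(pixels = pixels, spacing = spacing, id = as.character(id)[1]),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image '%s'> %d x %d px, spacing %.3g x %.3g mm, range [%.4g, %.4g]\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Construct a binary region-of-interest mask
#'
#' A `roi_mask` marks the peritumoral zone on a congruent [gray_image].
#' Masks come from seeded region growing ([region_grow]), manual edits,
#' or the synthetic cohort generator.
#'
#' @param mask logical (or 0/1) matrix; `TRUE` marks in-ROI pixels.
#' @param source one of `"seeded"`, `"manual"`, `"synthetic"`.
#' @return An object of class `roi_mask` with elements `mask` and `source`.
#' @export
roi_mask <- function(mask, source = c("manual", "seeded", "synthetic")) {
  source <- match.arg(source)
  mask <- as.matrix(mask)
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.logical(mask)) stop("mask must be logical or numeric 0/1", call. = FALSE)
  if (anyNA(mask)) stop("mask must not contain NA", call. = FALSE)
  if (!any(mask)) stop("mask must contain at least one pixel", call. = FALSE)
  structure(list(mask = mask, source = source), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d x %d, %d in-ROI px (%.1f%%), source '%s'\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask), x$source))
  invisible(x)
}

# congruence check used by every image+mask op
check_congruent <- function(image, roi) {
  stopifnot(inherits(image, "gray_image"), inherits(roi, "roi_mask"))
  if (!identical(dim(image$pixels), dim(roi$mask)))
    stop("image and ROI mask have different dimensions", call. = FALSE)
  invisible(TRUE)
}
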