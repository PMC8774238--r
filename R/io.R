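#' Read a grayscale image from file
#'
#' Reads a CT slice or fixture image into a [gray_image]. Three formats are
#' supported: single-frame grayscale DICOM (stored values rescaled to
#' Hounsfield units when RescaleSlope/Intercept are present, pixel spacing
#' taken from the header), binary PGM (P5, 8- or 16-bit), and grayscale PNG
#' (8- or 16-bit, decoded to integer sample values).
#'
#' @param path file path.
#' @param format `"auto"` (by extension/magic), `"dicom"`, `"pgm"` or `"png"`.
#' @param spacing pixel spacing in mm used for formats that carry none;
#'   ignored for DICOM when the header provides PixelSpacing.
#' @return A [gray_image].
#' @seealso [write_pgm()] for the fixture round-trip format.
#' @export
read_image <- function(path, format = c("auto", "dicom", "pgm", "png"),
                       spacing = c(1, 1)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  if (format == "auto") format <- sniff_format(path)
  switch(format,
         dicom = read_dicom(path),
         pgm   = read_pgm(path, spacing = spacing),
         png   = read_png_gray(path, spacing = spacing))
}

sniff_format <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  head <- readBin(con, "raw", 256L)
  if (length(head) >= 2 && rawToChar(head[1:2]) == "P5") return("pgm")
  if (length(head) >= 8 &&
      identical(head[1:8], as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))))
    return("png")
  if (length(head) >= 132 && rawToChar(head[129:132]) == "DICM") return("dicom")
  stop("cannot identify image format of ", path, call. = FALSE)
}

# ---- PGM (binary P5) ---------------------------------------------------

#' Read / write binary PGM (P5)
#'
#' PGM is the plain fixture format of the package: 8-bit for maxval <= 255,
#' 16-bit big-endian otherwise. Round-trips of integer-valued images are
#' exact.
#'
#' @param path file path.
#' @param spacing pixel spacing (mm) to attach on read.
#' @return `read_pgm` returns a [gray_image]; `write_pgm` returns `path`
#'   invisibly.
#' @export
read_pgm <- function(path, spacing = c(1, 1)) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- read_pnm_token(con)
  if (magic != "P5") stop("not a binary PGM (P5) file: ", path, call. = FALSE)
  w <- as.integer(read_pnm_token(con))
  h <- as.integer(read_pnm_token(con))
  maxval <- as.integer(read_pnm_token(con))
  if (is.na(w) || is.na(h) || is.na(maxval) || maxval <= 0)
    stop("corrupt PGM header in ", path, call. = FALSE)
  n <- w * h
  if (maxval < 256) {
    v <- as.integer(readBin(con, "raw", n))
  } else {
    v <- readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "big")
  }
  if (length(v) != n) stop("truncated PGM pixel data in ", path, call. = FALSE)
  gray_image(matrix(v, nrow = h, ncol = w, byrow = TRUE),
             spacing = spacing, id = basename(path))
}

read_pnm_token <- function(con) {
  tok <- character(0); ch <- ""
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0 || !nzchar(ch)) break
    if (ch == "#") { # comment to end of line
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!length(ch) || !nzchar(ch) || ch == "\n") break
      }
      next
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(tok)) break else next
    }
    tok <- c(tok, ch)
  }
  paste(tok, collapse = "")
}

#' @rdname read_pgm
#' @param image a [gray_image] with non-negative integer-valued pixels.
#' @param maxval maximum sample value declared in the header; defaults to
#'   255 or 65535 depending on the data range.
#' @export
write_pgm <- function(image, path, maxval = NULL) {
  stopifnot(inherits(image, "gray_image"))
  px <- round(image$pixels)
  if (min(px) < 0) stop("PGM cannot store negative values", call. = FALSE)
  if (is.null(maxval)) maxval <- if (max(px) <= 255) 255L else 65535L
  if (max(px) > maxval) stop("pixel values exceed maxval", call. = FALSE)
  con <- file(path, "wb"); on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(px), nrow(px), maxval),
            con, eos = NULL)
  v <- as.integer(t(px)) # row-major
  if (maxval < 256) {
    writeBin(as.raw(v), con)
  } else {
    writeBin(v, con, size = 2L, endian = "big")
  }
  invisible(path)
}

# ---- PNG ----------------------------------------------------------------

read_png_gray <- function(path, spacing = c(1, 1)) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L] # first channel of gray+alpha / RGB
  # readPNG scales to [0,1]; recover integer sample values (16-bit assumed
  # when any value is not an 8-bit multiple)
  v255 <- a * 255
  if (max(abs(v255 - round(v255))) < 1e-9) px <- round(v255) else px <- round(a * 65535)
  gray_image(px, spacing = spacing, id = basename(path))
}

#' Write a gray_image as 16-bit grayscale PNG
#'
#' Used for feature maps and fixtures; values are clipped to `[0, 65535]`
#' after optional affine scaling recorded in a JSON sidecar.
#'
#' @param image a [gray_image].
#' @param path output path.
#' @param sidecar if `TRUE`, write `<path>.json` with the original value
#'   range so maps can be decoded back to feature units.
#' @export
write_png16 <- function(image, path, sidecar = FALSE) {
  stopifnot(inherits(image, "gray_image"))
  px <- image$pixels
  rng <- range(px[is.finite(px)])
  if (diff(rng) == 0) scaled <- matrix(0, nrow(px), ncol(px))
  else scaled <- (px - rng[1]) / diff(rng)
  scaled[!is.finite(scaled)] <- 0
  png::writePNG(scaled, path, dpi = NULL)
  if (sidecar) {
    jsonlite::write_json(list(low = rng[1], high = rng[2]),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# ---- masks --------------------------------------------------------------

#' Read / write ROI masks as PGM
#'
#' Masks are stored as 8-bit PGM with 0 = background and 255 = in-ROI.
#'
#' @param path file path.
#' @param source provenance tag for the returned [roi_mask].
#' @export
read_mask <- function(path, source = "manual") {
  img <- read_pgm(path)
  roi_mask(img$pixels > 0, source = source)
}

#' @rdname read_mask
#' @param mask a [roi_mask].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  write_pgm(gray_image(ifelse(mask$mask, 255, 0)), path, maxval = 255L)
}
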