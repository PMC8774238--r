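# Minimal single-frame grayscale DICOM reader.
#
# Scope: little-endian transfer syntaxes (implicit VR 1.2.840.10008.1.2 and
# explicit VR 1.2.840.10008.1.2.1), uncompressed single-frame monochrome
# pixel data, 8/16 bits allocated, signed or unsigned. Stored values are
# mapped to output units through RescaleSlope/RescaleIntercept when present
# (slope 1 / intercept 0 otherwise), which yields Hounsfield units for CT.
# Multi-frame, color, compressed and big-endian files are rejected.

DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_IMPLICIT_LE <- "1.2.840.10008.1.2"

read_dicom <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path, call. = FALSE)
  pos <- 133L

  # ---- file meta group (0002): always explicit VR little endian ----
  transfer_syntax <- DICOM_EXPLICIT_LE
  meta_end <- length(raw)
  while (pos + 8L <= length(raw)) {
    grp <- uint16le(raw, pos)
    if (grp != 0x0002) break
    el <- dicom_element(raw, pos, explicit = TRUE)
    if (el$element == 0x0010)
      transfer_syntax <- trimws(dicom_string(el))
    pos <- el$next_pos
  }

  explicit <- switch(transfer_syntax,
                     "1.2.840.10008.1.2.1" = TRUE,
                     "1.2.840.10008.1.2"   = FALSE,
                     stop("unsupported DICOM transfer syntax: ", transfer_syntax,
                          call. = FALSE))

  tags <- list()
  while (pos + 8L <= length(raw)) {
    el <- dicom_element(raw, pos, explicit = explicit)
    key <- sprintf("%04x,%04x", el$group, el$element)
    tags[[key]] <- el
    pos <- el$next_pos
    if (el$group == 0x7fe0 && el$element == 0x0010) break
  }

  get_str <- function(key) {
    el <- tags[[key]]
    if (is.null(el)) return(NULL)
    trimws(dicom_string(el))
  }
  get_us <- function(key) {
    el <- tags[[key]]
    if (is.null(el)) return(NULL)
    uint16le(el$bytes, 1L)
  }

  rows <- get_us("0028,0010"); cols <- get_us("0028,0011")
  if (is.null(rows) || is.null(cols))
    stop("DICOM file lacks Rows/Columns: ", path, call. = FALSE)
  frames <- get_str("0028,0008")
  if (!is.null(frames) && as.integer(frames) > 1L)
    stop("multi-frame DICOM not supported", call. = FALSE)
  samples <- get_us("0028,0002")
  if (!is.null(samples) && samples != 1L)
    stop("only single-sample (grayscale) DICOM supported", call. = FALSE)
  bits <- get_us("0028,0100"); if (is.null(bits)) bits <- 16L
  pixrep <- get_us("0028,0103"); if (is.null(pixrep)) pixrep <- 0L
  slope <- get_str("0028,1053"); slope <- if (is.null(slope) || !nzchar(slope)) 1 else as.numeric(slope)
  intercept <- get_str("0028,1052"); intercept <- if (is.null(intercept) || !nzchar(intercept)) 0 else as.numeric(intercept)
  spacing_str <- get_str("0028,0030")
  spacing <- if (is.null(spacing_str) || !nzchar(spacing_str)) c(1, 1)
             else as.numeric(strsplit(spacing_str, "\\\\")[[1]][1:2])
  id <- get_str("0008,0018"); if (is.null(id) || !nzchar(id)) id <- basename(path)

  pix <- tags[["7fe0,0010"]]
  if (is.null(pix)) stop("DICOM file has no PixelData: ", path, call. = FALSE)
  n <- rows * cols
  if (bits == 8L) {
    v <- readBin(pix$bytes, "integer", n, size = 1L, signed = pixrep == 1L)
    if (pixrep == 0L) v <- v %% 256L
  } else if (bits == 16L) {
    v <- readBin(pix$bytes, "integer", n, size = 2L,
                 signed = pixrep == 1L, endian = "little")
  } else stop("unsupported BitsAllocated: ", bits, call. = FALSE)
  if (length(v) < n) stop("truncated PixelData in ", path, call. = FALSE)
  v <- v[seq_len(n)]

  # DICOM PixelData is row-major
  gray_image(matrix(v * slope + intercept, nrow = rows, ncol = cols, byrow = TRUE),
             spacing = spacing, id = id)
}

# decode a string element, dropping the NUL/space padding DICOM allows
dicom_string <- function(el) {
  b <- el$bytes[el$bytes != as.raw(0)]
  rawToChar(b)
}

uint16le <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
uint32le <- function(raw, pos) {
  as.integer(raw[pos]) + 256 * as.integer(raw[pos + 1L]) +
    65536 * as.integer(raw[pos + 2L]) + 16777216 * as.integer(raw[pos + 3L])
}

# parse one data element starting at pos; returns group, element, bytes,
# next_pos. Undefined-length (0xFFFFFFFF) items and sequences are rejected:
# they do not occur in the single-frame uncompressed files in scope.
dicom_element <- function(raw, pos, explicit) {
  grp <- uint16le(raw, pos); el <- uint16le(raw, pos + 2L)
  if (explicit) {
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- uint32le(raw, pos + 8L)
      data_pos <- pos + 12L
    } else {
      len <- uint16le(raw, pos + 6L)
      data_pos <- pos + 8L
    }
  } else {
    len <- uint32le(raw, pos + 4L)
    data_pos <- pos + 8L
  }
  if (len == 4294967295)
    stop("undefined-length DICOM element (sequence/encapsulated data) not supported",
         call. = FALSE)
  if (data_pos + len - 1L > length(raw))
    stop("truncated DICOM element", call. = FALSE)
  list(group = grp, element = el,
       bytes = if (len > 0) raw[data_pos:(data_pos + len - 1L)] else raw(0),
       next_pos = data_pos + len)
}
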