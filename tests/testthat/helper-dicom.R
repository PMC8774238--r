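# Minimal explicit-VR little-endian DICOM writer for fixtures (16-bit
# signed pixels, single frame). Kept independent of the package reader.

write_test_dicom <- function(path, stored, slope = NULL, intercept = NULL,
                             spacing = NULL) {
  stored <- as.matrix(stored)
  con <- file(path, "wb")
  on.exit(close(con))
  pad_even <- function(s) if (nchar(s) %% 2 == 1) paste0(s, " ") else s
  el_short <- function(group, element, vr, bytes) {
    writeBin(as.integer(c(group, element)), con, size = 2, endian = "little")
    writeChar(vr, con, eos = NULL)
    writeBin(length(bytes), con, size = 2, endian = "little")
    writeBin(bytes, con)
  }
  el_str <- function(group, element, vr, s) {
    el_short(group, element, vr, charToRaw(pad_even(s)))
  }
  el_us <- function(group, element, v) {
    el_short(group, element, "US", writeBin(as.integer(v), raw(),
                                            size = 2, endian = "little"))
  }
  el_ow <- function(group, element, vals) {
    writeBin(as.integer(c(group, element)), con, size = 2, endian = "little")
    writeChar("OW", con, eos = NULL)
    writeBin(as.raw(c(0, 0)), con) # reserved
    writeBin(length(vals) * 2L, con, size = 4, endian = "little")
    writeBin(as.integer(vals), con, size = 2, endian = "little")
  }

  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  # file meta: transfer syntax only (readers tolerate a minimal meta group)
  ts <- pad_even("1.2.840.10008.1.2.1")
  el_str(0x0002, 0x0010, "UI", ts)

  el_us(0x0028, 0x0002, 1)            # SamplesPerPixel
  el_us(0x0028, 0x0010, nrow(stored)) # Rows
  el_us(0x0028, 0x0011, ncol(stored)) # Columns
  if (!is.null(spacing))
    el_str(0x0028, 0x0030, "DS", paste(spacing, collapse = "\\"))
  el_us(0x0028, 0x0100, 16)           # BitsAllocated
  el_us(0x0028, 0x0103, 1)            # PixelRepresentation: signed
  if (!is.null(intercept)) el_str(0x0028, 0x1052, "DS", as.character(intercept))
  if (!is.null(slope)) el_str(0x0028, 0x1053, "DS", as.character(slope))
  el_ow(0x7fe0, 0x0010, as.vector(t(stored))) # row-major
  invisible(path)
}
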