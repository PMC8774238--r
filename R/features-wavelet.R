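#' Haar wavelet subband energies
#'
#' Dyadic orthonormal Haar decomposition of the ROI bounding box over
#' `scales` levels, reporting the mean squared coefficient (energy) in
#' each of the four subbands LL, LH, HL, HH at every scale — 20 values at
#' the default 5 scales. Wavelet energy quantifies how image variance is
#' distributed across spatial frequency and orientation: smooth,
#' long-range structure loads the deep scales, fine granular texture the
#' shallow ones.
#'
#' Conventions: the first subband letter is the filter applied along
#' rows, the second along columns (`HL` therefore responds to row-wise,
#' i.e. horizontal-stripe, variation). Out-of-ROI pixels in the bounding
#' box are filled with the in-ROI mean before transforming (avoids
#' spurious edge energy), and the box is mean-padded to a multiple of
#' `2^scales`. A subband energy averages only coefficients whose support
#' overlaps the ROI, tracked by 2x2 OR-pooling of the mask across scales.
#'
#' @param q a [normalize_quantize()] result.
#' @param scales number of dyadic scales (default 5).
#' @return Named feature vector `WavEn_<band>_s<scale>` (4 x `scales`
#'   values).
#' @export
wavelet_energies <- function(q, scales = 5L) {
  check_quantized(q)
  scales <- as.integer(scales)
  bands <- c("LL", "LH", "HL", "HH")
  nm <- sort_waven_names(scales)
  m <- q$mask
  rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
  if (diff(rr) < 1L || diff(cc) < 1L) {
    und <- rep("ROI bounding box smaller than 2 px", length(nm)); names(und) <- nm
    return(fv(stats::setNames(rep(NA_real_, length(nm)), nm), und))
  }
  sub <- q$levels[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  msk <- m[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  fill <- mean(sub[msk])
  sub[!msk] <- fill

  # mean-pad to a multiple of 2^scales so every level halves cleanly
  unit <- 2L^scales
  tr <- ceiling(nrow(sub) / unit) * unit
  tc <- ceiling(ncol(sub) / unit) * unit
  X <- matrix(fill, tr, tc); X[seq_len(nrow(sub)), seq_len(ncol(sub))] <- sub
  M <- matrix(FALSE, tr, tc); M[seq_len(nrow(msk)), seq_len(ncol(msk))] <- msk

  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  und <- character(0)
  for (s in seq_len(scales)) {
    dec <- haar_level(X)
    M <- pool_or(M)
    for (b in bands) {
      key <- sprintf("WavEn_%s_s%d", b, s)
      if (any(M)) out[key] <- mean(dec[[b]][M]^2)
      else und[key] <- sprintf("subsampled ROI empty at scale %d", s)
    }
    X <- dec$LL
  }
  fv(out, und)
}

sort_waven_names <- function(scales) {
  as.vector(vapply(seq_len(scales), function(s)
    sprintf("WavEn_%s_s%d", c("LL", "LH", "HL", "HH"), s), character(4)))
}

# one level of the 2D orthonormal Haar transform (rows then columns)
haar_level <- function(X) {
  nr <- nrow(X); nc <- ncol(X)
  odd_r <- seq(1L, nr, 2L); evn_r <- odd_r + 1L
  Lr <- (X[odd_r, , drop = FALSE] + X[evn_r, , drop = FALSE]) / sqrt(2)
  Hr <- (X[odd_r, , drop = FALSE] - X[evn_r, , drop = FALSE]) / sqrt(2)
  odd_c <- seq(1L, nc, 2L); evn_c <- odd_c + 1L
  list(LL = (Lr[, odd_c, drop = FALSE] + Lr[, evn_c, drop = FALSE]) / sqrt(2),
       LH = (Lr[, odd_c, drop = FALSE] - Lr[, evn_c, drop = FALSE]) / sqrt(2),
       HL = (Hr[, odd_c, drop = FALSE] + Hr[, evn_c, drop = FALSE]) / sqrt(2),
       HH = (Hr[, odd_c, drop = FALSE] - Hr[, evn_c, drop = FALSE]) / sqrt(2))
}

# 2x2 logical OR pooling (support overlap of the subsampled mask)
pool_or <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  odd_r <- seq(1L, nr, 2L); odd_c <- seq(1L, nc, 2L)
  (M[odd_r, odd_c, drop = FALSE] | M[odd_r + 1L, odd_c, drop = FALSE] |
   M[odd_r, odd_c + 1L, drop = FALSE] | M[odd_r + 1L, odd_c + 1L, drop = FALSE])
}
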