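#' Run-length matrix features
#'
#' Runs are maximal sequences of equal gray levels along one of the four
#' directions (`H`, `V`, `N` diagonal, `Z` anti-diagonal), truncated at
#' the ROI boundary. With run counts `p(i, r)` (level `i`, length `r`),
#' `Nr` total runs and `Np` in-ROI pixels, the five statistics are
#' short-run emphasis, long-run emphasis, gray-level non-uniformity,
#' run-length non-uniformity and the fraction of the image in runs
#' (`Nr / Np`). Gray-level non-uniformity grows with the number of runs
#' concentrated on few levels and is the run-length counterpart of
#' intensity variability.
#'
#' @param q a [normalize_quantize()] result.
#' @param direction one of `"H"`, `"V"`, `"N"`, `"Z"`.
#' @return Named feature vector `RLM_<dir>_{ShrtREmp, LngREmph, GLevNonU,
#'   RLNonUni, Fraction}`.
#' @export
rlm_features <- function(q, direction = c("H", "V", "N", "Z")) {
  check_quantized(q)
  direction <- match.arg(direction)
  runs <- rlm_runs(q$levels, direction)
  np <- sum(q$mask)
  nr <- length(runs$lengths)
  if (nr == 0L) stop("no runs found (empty mask?)", call. = FALSE)
  rl <- runs$lengths; lv <- runs$values
  vals <- c(
    ShrtREmp = mean(1 / rl^2),
    LngREmph = mean(rl^2),
    GLevNonU = sum(table(lv)^2) / nr,
    RLNonUni = sum(table(rl)^2) / nr,
    Fraction = nr / np
  )
  names(vals) <- paste0("RLM_", direction, "_", names(vals))
  fv(vals)
}

# enumerate maximal runs along a direction; NA (out-of-mask) breaks runs
rlm_runs <- function(L, direction) {
  lines <- switch(direction,
    H = split(L, row(L)),
    V = split(L, col(L)),
    N = split(L, col(L) - row(L)),        # main diagonals, top-left -> bottom-right
    Z = split(L, col(L) + row(L)))        # anti-diagonals
  all_len <- integer(0); all_val <- integer(0)
  for (ln in lines) {
    r <- rle(ln)
    keep <- !is.na(r$values)
    if (any(keep)) {
      all_len <- c(all_len, r$lengths[keep])
      all_val <- c(all_val, r$values[keep])
    }
  }
  list(lengths = all_len, values = all_val)
}
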