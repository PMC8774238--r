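#' Gray-level co-occurrence matrix
#'
#' Joint frequency of gray-level pairs at a fixed pixel offset. The
#' offset is one of the four standard directions `H` (0,1), `V` (1,0),
#' `N` (1,1), `Z` (1,-1) times a distance `d`. Only pairs with both
#' pixels in the ROI are counted (pairs crossing the irregular mask
#' boundary are dropped, not padded); accumulation is symmetric (each
#' pair counted in both orders) and the matrix is normalized to sum 1.
#'
#' @param q a [normalize_quantize()] result.
#' @param direction one of `"H"`, `"V"`, `"N"`, `"Z"`.
#' @param distance integer offset length in pixels (>= 1).
#' @return `ng` x `ng` matrix of pair probabilities summing to 1.
#' @export
glcm <- function(q, direction = c("H", "V", "N", "Z"), distance = 1L) {
  check_quantized(q)
  direction <- match.arg(direction)
  distance <- as.integer(distance)
  if (distance < 1L) stop("distance must be >= 1", call. = FALSE)
  off <- DIRECTION_OFFSETS[[direction]] * distance
  L <- q$levels
  nr <- nrow(L); nc <- ncol(L)
  r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  if (!length(r1) || !length(c1))
    stop(sprintf("offset %s d=%d exceeds image extent", direction, distance),
         call. = FALSE)
  a <- L[r1, c1, drop = FALSE]
  b <- L[r1 + off[1], c1 + off[2], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok))
    stop(sprintf("no valid in-ROI pixel pairs for offset %s d=%d", direction, distance),
         call. = FALSE)
  ai <- a[ok]; bi <- b[ok]
  ng <- q$ng
  counts <- tabulate(ai + (bi - 1L) * ng, nbins = ng * ng) +
    tabulate(bi + (ai - 1L) * ng, nbins = ng * ng)
  P <- matrix(counts / sum(counts), ng, ng)
  P
}

#' Haralick features of a co-occurrence matrix
#'
#' The eleven second-order statistics of the feature set, computed from a
#' normalized GLCM `P` with marginals `p_x`, `p_y` and the sum/difference
#' distributions `p_{x+y}`, `p_{x-y}`:
#' angular second moment, contrast, correlation, sum of squares (variance
#' about the marginal mean), inverse difference moment, sum average, sum
#' variance, sum entropy, entropy, difference variance and difference
#' entropy. All entropies use the natural logarithm with `0 log 0 = 0`.
#'
#' @param P normalized co-occurrence matrix (as from [glcm()]).
#' @param prefix name prefix (e.g. `"GLCM_H_d1_"`).
#' @return Named feature vector of the 11 statistics; `Correlat` is `NA`
#'   with a reason when a marginal is degenerate.
#' @export
glcm_features <- function(P, prefix = "") {
  ng <- nrow(P)
  if (abs(sum(P) - 1) > 1e-8) stop("GLCM must be normalized to sum 1", call. = FALSE)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  lev <- seq_len(ng)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sx <- sqrt(sum((lev - mux)^2 * px)); sy <- sqrt(sum((lev - muy)^2 * py))

  # p_{x+y}(k), k = 2..2*ng; p_{x-y}(k), k = 0..ng-1
  # (every k occurs in a full index grid, so rowsum covers the range)
  psum <- as.numeric(rowsum(c(P), c(i + j)))
  ks <- 2:(2 * ng)
  pd <- as.numeric(rowsum(c(P), c(abs(i - j))))
  kd <- 0:(ng - 1)

  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

  vals <- c(
    AngScMom = sum(P^2),
    Contrast = sum((i - j)^2 * P),
    Correlat = if (sx * sy > 0) (sum(i * j * P) - mux * muy) / (sx * sy) else NA_real_,
    SumOfSqs = sum((i - mux)^2 * P),
    InvDfMom = sum(P / (1 + (i - j)^2)),
    SumAverg = sum(ks * psum),
    SumVarnc = sum((ks - sum(ks * psum))^2 * psum),
    SumEntrp = -sum(xlogx(psum)),
    Entropy  = -sum(xlogx(P)),
    DifVarnc = sum((kd - sum(kd * pd))^2 * pd),
    DifEntrp = -sum(xlogx(pd))
  )
  und <- character(0)
  if (is.na(vals["Correlat"])) und <- c(Correlat = "degenerate marginal (zero variance)")
  names(vals) <- paste0(prefix, names(vals))
  if (length(und)) names(und) <- paste0(prefix, names(und))
  fv(vals, und)
}

# all GLCM features for one quantized ROI under a profile
glcm_all_features <- function(q, distances = 1:5) {
  parts <- list()
  for (dir in names(DIRECTION_OFFSETS)) {
    for (d in distances) {
      prefix <- sprintf("GLCM_%s_d%d_", dir, d)
      parts[[prefix]] <- tryCatch(
        glcm_features(glcm(q, dir, d), prefix = prefix),
        error = function(e) {
          nm <- paste0(prefix, GLCM_FEATURE_NAMES)
          und <- rep(conditionMessage(e), length(nm)); names(und) <- nm
          fv(stats::setNames(rep(NA_real_, length(nm)), nm), und)
        })
    }
  }
  do.call(fv_concat, parts)
}

GLCM_FEATURE_NAMES <- c("AngScMom", "Contrast", "Correlat", "SumOfSqs",
                        "InvDfMom", "SumAverg", "SumVarnc", "SumEntrp",
                        "Entropy", "DifVarnc", "DifEntrp")
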