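# Independent brute-force oracles and fixture builders. These stay
# deliberately naive (double loops, full enumerations) so they cannot
# share bugs with the vectorized implementations they check.

random_quantized_roi <- function(nr, nc, ng = 8L, p_mask = 0.8) {
  lev <- matrix(sample.int(ng, nr * nc, replace = TRUE), nr, nc)
  m <- matrix(stats::runif(nr * nc) < p_mask, nr, nc)
  if (!any(m)) m[1, 1] <- TRUE
  lev[!m] <- NA_integer_
  structure(list(levels = lev, mask = m, ng = as.integer(ng), bits = NA_integer_,
                 norm_stats = c(mu = NA, sigma = NA, low = NA, high = NA),
                 degenerate = FALSE),
            class = "quantized_roi")
}

quantized_from_levels <- function(lev, ng = max(lev, na.rm = TRUE)) {
  lev <- as.matrix(lev)
  storage.mode(lev) <- "integer"
  structure(list(levels = lev, mask = !is.na(lev), ng = as.integer(ng),
                 bits = NA_integer_,
                 norm_stats = c(mu = NA, sigma = NA, low = NA, high = NA),
                 degenerate = FALSE),
            class = "quantized_roi")
}

# O(N^2) pair enumeration GLCM oracle
glcm_oracle <- function(q, dir, d) {
  off <- list(H = c(0, 1), V = c(1, 0), N = c(1, 1), Z = c(1, -1))[[dir]] * d
  L <- q$levels
  P <- matrix(0, q$ng, q$ng)
  for (r in seq_len(nrow(L))) for (cc in seq_len(ncol(L))) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    if (r2 >= 1 && r2 <= nrow(L) && c2 >= 1 && c2 <= ncol(L) &&
        !is.na(L[r, cc]) && !is.na(L[r2, c2])) {
      P[L[r, cc], L[r2, c2]] <- P[L[r, cc], L[r2, c2]] + 1
      P[L[r2, c2], L[r, cc]] <- P[L[r2, c2], L[r, cc]] + 1
    }
  }
  if (sum(P) == 0) stop("oracle: no pairs")
  P / sum(P)
}

# naive GLCM statistics straight from the defining sums
glcm_features_oracle <- function(P) {
  ng <- nrow(P)
  asm <- contrast <- sumsq <- idm <- ent <- corr_num <- 0
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  psum <- rep(0, 2 * ng); pd <- rep(0, ng)
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    p <- P[i, j]
    asm <- asm + p^2
    contrast <- contrast + (i - j)^2 * p
    sumsq <- sumsq + (i - mux)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    if (p > 0) ent <- ent - p * log(p)
    corr_num <- corr_num + i * j * p
    psum[i + j] <- psum[i + j] + p
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p
  }
  ks <- seq_len(2 * ng); kd <- 0:(ng - 1)
  sa <- sum(ks * psum)
  sv <- sum((ks - sa)^2 * psum)
  se <- -sum(ifelse(psum > 0, psum * log(psum), 0))
  mud <- sum(kd * pd)
  dv <- sum((kd - mud)^2 * pd)
  de <- -sum(ifelse(pd > 0, pd * log(pd), 0))
  c(AngScMom = asm, Contrast = contrast,
    Correlat = if (sx * sy > 0) (corr_num - mux * muy) / (sx * sy) else NA_real_,
    SumOfSqs = sumsq, InvDfMom = idm, SumAverg = sa, SumVarnc = sv,
    SumEntrp = se, Entropy = ent, DifVarnc = dv, DifEntrp = de)
}

# naive run enumeration: walk every line pixel by pixel
rlm_oracle <- function(q, dir) {
  off <- list(H = c(0, 1), V = c(1, 0), N = c(1, 1), Z = c(1, -1))[[dir]]
  L <- q$levels
  nr <- nrow(L); nc <- ncol(L)
  starts <- list()
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    pr <- r - off[1]; pc <- cc - off[2]
    before <- pr >= 1 && pr <= nr && pc >= 1 && pc <= nc
    if (!before) starts[[length(starts) + 1]] <- c(r, cc)
  }
  lens <- integer(0); vals <- integer(0)
  for (s in starts) {
    r <- s[1]; cc <- s[2]
    cur <- NA_integer_; len <- 0L
    while (r >= 1 && r <= nr && cc >= 1 && cc <= nc) {
      v <- L[r, cc]
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1L
      } else {
        if (!is.na(cur)) { lens <- c(lens, len); vals <- c(vals, cur) }
        cur <- v; len <- 1L
      }
      r <- r + off[1]; cc <- cc + off[2]
    }
    if (!is.na(cur)) { lens <- c(lens, len); vals <- c(vals, cur) }
  }
  nr_runs <- length(lens)
  np <- sum(q$mask)
  c(ShrtREmp = mean(1 / lens^2), LngREmph = mean(lens^2),
    GLevNonU = sum(table(vals)^2) / nr_runs,
    RLNonUni = sum(table(lens)^2) / nr_runs,
    Fraction = nr_runs / np)
}

# exact two-sided Mann-Whitney p by enumerating all label assignments
mann_whitney_enum <- function(x, y) {
  pool <- c(x, y); nx <- length(x)
  combos <- utils::combn(length(pool), nx)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_of(x, y)
  us <- apply(combos, 2, function(idx) u_of(pool[idx], pool[-idx]))
  mu <- nx * (length(pool) - nx) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# plain named numeric values of a feature vector (drops bookkeeping attrs)
fvals <- function(x) {
  y <- as.numeric(x)
  names(y) <- names(x)
  y
}

# clockwise rotation: element (r, c) -> (c, nr + 1 - r)
rotate90 <- function(m) {
  nr <- nrow(m)
  out <- t(m)
  out[, seq_len(nr)] <- out[, rev(seq_len(nr))]
  out
}
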