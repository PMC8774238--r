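#' Causal autoregressive model of a quantized ROI
#'
#' Least-squares fit of the first-order causal AR model
#' `x(s) - m = th1 (x_left - m) + th2 (x_upright - m) + th3 (x_up - m) +
#' th4 (x_upleft - m) + e(s)`, where `m` is the ROI level mean, over all
#' in-ROI pixels whose four causal neighbours are also in-ROI. `Sigma` is
#' the standard deviation of the residuals. These five parameters
#' summarize local spatial dependence of the texture.
#'
#' @param q a [normalize_quantize()] result.
#' @param min_pixels minimum number of usable pixels (default 20).
#' @return An object of class `pz_ar_fit` with `theta` (length 4),
#'   `sigma`, `se` (standard errors), `n` and `degenerate`.
#' @seealso [ar_features()] for the flat feature-vector form.
#' @export
ar_model <- function(q, min_pixels = 20L) {
  check_quantized(q)
  L <- q$levels
  m <- q$mask
  nr <- nrow(L); nc <- ncol(L)
  if (nr < 2L || nc < 3L)
    stop("ROI grid too small for causal AR neighbourhood", call. = FALSE)
  ri <- 2:nr; ci <- 2:(nc - 1)
  ok <- m[ri, ci] & m[ri, ci - 1] & m[ri - 1, ci + 1] & m[ri - 1, ci] & m[ri - 1, ci - 1]
  n <- sum(ok)
  if (n < min_pixels)
    stop(sprintf("only %d usable pixels for AR fit (need >= %d)", n, min_pixels),
         call. = FALSE)
  mu <- mean(L[m])
  y <- (L[ri, ci])[ok] - mu
  X <- cbind(left    = (L[ri, ci - 1])[ok],
             upright = (L[ri - 1, ci + 1])[ok],
             up      = (L[ri - 1, ci])[ok],
             upleft  = (L[ri - 1, ci - 1])[ok]) - mu
  qrX <- qr(X)
  if (qrX$rank < 4L) {
    # constant / rank-deficient ROI: model undefined, residual scale is 0
    return(structure(list(theta = rep(NA_real_, 4), sigma = stats::sd(y) * 0,
                          se = rep(NA_real_, 4), n = n, degenerate = TRUE),
                     class = "pz_ar_fit"))
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  sigma <- sqrt(mean(res^2))
  df <- n - 4L
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(diag(XtXinv) * s2)
  structure(list(theta = as.numeric(beta), sigma = sigma, se = as.numeric(se),
                 n = n, degenerate = FALSE),
            class = "pz_ar_fit")
}

#' @export
print.pz_ar_fit <- function(x, ...) {
  cat("<causal AR fit>", if (x$degenerate) "(degenerate)" else "", "\n")
  if (!x$degenerate)
    cat(sprintf("  theta: %s\n  sigma: %.4g  (n = %d)\n",
                paste(sprintf("%.4f", x$theta), collapse = ", "), x$sigma, x$n))
  invisible(x)
}

#' @rdname ar_model
#' @return `ar_features` returns the named feature vector
#'   `AR_Teta1..AR_Teta4, AR_Sigma`.
#' @export
ar_features <- function(q, min_pixels = 20L) {
  nm <- c(paste0("AR_Teta", 1:4), "AR_Sigma")
  fit <- tryCatch(ar_model(q, min_pixels = min_pixels), error = function(e) e)
  if (inherits(fit, "error")) {
    und <- rep(conditionMessage(fit), 5); names(und) <- nm
    return(fv(stats::setNames(rep(NA_real_, 5), nm), und))
  }
  vals <- stats::setNames(c(fit$theta, fit$sigma), nm)
  und <- character(0)
  if (fit$degenerate) {
    und <- rep("rank-deficient AR design (constant ROI)", 4)
    names(und) <- nm[1:4]
  }
  fv(vals, und)
}
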