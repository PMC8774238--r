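test_that("Mann-Whitney matches full enumeration on small untied samples", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1) # 2/20 assignments as extreme, both tails
  expect_equal(mann_whitney_enum(c(1, 2, 3), c(4, 5, 6)), 0.1)

  set.seed(14)
  for (rep in 1:10) {
    x <- stats::rnorm(sample(3:5, 1)); y <- stats::rnorm(sample(3:5, 1))
    expect_equal(mann_whitney(x, y)$p, mann_whitney_enum(x, y), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney symmetry identities hold", {
  x <- c(3, 1, 4, 1, 5); y <- c(9, 2, 6, 5, 3, 5)
  a <- mann_whitney(x, y); b <- mann_whitney(y, x)
  expect_equal(a$U + b$U, length(x) * length(y))
  expect_equal(a$p, b$p)
  # identical multisets: U = n_x n_y / 2
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$U, 4.5)
  expect_equal(mann_whitney(rep(1, 4), rep(1, 6))$p, 1)
})

test_that("Bonferroni threshold is alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 19), 0.05 / 19)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 22), 0.05 / 22, tolerance = 1e-12)
  expect_error(bonferroni_threshold(0.05, 0), "m")
})

test_that("ROC handles perfect separation and reports Youden = 1", {
  r <- roc_analysis(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$youden, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_identical(r$direction, "greater_is_positive")
})

test_that("AUC equals U/(n1 n2) from the Mann-Whitney statistic", {
  set.seed(21)
  for (rep in 1:25) {
    scores <- stats::rnorm(30)
    labels <- stats::runif(30) > 0.5
    if (sum(labels) %in% c(0, 30)) next
    if (rep %% 3 == 0) scores <- round(scores) # exercise ties
    u <- mann_whitney(scores[labels], scores[!labels])$U
    auc <- roc_analysis(scores, labels, direction = "greater_is_positive")$auc
    expect_equal(auc, u / (sum(labels) * sum(!labels)), tolerance = 1e-12)
  }
})

test_that("ROC agrees with pROC on AUC and DeLong standard error", {
  skip_if_not_installed("pROC")
  set.seed(31)
  scores <- stats::rnorm(40); labels <- c(rep(1, 18), rep(0, 22))
  scores[labels == 1] <- scores[labels == 1] + 1
  mine <- roc_analysis(scores, labels == 1)
  ref <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(mine$se_delong, sqrt(pROC::var(ref, method = "delong")),
               tolerance = 1e-10)
})

test_that("null scores give AUC centred at one half", {
  set.seed(404)
  aucs <- replicate(200, {
    roc_analysis(stats::rnorm(30), rep(c(TRUE, FALSE), 15),
                 direction = "greater_is_positive")$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 3 * stats::sd(aucs) / sqrt(200))
})

test_that("anti-predictive scores flip direction so AUC >= 0.5", {
  r <- roc_analysis(c(10, 9, 8, 1, 2, 3), c(0, 0, 0, 1, 1, 1))
  expect_identical(r$direction, "lesser_is_positive")
  expect_gte(r$auc, 0.5)
  expect_match(r$criterion, "^<=")
})

test_that("enter model reproduces closed-form least squares on a toy set", {
  X <- cbind(x1 = c(1, 2, 3, 4, 5, 6, 7, 8),
             x2 = c(2, 1, 4, 3, 6, 5, 8, 7))
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  fit <- fit_enter_model(X, labels = y == 1)
  Xd <- cbind(1, X)
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  expect_equal(unname(fit$coefficients$coefficient), unname(beta[2:3, 1]),
               tolerance = 1e-10)
  expect_equal(fit$mcc, sqrt(fit$r2), tolerance = 1e-12)
})

test_that("orthonormal predictors have unit VIF; collinearity is flagged", {
  # centered orthogonal predictors (VIF regressions include an intercept)
  set.seed(90)
  qx <- qr.Q(qr(scale(matrix(stats::rnorm(40), 10, 4), scale = FALSE)))
  colnames(qx) <- paste0("q", 1:4)
  y <- c(rep(0, 5), rep(1, 5))
  fit <- fit_enter_model(qx, labels = y == 1)
  expect_equal(unname(fit$coefficients$vif), rep(1, 4), tolerance = 1e-8)
  # exact collinearity errors with the offending column named
  bad <- cbind(a = stats::rnorm(10), b = 1:10, c = 2 * (1:10))
  expect_error(fit_enter_model(bad, labels = y == 1), "collinearity")
})

test_that("enter model VIF and p-values agree with the reference engines", {
  skip_if_not_installed("car")
  set.seed(61)
  X <- matrix(stats::rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  X[, 2] <- X[, 1] * 0.8 + stats::rnorm(20, 0, 0.4)
  y <- as.numeric(X[, 1] + stats::rnorm(20) > 0)
  fit <- fit_enter_model(X, labels = y == 1)
  ref <- stats::lm(y ~ ., data = data.frame(y = y, X))
  expect_equal(unname(fit$coefficients$vif), unname(car::vif(ref)),
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients$p),
               unname(summary(ref)$coefficients[-1, 4]), tolerance = 1e-12)
})

test_that("outcome exactly linear in predictors gives R2 = MCC = 1", {
  X <- cbind(x = c(0, 0, 0, 1, 1, 1, 0, 1), z = c(0, 1, 0, 1, 0, 1, 1, 0))
  y <- X[, "x"]
  # a perfect fit makes summary.lm warn; the fit itself is the point here
  fit <- suppressWarnings(fit_enter_model(X, labels = y == 1))
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$mcc, 1, tolerance = 1e-12)
  pr <- prediction_roc(fit)
  expect_equal(pr$auc, 1)
})

test_that("fitted values are invariant to affine predictor rescaling", {
  set.seed(71)
  X <- matrix(stats::rnorm(48), 16, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- stats::runif(16) > 0.5
  if (sum(y) < 2 || sum(!y) < 2) y[1:4] <- c(TRUE, TRUE, FALSE, FALSE)
  f1 <- fit_enter_model(X, labels = y)
  X2 <- sweep(sweep(X, 2, c(3, 0.2, 10), "*"), 2, c(-5, 2, 100), "+")
  f2 <- fit_enter_model(X2, labels = y)
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-9)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-12)
})
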