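test_that("Fisher coefficient matches its defining ratio", {
  # mu1 = 0, mu2 = 2, population sigma = 1 per class, equal sizes -> F = 1
  x <- c(-1, 1, 1, 3) # class means 0 and 2, within-variance 1 each
  g <- c(FALSE, FALSE, TRUE, TRUE)
  expect_equal(fisher_score(x, g), 1)
  # identical class distributions -> 0
  expect_equal(fisher_score(c(1, 2, 1, 2), g), 0)
  # affine invariance
  set.seed(8)
  z <- stats::rnorm(20); gg <- rep(c(TRUE, FALSE), 10)
  expect_equal(fisher_score(z, gg), fisher_score(10 * z - 3, gg))
  # zero within-variance: Inf for distinct means, 0 for equal means
  expect_identical(fisher_score(c(0, 0, 1, 1), g), Inf)
  expect_identical(fisher_score(c(1, 1, 1, 1), g), 0)
})

test_that("select_fisher ranks by F and is invariant to rescaling", {
  set.seed(101)
  M <- synthetic_feature_matrix(n_pos = 10, n_neg = 10, n_features = 20,
                                n_effect = 3, effect_size = 3)
  s1 <- select_fisher(M, k = 5)
  expect_equal(nrow(s1$ranked), 5)
  expect_true(all(diff(s1$ranked$score) <= 0)) # descending scores
  expect_true(all(paste0("effect_", 1:3) %in% s1$ranked$feature))
  # per-feature affine rescaling leaves the ranking unchanged
  V2 <- sweep(M$values, 2, stats::runif(20, 0.1, 5), "*")
  V2 <- sweep(V2, 2, stats::rnorm(20), "+")
  M2 <- feature_matrix(V2, ifelse(M$labels, "A", "B"), positive = "A")
  expect_identical(select_fisher(M2, k = 5)$ranked$feature, s1$ranked$feature)
})

test_that("POE is the minimal single-threshold error over both polarities", {
  g <- rep(c(TRUE, FALSE), each = 4)
  expect_equal(poe(c(5, 6, 7, 8, 1, 2, 3, 4), g), 0)   # separable
  expect_equal(poe(c(1, 2, 3, 4, 5, 6, 7, 8), g), 0)   # reversed polarity
  expect_equal(poe(c(1, 2, 3, 5, 4, 6, 7, 8), g), 1 / 8) # one crossover
})

test_that("POE+ACC prefers independent features over redundant duplicates", {
  set.seed(5)
  n <- 20
  g <- rep(c("A", "B"), each = 10)
  f1 <- c(stats::rnorm(10, 2), stats::rnorm(10, 0)) # informative
  f2 <- f1                                          # exact duplicate
  f3 <- c(stats::rnorm(10, 1.8), stats::rnorm(10, 0)) # informative, independent
  M <- feature_matrix(cbind(a_dup = f2, b_orig = f1, c_indep = f3),
                      g, positive = "A")
  sel <- select_poe_acc(M, k = 2)
  # second pick must be the independent feature, not the duplicate
  expect_false(all(c("a_dup", "b_orig") %in% sel$ranked$feature))
  expect_true("c_indep" %in% sel$ranked$feature)
})

test_that("greedy POE+ACC sequence equals exhaustive greedy evaluation", {
  set.seed(33)
  n <- 16
  g <- rep(c("A", "B"), each = 8)
  V <- matrix(stats::rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  V[g == "A", 1] <- V[g == "A", 1] + 2
  V[g == "A", 4] <- V[g == "A", 4] + 1
  M <- feature_matrix(V, g, positive = "A")
  sel <- select_poe_acc(M, k = 3)

  # brute-force the same greedy criterion step by step
  Vs <- scale(M$values)
  poes <- apply(Vs, 2, poe, labels = M$labels)
  chosen <- character(0)
  for (step in 1:3) {
    rem <- setdiff(colnames(Vs), chosen)
    crit <- sapply(rem, function(f) {
      if (!length(chosen)) poes[[f]]
      else poes[[f]] + mean(abs(stats::cor(Vs[, f], Vs[, chosen, drop = FALSE])))
    })
    chosen <- c(chosen, rem[order(crit, rem)][1])
  }
  expect_identical(sel$ranked$feature, chosen)
})

test_that("merging shortlists reproduces union and overlap arithmetic", {
  a <- paste0("f", 1:10)
  b <- c(paste0("f", 8:10), paste0("g", 1:7)) # shares exactly 3
  m <- merge_selections(a, b)
  expect_length(m$unique, 17)
  expect_length(m$overlap, 3)
  expect_identical(merge_selections(a, paste0("h", 1:10))$overlap, character(0))
  expect_length(merge_selections(a, paste0("h", 1:10))$unique, 20)
  expect_length(merge_selections(a, a)$unique, 10)
  expect_length(merge_selections(a, a)$overlap, 10)
})

test_that("selection recovers planted large effects", {
  # Fisher ranks purely by separability, so all five d = 2 effect
  # features must make its top 10. POE+ACC penalizes redundancy: effect
  # features sharing one class signal correlate at r ~ d^2/(d^2 + 4),
  # so the method intentionally passes over some of them once one is in
  # the set — its guarantee is that the error-minimizing first pick is
  # an effect feature and effect features are represented.
  set.seed(2718)
  hits_f <- first_p <- any_p <- logical(100)
  for (r in 1:100) {
    M <- synthetic_feature_matrix(n_pos = 17, n_neg = 19, n_features = 100,
                                  n_effect = 5, effect_size = 2)
    eff <- paste0("effect_", 1:5)
    hits_f[r] <- all(eff %in% select_fisher(M, 10)$ranked$feature)
    sel_p <- select_poe_acc(M, 10)$ranked$feature
    first_p[r] <- sel_p[1] %in% eff
    any_p[r] <- any(eff %in% sel_p)
  }
  expect_gte(mean(hits_f), 0.95)
  expect_gte(mean(first_p), 0.95)
  expect_gte(mean(any_p), 0.95)
})

test_that("constant features are dropped with a warning before selection", {
  V <- cbind(good = stats::rnorm(10), flat = rep(1, 10))
  expect_warning(M <- feature_matrix(V, rep(c("A", "B"), 5)), "constant")
  expect_identical(colnames(M$values), "good")
})
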