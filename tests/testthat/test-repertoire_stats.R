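test_that("the 2x2 chi-square test matches the closed form and base R", {
  res <- chisq_2x2(53, 25412, 21, 23021)
  ref <- stats::chisq.test(matrix(c(53, 25412, 21, 23021), 2, 2,
                                  byrow = TRUE), correct = FALSE)
  expect_equal(res$stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  # identical row proportions give statistic 0, p 1
  flat <- chisq_2x2(10, 10, 10, 10)
  expect_equal(flat$stat, 0)
  expect_equal(flat$p, 1)
  expect_equal(chisq_2x2(20, 40, 10, 20)$stat, 0)
  # invariance under transposition and row/column swaps
  expect_equal(chisq_2x2(53, 25412, 21, 23021)$stat,
               chisq_2x2(53, 21, 25412, 23021)$stat)
  expect_equal(chisq_2x2(53, 25412, 21, 23021)$stat,
               chisq_2x2(21, 23021, 53, 25412)$stat)
  expect_error(chisq_2x2(0, 0, 5, 5), "degenerate")
  yates <- chisq_2x2(12, 5, 3, 14, correction = "yates")
  ref_y <- stats::chisq.test(matrix(c(12, 5, 3, 14), 2, 2, byrow = TRUE))
  expect_equal(yates$p, ref_y$p.value, tolerance = 1e-12)
})

test_that("the family-size-ratio test behaves analytically", {
  expect_equal(family_size_ratio_test(rep(1.16, 10), 1.16)$p, 1)
  expect_error(family_size_ratio_test(rep(2, 10), 1.16), "degenerate")
  set.seed(6)
  ratios <- stats::rnorm(3932, 1.16, 0.3)
  res <- family_size_ratio_test(ratios, 2.52, focal = 53 / 21)
  # separation of ~1.36 at n = 3932, sd 0.3: |t| ~ 280, p astronomically small
  expect_lt(res$p, 1e-10)
  expect_gt(res$focal_quantile, 0.99)
  expect_equal(round(53 / 21, 2), 2.52)
})

test_that("repertoire PCA conserves variance and exposes planted loadings", {
  m <- simulate_repertoire_matrix(5, 8, 16, 3, 9, boost = 6, seed = 2)
  pc <- pca_repertoire(m)
  expect_equal(sum(pc$var_explained), 100, tolerance = 1e-6)
  # perfectly correlated pair of variables: PC1 explains everything
  x <- cbind(a = 1:10, b = 2 * (1:10))
  rownames(x) <- paste0("s", 1:10)
  pc2 <- pca_repertoire(x)
  expect_equal(pc2$var_explained[1], 100, tolerance = 1e-9)
  # scores reproduce pairwise Euclidean distances of centered data
  d_scores <- stats::dist(pc$scores)
  d_data <- stats::dist(scale(m, center = TRUE, scale = FALSE))
  expect_equal(as.vector(d_scores), as.vector(d_data), tolerance = 1e-9)
  # the boosted subfamily drives PC1 in most simulations
  hits <- 0L
  for (s in 1:20) {
    mm <- simulate_repertoire_matrix(5, 8, 16, 3, 9, boost = 10,
                                     seed = 100 + s)
    pcs <- pca_repertoire(mm)
    if (which.max(abs(pcs$loadings[, 1])) == 9) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
  expect_error(pca_repertoire(matrix(1, 5, 3)), "degenerate")
})

test_that("ANOSIM matches vegan, hits rank extremes, and permutes correctly", {
  m <- simulate_repertoire_matrix(5, 8, 16, 3, 9, boost = 8, seed = 3)
  g <- attr(m, "ecotype")
  an <- anosim_test(m, g, n_perm = 999, seed = 2)
  skip_if_not_installed("vegan")
  va <- vegan::anosim(stats::dist(m), g, permutations = 199)
  expect_equal(an$R, unname(va$statistic), tolerance = 1e-12)
  expect_true(an$p > 0 && an$p <= 1)
  # perfect separation: all between-distances exceed within -> R = 1
  sep <- rbind(matrix(0, 3, 2), matrix(100, 3, 2)) +
    matrix(stats::rnorm(12, 0, 0.1), 6, 2)
  rownames(sep) <- paste0("s", 1:6)
  expect_equal(anosim_test(sep, rep(c("x", "y"), each = 3), seed = 1)$R, 1)
  # R invariant to observation order
  perm <- sample(nrow(m))
  an2 <- anosim_test(m[perm, ], g[perm], n_perm = 99, seed = 2)
  expect_equal(an2$R, an$R, tolerance = 1e-12)
  expect_warning(anosim_test(m[1:4, ], c("a", "b", "b", "b"), n_perm = 99),
                 "singleton")
})

test_that("phylogenetic logistic regression reduces to glm on a star tree", {
  set.seed(2)
  n <- 60
  star <- parse_newick(paste0("(", paste(sprintf("t%d:1", 1:n),
                                         collapse = ","), ");"))
  x <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, stats::plogis(-0.5 + 1.2 * x))
  names(x) <- names(y) <- star$tip.label
  fit <- phylo_logistic_regression(star, y, x)
  g <- stats::glm(y ~ x, family = stats::binomial())
  expect_lt(abs(fit$coef[2] / stats::coef(g)[2] - 1), 0.1)
  expect_lt(fit$s2, 0.01)
  expect_true(is.finite(fit$aic))
  expect_false(fit$separation)
})

test_that("phylogenetic logistic regression agrees in direction with binaryPGLMM", {
  set.seed(4)
  tr <- ape::rcoal(20)
  tr$tip.label <- sprintf("s%d", 1:20)
  C <- ape::vcv(tr); C <- C / mean(diag(C)); L <- chol(C)
  x <- drop(t(L) %*% stats::rnorm(20))
  y <- stats::rbinom(20, 1, stats::plogis(1.5 * x))
  names(x) <- names(y) <- tr$tip.label
  fit <- phylo_logistic_regression(tr, y, x)
  pg <- ape::binaryPGLMM(y ~ x, data = data.frame(y = y, x = x,
                                                  row.names = tr$tip.label),
                         phy = tr)
  expect_equal(sign(fit$coef[2]), sign(pg$B[2, 1]))
  expect_gt(fit$coef[2], 0)
})

test_that("degenerate phyloglm inputs are handled explicitly", {
  tr <- balanced_tree(c("a", "b", "c", "d"), brlen = 1)
  y_const <- stats::setNames(c(1, 1, 1, 1), tr$tip.label)
  x <- stats::setNames(1:4, tr$tip.label)
  expect_error(phylo_logistic_regression(tr, y_const, x), "constant")
  # perfectly separating predictor triggers the flagged fallback
  y_sep <- stats::setNames(c(0, 0, 1, 1), tr$tip.label)
  x_sep <- stats::setNames(c(1, 2, 10, 11), tr$tip.label)
  fit <- phylo_logistic_regression(tr, y_sep, x_sep)
  expect_true(fit$separation)
  expect_true(is.finite(fit$aic))
})
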