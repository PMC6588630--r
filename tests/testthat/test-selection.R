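test_that("the GY94 generator has the defining structural properties", {
  set.seed(8)
  for (i in 1:5) {
    kappa <- stats::runif(1, 0.5, 5)
    omega <- stats::runif(1, 0.05, 4)
    f <- as.vector(stats::rgamma(61, 5))
    f <- f / sum(f)
    q <- gy94_rate_matrix(kappa, omega, f)
    expect_lt(max(abs(rowSums(q))), 1e-12)
    # reversibility: pi_i q_ij = pi_j q_ji
    flux <- f * q
    expect_lt(max(abs(flux - t(flux))), 1e-12)
    # mean rate 1 at stationarity
    expect_equal(-sum(f * diag(q)), 1, tolerance = 1e-12)
  }
  # omega = kappa = 1, uniform frequencies: all single-step rates equal
  q1 <- gy94_rate_matrix(1, 1, rep(1 / 61, 61))
  tab <- codon_table()
  off <- q1[tab$ndiff == 1L]
  expect_lt(diff(range(off)), 1e-12)
  expect_true(all(q1[tab$ndiff > 1L] == 0))
  expect_error(gy94_rate_matrix(2, 0.5, rep(1, 61)), "sum")
})

test_that("the pruning likelihood equals brute-force enumeration on small trees", {
  set.seed(9)
  trees <- list(parse_newick("(a:0.2,b:0.4);"),
                parse_newick("((a:0.2,b:0.3):0.1,c:0.25);"),
                parse_newick("((a:0.2,b:0.3):0.1,(c:0.25,d:0.15):0.2);"))
  for (tr in trees) {
    sim <- simulate_codon_alignment(tr, list(list(prop = 1, omega = 0.7)),
                                    kappa = 1.8, n_codons = 3, seed = 31)
    f <- rep(1 / 61, 61)
    pat <- codon_patterns(sim$alignment)
    plan <- chemorep:::tree_plan(tr, pat$labels)
    ll_classes <- chemorep:::class_site_logliks(
      plan, pat$states, 1.8, list(list(prop = 1, omega = 0.7)), f)
    ll_prune <- sum(ll_classes[1, ] * pat$weights)
    ll_brute <- brute_force_codon_loglik(sim$alignment, tr, 1.8, 0.7, f)
    expect_equal(ll_prune, ll_brute, tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to root placement (reversibility)", {
  tr <- parse_newick("((a:0.2,b:0.3):0.1,(c:0.25,d:0.15):0.2);")
  sim <- simulate_codon_alignment(tr, list(list(prop = 1, omega = 0.5)),
                                  kappa = 2, n_codons = 40, seed = 12)
  f <- codon_frequencies(sim$alignment, "F3X4")
  ll_of <- function(tree) {
    pat <- codon_patterns(sim$alignment)
    plan <- chemorep:::tree_plan(tree, pat$labels)
    sum(chemorep:::class_site_logliks(plan, pat$states, 2,
                                      list(list(prop = 1, omega = 0.5)),
                                      f)[1, ] * pat$weights)
  }
  rerooted <- ape::root(ape::unroot(tr), outgroup = "c",
                        resolve.root = TRUE)
  expect_equal(ll_of(tr), ll_of(rerooted), tolerance = 1e-6)
})

test_that("nested site models respect likelihood ordering and recover omega", {
  tr <- parse_newick("((a:0.5,b:0.5):0.3,(c:0.5,d:0.5):0.3);")
  sim <- simulate_codon_alignment(tr, list(list(prop = 1, omega = 0.5)),
                                  kappa = 2, n_codons = 600, seed = 3)
  m0 <- fit_site_model(sim$alignment, tr, "M0", starts = 1, seed = 1)
  expect_true(m0$convergence)
  expect_lt(abs(m0$params[["omega"]] - 0.5), 0.15)
  expect_lt(abs(m0$kappa - 2), 0.5)
  m1a <- fit_site_model(sim$alignment, tr, "M1a", starts = 1, seed = 1,
                        lengths = m0$lengths)
  m2a <- fit_site_model(sim$alignment, tr, "M2a", starts = 1, seed = 1,
                        lengths = m0$lengths)
  expect_gte(m2a$lnL, m1a$lnL - 1e-6)   # nesting
  lrt <- likelihood_ratio_test(m2a, m1a, df = 2)
  expect_gte(lrt$stat, 0)
  expect_true(lrt$p >= 0 && lrt$p <= 1)
})

test_that("LRT p-values match the chi-square closed form", {
  # df = 1: p = erfc(sqrt(x/2)), checked at landmark statistics
  for (x in c(0, 3.84, 5.36, 14.14)) {
    p_closed <- pracma::erfc(sqrt(x / 2))
    lrt <- likelihood_ratio_test(x / 2, 0, df = 1)
    expect_equal(lrt$stat, x, tolerance = 1e-12)
    expect_equal(lrt$p, p_closed, tolerance = 1e-10)
  }
  expect_equal(likelihood_ratio_test(-100, -100, df = 1)$p, 1)
  expect_warning(likelihood_ratio_test(-101, -100, df = 1), "negative")
})

test_that("empirical-Bayes posteriors separate planted positive-selection sites", {
  tr <- balanced_tree(c("a", "b", "c", "d", "e", "f"), brlen = 0.3)
  sim <- simulate_codon_alignment(tr, list(list(prop = 0.9, omega = 0.1),
                                           list(prop = 0.1, omega = 4)),
                                  kappa = 2, n_codons = 300, seed = 5)
  m2a <- fit_site_model(sim$alignment, tr, "M2a", starts = 1, seed = 1)
  for (method in c("NEB", "BEB")) {
    post <- posterior_site_classes(m2a, method)
    expect_true(all(post$posterior >= 0 & post$posterior <= 1))
    pos <- sim$site_class == 2
    expect_gt(mean(post$posterior[pos]), mean(post$posterior[!pos]) + 0.3)
  }
  # NEB agrees with a direct per-site computation from the fit internals
  post <- posterior_site_classes(m2a, "NEB")
  ll <- m2a$site_ll
  direct <- numeric(ncol(ll))
  for (j in seq_len(ncol(ll))) {
    w <- m2a$classes$props * exp(ll[, j] - max(ll[, j]))
    direct[j] <- (w / sum(w))[3]
  }
  expect_equal(post$posterior, direct[m2a$patterns$index], tolerance = 1e-10)
  m1a <- fit_site_model(sim$alignment, tr, "M1a", starts = 1, seed = 1,
                        lengths = m2a$lengths)
  expect_error(posterior_site_classes(m1a), "positive")
})

test_that("branch-site model A detects foreground selection and nests its null", {
  tr <- parse_newick(
    "(((t1:0.2,t2:0.2)n12:0.5,(t3:0.2,t4:0.2)n34:0.2):0.2,(t5:0.3,t6:0.3):0.2);")
  lens <- chemorep:::tree_plan(tr, tr$tip.label)$len
  hits <- 0L
  for (s in 1:8) {
    sim <- simulate_codon_alignment(
      tr, list(list(prop = 0.45, omega = 0.2), list(prop = 0.2, omega = 1),
               list(prop = 0.35, omega = 0.2, omega_fg = 3)),
      kappa = 2, n_codons = 250, seed = 700 + s, foreground = "n12")
    alt <- fit_branch_site(sim$alignment, tr, "n12", null = FALSE,
                           starts = 1, seed = 1, lengths = lens)
    nul <- fit_branch_site(sim$alignment, tr, "n12", null = TRUE,
                           starts = 1, seed = 1, lengths = lens)
    expect_gte(alt$lnL, nul$lnL - 1e-4)
    lrt <- suppressWarnings(likelihood_ratio_test(alt, nul, df = 1))
    if (lrt$p <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 6L)
  tr_full <- parse_newick(
    "(((t1:0.2,t2:0.2)n12:0.5,(t3:0.2,t4:0.2)n34:0.2)nA:0.2,(t5:0.3,t6:0.3)nB:0.2)root;")
  expect_error(fit_branch_site(sim$alignment, tr_full,
                               c(tr_full$tip.label, "n12", "n34", "nA", "nB"),
                               lengths = lens),
               "every branch")
})

test_that("per-category conservation comparison flags planted variability", {
  set.seed(33)
  base <- random_protein(60)
  mk_set <- function(randomize_cols = NULL) {
    aln <- vapply(1:12, function(i) mutate_seq(base, 0.02, AA20), "")
    names(aln) <- paste0("g", 1:12)
    if (!is.null(randomize_cols)) {
      m <- do.call(rbind, strsplit(aln, ""))
      for (j in randomize_cols) m[, j] <- sample(AA20, nrow(m), replace = TRUE)
      aln <- apply(m, 1, paste, collapse = "")
    }
    aln
  }
  cats <- rep(c("proximal", "selectivity", "structural"), each = 20)
  prof_a <- column_information(mk_set(), site_categories = cats)
  prof_b <- column_information(mk_set(randomize_cols = 21:40),
                               site_categories = cats)
  cmp <- compare_site_variability(list(expanded = prof_b,
                                       nonexpanded = prof_a))
  sel <- cmp$tests[cmp$tests$category == "selectivity", ]
  expect_lt(sel$mean_ref, sel$mean_other)
  expect_lt(sel$p, 0.05)
  expect_true(all(cmp$summary >= 0 & cmp$summary <= log2(20)))
  # identical profiles: zero differences, p = 1
  same <- compare_site_variability(list(a = prof_a, b = prof_a))
  expect_true(all(same$tests$p == 1))
  expect_equal(same$tests$mean_ref, same$tests$mean_other)
})
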