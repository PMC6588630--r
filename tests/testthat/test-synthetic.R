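test_that("genome simulation is a pure function of its seed", {
  a <- simulate_receptor_genome(n_intact = 2, n_truncated = 1, n_pseudo = 2,
                                divergence = 0.1, contig_len = 40000, seed = 7)
  b <- simulate_receptor_genome(n_intact = 2, n_truncated = 1, n_pseudo = 2,
                                divergence = 0.1, contig_len = 40000, seed = 7)
  expect_identical(a$contigs, b$contigs)
  expect_identical(a$truth, b$truth)
})

test_that("zero-divergence planted genes translate back to the seed protein", {
  sp <- synthetic_seed_protein(120)
  sim <- simulate_receptor_genome(sp, n_intact = 5, n_truncated = 0,
                                  n_pseudo = 0, divergence = 0,
                                  contig_len = 40000, seed = 3)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    cds <- substr(sim$contigs[[tr$contig]], tr$start, tr$end)
    if (tr$strand == "-") cds <- chemorep:::revcomp(cds)
    prot <- chemorep:::translate_dna(cds)
    expect_identical(sub("\\*$", "", prot), unname(sp))
  }
})

test_that("planted pseudogenes carry a stop or frame disruption on re-translation", {
  sim <- simulate_receptor_genome(n_intact = 0, n_truncated = 0, n_pseudo = 3,
                                  divergence = 0.05, contig_len = 40000,
                                  seed = 11)
  expect_true(all(sim$truth$status == "pseudogene"))
  expect_true(all(nzchar(sim$truth$disruption_kind)))
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    cds <- substr(sim$contigs[[tr$contig]], tr$start, tr$end)
    if (tr$strand == "-") cds <- chemorep:::revcomp(cds)
    prot <- chemorep:::translate_dna(cds)
    internal_stop <- grepl("\\*", substr(prot, 1, nchar(prot) - 1))
    frame_off <- nchar(cds) %% 3 != 0
    expect_true(internal_stop || frame_off)
  }
})

test_that("genome simulation errors when genes cannot fit the contig", {
  expect_error(simulate_receptor_genome(n_intact = 10, contig_len = 5000,
                                        seed = 1), "capacity")
})

test_that("pure birth-death bookkeeping: congruent case and branch identity", {
  st <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  fam <- simulate_family_evolution(st, birth = 0, death = 0, n_root = 1,
                                   seed = 5)
  expect_false(fam$extinct)
  expect_true(all(fam$events$gains == 0) && all(fam$events$losses == 0))
  expect_equal(as.vector(fam$tip_counts), rep(1L, 4))
  gt <- fam$gene_tree
  gt$tip.label <- sub("_g[0-9]+$", "", gt$tip.label)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(gt), ape::unroot(st))), 0)
  # per-branch conservation holds for every replicate of a noisy process
  for (s in 1:25) {
    f <- simulate_family_evolution(st, birth = 0.5, death = 0.4, n_root = 2,
                                   seed = s)
    with(f$events, expect_equal(leaving, entering + gains - losses))
  }
})

test_that("a birth burst on one terminal branch inflates only that species", {
  st <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  nedge <- nrow(st$edge)
  b <- rep(0, nedge)
  a_edge <- which(st$edge[, 2] == which(st$tip.label == "A"))
  b[a_edge] <- 2.0
  counts <- t(vapply(1:200, function(s) {
    f <- simulate_family_evolution(st, birth = b, death = 0, n_root = 1,
                                   seed = s)
    as.vector(f$tip_counts)
  }, numeric(4)))
  colnames(counts) <- st$tip.label
  # expected copies at A: e^(b t) = e^2 ~ 7.4; other species keep 1 copy
  expect_gt(mean(counts[, "A"]), 4)
  expect_lt(abs(mean(counts[, "A"]) - exp(2)), 2.5)
  expect_true(all(counts[, c("B", "C", "D")] == 1))
})

test_that("codon simulation: zero-length tree gives identical sequences", {
  tr <- parse_newick("(a:0,b:0);")
  sim <- simulate_codon_alignment(tr, list(list(prop = 1, omega = 1)),
                                  kappa = 1, n_codons = 50, seed = 2)
  expect_identical(sim$alignment[["a"]], sim$alignment[["b"]])
  tr_nolen <- ape::read.tree(text = "(a,b);")
  expect_error(simulate_codon_alignment(tr_nolen,
                                        list(list(prop = 1, omega = 1))),
               "branch length")
})

test_that("repertoire and expression generators are deterministic and validated", {
  m1 <- simulate_repertoire_matrix(seed = 9)
  m2 <- simulate_repertoire_matrix(seed = 9)
  expect_identical(m1, m2)
  expect_error(simulate_repertoire_matrix(n_subfamilies = 1), "degenerate")
  expect_error(simulate_repertoire_matrix(boost = 0.5), "boost")
  e1 <- simulate_expression_counts(n_genes = 100, seed = 4)
  e2 <- simulate_expression_counts(n_genes = 100, seed = 4)
  expect_identical(e1$counts, e2$counts)
  expect_error(simulate_expression_counts(dispersion = 0), "dispersion")
})

test_that("null expression simulation yields uniform rank-sum p-values", {
  sim <- simulate_expression_counts(n_genes = 2000, n_per_group = 5,
                                    de_fraction = 0, seed = 8)
  fpkm <- compute_fpkm(sim$counts, sim$lengths)
  p <- apply(fpkm, 1, function(v) {
    stats::wilcox.test(v[sim$condition == "before"],
                       v[sim$condition == "after"], exact = FALSE)$p.value
  })

  # the rank-sum null at n = 5 vs 5 is discrete (14 attainable p-values), so
  # uniformity is checked through rejection rates: valid (never above the
  # nominal level by more than Monte Carlo noise) and non-degenerate
  for (alpha in c(0.05, 0.2, 0.5)) {
    rej <- mean(p <= alpha)
    expect_lte(rej, alpha + 0.02)
    expect_gte(rej, alpha / 3)
  }
})
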