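test_that("Poisson distances follow the closed form with pairwise deletion", {
  a <- strrep("A", 100)
  b <- paste0(strrep("A", 90), strrep("C", 10))
  d <- poisson_distance_matrix(c(x = a, y = b))
  expect_equal(d["x", "y"], -log(0.9), tolerance = 1e-12)
  expect_equal(d["x", "x"], 0)
  expect_equal(d, t(d))
  # gap columns are deleted pairwise: 10 mismatches hidden behind gaps
  bg <- paste0(strrep("A", 90), strrep("-", 10))
  dg <- poisson_distance_matrix(c(x = a, y = bg))
  expect_equal(dg["x", "y"], 0)
  # saturated pair flagged
  ds <- poisson_distance_matrix(c(x = strrep("A", 10), y = strrep("C", 10)))
  expect_true(attr(ds, "saturated")["x", "y"])
  expect_true(is.infinite(ds["x", "y"]))
  # no shared non-gap columns is an error
  expect_error(poisson_distance_matrix(c(x = "AA--", y = "--CC")),
               "incomparable")
})

test_that("neighbor-joining recovers additive trees exactly", {
  tr <- parse_newick("(((a:1,b:2):1,(c:1.5,d:1):2):1,(e:2,f:1):1.5);")
  dm <- ape::cophenetic.phylo(tr)
  nj <- nj_tree(dm)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), nj)), 0)
  # three taxa: branch lengths solve the three-point equations
  dm3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(dm3)
  pend <- stats::setNames(t3$edge.length[t3$edge[, 2] <= 3],
                          t3$tip.label[t3$edge[t3$edge[, 2] <= 3, 2]])
  expect_equal(unname(pend[c("a", "b", "c")]), c(1, 2, 4), tolerance = 1e-9)
  # taxon-order invariance of the unrooted topology
  perm <- sample(rownames(dm))
  nj2 <- nj_tree(dm[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(nj, nj2)), 0)
  # saturated entries refused unless explicitly allowed
  dms <- dm
  dms[1, 2] <- dms[2, 1] <- Inf
  expect_error(nj_tree(dms), "saturated")
  expect_s3_class(nj_tree(dms, allow_saturated = TRUE), "phylo")
})

test_that("bootstrap supports behave at the boundaries and are deterministic", {
  set.seed(3)
  base1 <- random_protein(150)
  base2 <- random_protein(150)
  aln <- c(a1 = mutate_seq(base1, 0.05, AA20), a2 = mutate_seq(base1, 0.05, AA20),
           a3 = mutate_seq(base1, 0.05, AA20), b1 = mutate_seq(base2, 0.05, AA20),
           b2 = mutate_seq(base2, 0.05, AA20))
  one <- suppressMessages(bootstrap_support(aln, n_reps = 1, seed = 4))
  expect_true(all(attr(one, "support") %in% c(0, 100)))
  b1 <- suppressMessages(bootstrap_support(aln, n_reps = 30, seed = 9))
  b2 <- suppressMessages(bootstrap_support(aln, n_reps = 30, seed = 9))
  expect_identical(attr(b1, "support"), attr(b2, "support"))
  # the deep split between the two sequence families is well supported
  splits <- chemorep:::tree_splits(b1)
  deep <- vapply(splits, function(s)
    setequal(s, c("a1", "a2", "a3")) || setequal(s, c("b1", "b2")),
    logical(1))
  expect_true(any(deep))
  expect_true(all(attr(b1, "support")[deep] >= 95))
})

test_that("subfamily assignment follows the smallest pure clade with fallbacks", {
  set.seed(13)
  base1 <- random_protein(200)
  base2 <- mutate_seq(base1, 0.5, AA20)   # a related, clearly distinct subfamily
  refs <- c(r1 = mutate_seq(base1, 0.03, AA20), r2 = mutate_seq(base1, 0.04, AA20),
            r3 = mutate_seq(base2, 0.03, AA20), r4 = mutate_seq(base2, 0.04, AA20))
  labels <- c("9", "9", "3", "3")
  q <- stats::setNames(mutate_seq(base1, 0.08, AA20), "q")
  expect_equal(suppressMessages(assign_subfamily(q, refs, labels)), "9")
  # a reference used as its own query keeps its label
  expect_equal(assign_subfamily(stats::setNames(refs["r3"], "r3"), refs,
                                labels), "3")
  # equidistant query between two single-member subfamilies is unassigned
  refs2 <- c(ra = "AAAAAAAAAA", rb = "CCCCCCCCCC")
  qq <- stats::setNames("AAAAACCCCC", "q")
  expect_true(is.na(assign_subfamily(qq, refs2, c("1", "2"))))
  expect_error(assign_subfamily(qq, character(0), character(0)), "empty")
})

test_that("column information content matches hand-computed entropies", {
  ic <- column_information(c(a = "AC", b = "AC", c = "AA", d = "AC"))
  expect_equal(ic$ic[1], log2(20), tolerance = 1e-12)
  h <- -(0.25 * log2(0.25) + 0.75 * log2(0.75))
  expect_equal(ic$ic[2], log2(20) - h, tolerance = 1e-12)
  # column half A half C carries log2(20) - 1 bits
  ic2 <- column_information(c(a = "A", b = "A", c = "C", d = "C"))
  expect_equal(ic2$ic[1], log2(20) - 1, tolerance = 1e-12)
  # uniform column over all 20 residues carries 0 bits
  ic3 <- column_information(stats::setNames(AA20, paste0("s", 1:20)))
  expect_equal(ic3$ic[1], 0, tolerance = 1e-12)
  # all-gap column flagged, not scored
  ic4 <- column_information(c(a = "A-", b = "A-"))
  expect_true(ic4$all_gap[2])
  expect_true(is.na(ic4$ic[2]))
  # category labels attach and bound holds
  ic5 <- column_information(c(a = "ARN", b = "ARD"),
                            site_categories = c("proximal", "selectivity",
                                                "other"))
  expect_equal(ic5$category, c("proximal", "selectivity", "other"))
  expect_true(all(ic5$ic >= 0 & ic5$ic <= log2(20) + 1e-12))
})
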