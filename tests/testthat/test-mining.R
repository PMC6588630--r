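test_that("an identical planted copy of a query is found as a strong self-hit", {
  set.seed(21)
  q <- c(myq = random_protein(150))
  cds <- chemorep:::back_translate(q[[1]])
  contig <- paste0(random_dna_str(3000), cds, random_dna_str(3000))
  hits <- search_homologs(c(ctg = contig), q)
  expect_gt(nrow(hits), 0)
  best <- hits[which.max(hits$bitscore), ]
  expect_gte((best$qend - best$qstart + 1) / nchar(q), 0.95)
  expect_lte(best$evalue, 1e-10)
  expect_equal(best$strand, "+")
  expect_equal(best$sstart, 3001)
})

test_that("a reverse-complement planted gene is reported on the minus strand with forward coordinates", {
  set.seed(22)
  q <- c(myq = random_protein(150))
  cds <- chemorep:::back_translate(q[[1]])
  contig <- paste0(random_dna_str(2000), chemorep:::revcomp(cds),
                   random_dna_str(2000))
  hits <- search_homologs(c(ctg = contig), q)
  expect_gt(nrow(hits), 0)
  best <- hits[which.max(hits$bitscore), ]
  expect_equal(best$strand, "-")
  expect_lte(best$sstart, best$send)
  expect_equal(best$sstart, 2001)
})

test_that("random sequence yields no hits at the e-value cutoff", {
  q <- c(myq = random_protein(250, seed = 30))
  n_hit <- 0L
  for (s in 1:20) {
    contig <- random_dna_str(20000, seed = 400 + s)
    h <- search_homologs(c(ctg = contig), q, e_cutoff = 1e-10)
    n_hit <- n_hit + nrow(h)
  }
  expect_equal(n_hit, 0L)
})

test_that("hit merging follows overlap, strand, and length rules", {
  mk <- function(sstart, send, strand, bit = 100) {
    data.frame(qseqid = "q", sseqid = "ctg", pident = 90, length = 100,
               mismatch = 0, gapopen = 0, qstart = 1, qend = 100,
               sstart = sstart, send = send, evalue = 1e-30, bitscore = bit,
               strand = strand, stringsAsFactors = FALSE)
  }
  merged <- merge_hits(rbind(mk(100, 400, "+"), mk(350, 800, "+", 120)))
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(100, 800))
  two <- merge_hits(rbind(mk(100, 400, "+"), mk(350, 800, "-")))
  expect_equal(nrow(two), 2L)
  expect_equal(nrow(merge_hits(mk(100, 249, "+"))), 0L)  # < 200 nt dropped
  # merged loci are pairwise disjoint per contig and strand
  set.seed(5)
  hits <- do.call(rbind, lapply(1:40, function(i)
    mk(s <- sample(1:50000, 1), s + sample(200:900, 1),
       sample(c("+", "-"), 1))))
  loci <- merge_hits(hits, max_gap = 1000)
  for (str in c("+", "-")) {
    l <- loci[loci$strand == str, ]
    if (nrow(l) > 1) {
      l <- l[order(l$start), ]
      expect_true(all(l$start[-1] > l$end[-nrow(l)]))
    }
  }
})

test_that("gene models recover planted status, disruptions, and coverage", {
  q <- synthetic_seed_protein()
  sim <- simulate_receptor_genome(q, n_intact = 1, n_truncated = 1,
                                  n_pseudo = 2, divergence = 0.1,
                                  contig_len = 30000, seed = 31)
  res <- mine_receptors(sim$contigs, q, flank = 3000)
  ann <- res$annotations
  expect_equal(nrow(ann), nrow(sim$truth))
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    j <- which(ann$contig == tr$contig & ann$start <= tr$end &
                 ann$end >= tr$start)
    expect_length(j, 1L)
    expect_equal(ann$status[j], tr$status)
    expect_equal(ann$strand[j], tr$strand)
    if (tr$status == "intact") {
      expect_gte(ann$coverage[j], 0.95)
      expect_equal(ann$n_disruptions[j], 0L)
    }
    if (tr$status == "truncated") expect_lt(ann$coverage[j], 1)
    if (tr$status == "pseudogene" && tr$disruption_kind == "nonsense") {
      d <- res$models[[j]]$disruptions
      genomic_truth <- if (tr$strand == "+") tr$start + tr$disruption_pos - 1
        else tr$end - tr$disruption_pos + 1
      expect_true(any(d$kind == "nonsense" &
                        abs(d$genomic_pos - genomic_truth) <= 4))
    }
  }
})

test_that("a planted nonsense mutation is located within one codon", {
  q <- synthetic_seed_protein(250, seed = 77)
  found <- 0L
  checked <- 0L
  for (s in 1:6) {
    sim <- simulate_receptor_genome(q, n_intact = 0, n_truncated = 0,
                                    n_pseudo = 1, divergence = 0.08,
                                    contig_len = 15000, seed = 600 + s)
    tr <- sim$truth[1, ]
    if (tr$disruption_kind != "nonsense") next
    checked <- checked + 1L
    res <- mine_receptors(sim$contigs, q, flank = 2000)
    d <- res$models[[1]]$disruptions
    genomic_truth <- if (tr$strand == "+") tr$start + tr$disruption_pos - 1
      else tr$end - tr$disruption_pos + 1
    if (any(d$kind == "nonsense" & abs(d$genomic_pos - genomic_truth) <= 4)) {
      found <- found + 1L
    }
  }
  expect_gte(checked, 1L)
  expect_equal(found, checked)
})

test_that("classification is a total function with the documented rules", {
  mk_model <- function(coverage, n_disrupt, edge) {
    structure(list(coverage = coverage,
                   disruptions = data.frame(kind = rep("frameshift", n_disrupt),
                                            cds_pos = seq_len(n_disrupt),
                                            genomic_pos = seq_len(n_disrupt)),
                   contig_edge = edge), class = "gene_model")
  }
  expect_equal(classify_gene(mk_model(1.0, 0, FALSE)), "intact")
  expect_equal(classify_gene(mk_model(1.0, 1, FALSE)), "pseudogene")
  expect_equal(classify_gene(mk_model(0.6, 0, TRUE)), "truncated")
  expect_equal(classify_gene(mk_model(0.95, 0, TRUE)), "truncated")
  expect_equal(classify_gene(mk_model(0.2, 2, TRUE)), "pseudogene")
  for (cov in c(0, 0.5, 0.9, 1)) {
    for (nd in 0:1) {
      for (edge in c(TRUE, FALSE)) {
        expect_true(classify_gene(mk_model(cov, nd, edge)) %in%
                      c("intact", "truncated", "pseudogene"))
      }
    }
  }
})

test_that("family verification accepts homologs, rejects decoys, rejects ties", {
  set.seed(41)
  target <- random_protein(200)
  decoy <- random_protein(200)
  refs <- c(t1 = target, d1 = decoy)
  labels <- c("target", "decoy")
  mutant <- mutate_seq(target, 0.1, AA20)
  expect_true(as.logical(verify_family_membership(mutant, refs, labels)))
  expect_false(as.logical(verify_family_membership(
    mutate_seq(decoy, 0.1, AA20), refs, labels)))
  # exact tie between a target and a decoy copy is rejected
  refs_tie <- c(t1 = target, d1 = target)
  expect_false(as.logical(verify_family_membership(target, refs_tie,
                                                   c("target", "decoy"))))
  expect_error(verify_family_membership(target, character(0), character(0)),
               "empty")
})
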