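# chemorep

Comparative analysis of chemoreceptor gene-family repertoires in fish
genomes, built around the OlfC (vomeronasal type-2 receptor-like, V2R-like)
family and its association with the pheromone-elicited fright reaction of
ostariophysan fishes.

Ostariophysans detect a skin-derived alarm substance by smell; the receptor
candidates are the OlfC genes, whose water-soluble-ligand binding and
explosive family dynamics make repertoire size and composition natural
comparative variables. chemorep implements the full analytical chain such a
study needs, for anyone asking the same questions of any receptor family:

- **Genome mining** — six-frame seeded homology search (or imported hit
  tables), hit merging, frame-aware protein-to-DNA gene models, and
  classification of each locus as **intact** (complete ORF and coding
  region), **truncated** (intact frame, incomplete coding region), or
  **pseudogene** (nonsense/frameshift-disrupted), with family verification
  against a target + decoy panel.
- **Phylogenetics** — Poisson protein distances `d = −ln(1 − p)` with
  pairwise gap deletion, neighbor-joining trees, bootstrap supports,
  subfamily assignment, and per-column conservation (information content
  `IC = log2 20 − H` bits).
- **Duplication–loss reconciliation** — LCA-mapping parsimony of a gene
  tree against a species tree: per-branch gains and losses, ancestral copy
  numbers obeying `child = parent + gains − losses`, minimum-cost rooting.
- **Gene conversion** — Sawyer-style maximal identity fragments over
  polymorphic sites with a joint column-permutation test (per-pair and
  global p-values).
- **Repertoire–ecotype association** — uncorrected 2×2 Pearson χ²,
  one-sample family-size-ratio t test, centered PCA, Clarke's ANOSIM
  `R = (r̄_B − r̄_W)/(n(n−1)/4)` on Euclidean distances, and phylogenetic
  logistic regression of a binary ecotype (Laplace ML of a logistic GLMM
  with Brownian phylogenetic random effect; F-referenced LRT slope test).
- **Selection** — GY94 codon models: site models M0/M1a/M2a/M7/M8/M8a,
  branch-site model A and its null, likelihood-ratio tests, and NEB/BEB
  identification of positively selected sites.
- **Expression statistics** — FPKM, FPKM > 1-in-half-the-samples activity
  filtering, TMM scaling factors, and rank-sum contrasts of expression
  levels and before/after absolute changes across gene sets.
- **Synthetic data with ground truth** — generators for genomes with
  planted I/T/P genes, birth–death gene families, codon alignments with ω
  site classes, repertoire matrices with a boosted subfamily, and
  negative-binomial expression counts; every generator is a pure function
  of its seed and returns the planted truth.

## Worked example

Mine a synthetic genome with known planted genes, then compute the study's
desk statistics:

```r
library(chemorep)

sim <- simulate_receptor_genome(n_intact = 2, n_truncated = 1, n_pseudo = 1,
                                divergence = 0.1, contig_len = 30000, seed = 42)
res <- mine_receptors(sim$contigs, synthetic_seed_protein(), flank = 3000)
res$annotations[, c("contig", "strand", "start", "end", "status", "coverage")]
#>       contig strand start   end     status coverage
#> 1 ctg_trunc1      -     1   582  truncated   0.6467
#> 2       ctg1      +  7393  8292     intact   1.0000
#> 3       ctg1      + 14855 15754     intact   1.0000
#> 4       ctg1      - 22530 23431 pseudogene   1.0000
```

All four planted genes are recovered with their planted status: the
truncated gene abuts its contig edge (coverage 0.65 of the query), the two
intact genes cover the query completely with no disruptions, and the
pseudogene's planted frame disruption is detected despite full coverage.

```r
chi <- chisq_2x2(53, 25412, 21, 23021)   # intact OlfC vs rest: zebrafish, cave fish
sprintf("chi-square = %.2f, p = %.6f", chi$stat, chi$p)
#> "chi-square = 10.87, p = 0.000978"

lrt <- likelihood_ratio_test(-36477.91, -36484.98, df = 1)  # M8 vs M8a lnL
sprintf("2*delta-lnL = %.2f, p = %.2e", lrt$stat, lrt$p)
#> "2*delta-lnL = 14.14, p = 1.70e-04"

m <- simulate_repertoire_matrix(5, 8, 16, 3, 9, boost = 10, seed = 1)
an <- anosim_test(m, attr(m, "ecotype"), n_perm = 999, seed = 1)
sprintf("ANOSIM R = %.3f, p = %.3f", an$R, an$p)
#> "ANOSIM R = 1.000, p = 0.001"
```

The χ² p-value (0.000978) is the significance of the receptor family's
genomic over-representation in a fright-reaction species versus its closest
non-fright relative; the likelihood-ratio statistic 14.14 is the site-model
evidence for a positive-selection class recomputed from the reported model
log-likelihoods; the ANOSIM R of 1.0 on a strongly boosted synthetic
repertoire indicates complete between-ecotype separation of subfamily
profiles.

A full synthetic study (four genomes → mining → repertoire statistics →
reconciliation → conversion/selection/expression) runs from one seeded
configuration:

```r
report <- run_pipeline(demo_config(out_dir = "run1", seed = 1))
```

Outputs are plain files (FASTA, GFF-lite, Newick, TSV) plus a
`manifest.json` of parameters, seeds, and checksums; identical
configurations give identical manifests.

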