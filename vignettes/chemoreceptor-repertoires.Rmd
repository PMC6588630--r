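---
title: "Models and methods behind chemorep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chemorep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemorep)
```

## The scientific problem

Ostariophysan fishes mount a pheromone-elicited fright reaction: an alarm
substance released from damaged skin triggers defensive behavior in
conspecifics, detected by smell. The receptor candidates are the OlfC genes
(vomeronasal type-2 receptor-like, V2R-like), a large and volatile gene
family in teleost genomes. Comparative questions about such a family have a
standard analytical shape:

1. **Mine** each genome for family members and classify every locus as
   intact (complete open reading frame and coding region), truncated
   (intact frame, incomplete coding region), or pseudogene (frame disrupted
   by nonsense or frameshift mutations).
2. **Place** the intact repertoire on a gene tree, assign subfamilies, and
   **reconcile** the gene tree against the species tree to localize gains
   and losses on branches.
3. Test for **gene conversion** among close paralogs (concerted evolution
   can mimic recent duplication).
4. Ask whether repertoire composition **associates with ecotype** (here:
   having vs lacking the fright reaction), with ordination, ANOSIM, and
   phylogenetic logistic regression.
5. Ask whether expanded subfamilies show **positive selection** (codon
   site and branch-site models) and distinctive **expression dynamics**.

chemorep implements this pipeline end to end, with every stochastic input
replaceable by a synthetic generator that carries machine-readable ground
truth, so each inference layer can be scored against planted answers.

## Synthetic data: what it emulates, what it does not

`simulate_receptor_genome()` plants back-translated, point-mutated copies of
a seed protein in random background sequence. Back-translation picks codons
uniformly per amino acid, deliberately avoiding codon bias so that mining
sensitivity is not confounded by composition. Pseudogenes receive exactly
one disruption: a nonsense substitution (a sense codon one substitution away
from a stop) or a 1–2 bp indel, positioned in the central 70% of the CDS so
that it falls inside any reasonable alignment. Truncated genes are emitted
on their own contigs with the gene cut by the contig boundary, which is how
assembly fragmentation produces them in real data. Planted genes are spaced
at least 6 kb apart — beyond the default 5 kb hit-merge distance — so that
distinct loci remain distinct; real tandem arrays tighter than the merge
distance would be fused by this (and any) envelope-merging pipeline. Not
emulated: introns (mining is intronless by design), repeat families,
base-composition heterogeneity, and sequencing error. Passing tests
therefore demonstrate correctness of the inference machinery on clean
assemblies, not robustness to every artifact of real ones.

`simulate_family_evolution()` runs independent per-lineage birth–death
processes along each species-tree branch (rates per lineage per unit branch
length, optionally branch-specific) and records realized duplication and
loss counts per branch; the returned gene tree contains only surviving
lineages, with duplication nodes at their event times. The bookkeeping
identity `leaving = entering + gains − losses` holds on every branch by
construction and is asserted in tests.

`simulate_codon_alignment()`, `simulate_repertoire_matrix()`, and
`simulate_expression_counts()` provide codon alignments with ω site classes
(optionally branch-specific), Poisson count matrices with a group effect
concentrated in one subfamily, and negative-binomial expression counts with
planted fold changes. All generators are pure functions of their seed.

## Mining

The search stage is a self-contained translated homology search: six-frame
translation, exact amino-acid 4-mer seeding, seed clustering, and gapped
local extension under BLOSUM62 (gap open 11, extend 1). E-values use the
Karlin–Altschul form with fixed gapped parameters (λ = 0.267, K = 0.041)
and the query × genome search space; the default cutoff is 1e-10.
Pre-computed tabular hits from an external search can be imported instead —
the stage's contract is "a filtered hit table", not a particular binary.

Hits on the same contig and strand within 5 kb are merged into loci;
envelopes shorter than 200 nt are discarded. Each locus is extended by
10 kb per side (clipped at contig ends) and the best query is aligned to
the extended DNA by a frame-aware local dynamic program (Rcpp): one residue
may consume 2, 3, or 4 nt, with frame switches charged 15 score units and
reported as frameshift disruptions; in-frame stops score −5 and are
reported as nonsense disruptions. Frame switches closer than 3 codons merge
into one event, since a 2-bp indel is realized by two 1-bp moves in the DP.
Classification: any disruption → pseudogene; else coverage ≥ 0.9 of the
query and no contig-edge contact → intact; else truncated. The completeness
threshold and all distances are configurable; defaults are logged in GFF
output headers. Family verification accepts a protein only when its single
best local-alignment hit in a labeled panel (targets plus decoys) is
target-family; ties are conservatively rejected.

## Distance phylogenetics

Poisson protein distances `d = −ln(1 − p)` are computed with pairwise
deletion of gap sites; pairs with `p ≥ 1` are flagged saturated and refused
by the tree builder unless explicitly allowed (they are then set to twice
the largest finite distance). Neighbor-joining is delegated to `ape::nj()`
with negative branch lengths clamped to zero. Bootstrap support resamples
alignment columns and counts bipartition recovery. Subfamily assignment
takes the smallest tree split containing the query whose references are
single-subfamily; tied splits and no-split cases fall back to the nearest
reference by distance, and remaining ties are unassigned. Column
conservation is Shannon information content, `IC = log2(20) − H`, over
non-gap residues without small-sample correction (a correction is not part
of the entropy definition used here and can be applied downstream if
desired). Maximum-likelihood tree search is intentionally out of scope; an
externally built ML tree can be imported wherever a tree is consumed.

## Duplication–loss reconciliation

`reconcile_dl()` implements LCA-mapping parsimony: each gene node maps to
the LCA of its children's mappings; a node is a duplication iff a child
maps to the same species node (equivalently, iff it maps at or above its
children's LCA with overlap). Losses are read off the species path each
gene lineage traverses: a lineage crossing a speciation without descendants
in one child lineage is a loss on that child branch. Gains are assigned to
the branch above their mapped node. Copy numbers at species nodes are
counted directly from lineage crossings, so the per-branch identity
`child = parent + gains − losses` is a genuine check, not a definition.
Events are counted at and below the gene root's mapping (the standard
convention; nothing is inferred about branches the family predates).
Duplication and loss costs default to 1/1 and are configurable;
`rooting = "minimize"` tries every rooting of the unrooted gene tree and
keeps the minimum cost, breaking ties by the lexicographically smallest
root split. Tests verify cost-optimality against exhaustive enumeration
over all valid mappings.

## Gene conversion

Sawyer's framework: the alignment is condensed to polymorphic, gap-free
columns; for each sequence pair the statistic is the maximal run of
identical polymorphic sites (mismatch-free fragments; a finite mismatch
penalty with maximal-scoring segments is available). Significance comes
from jointly permuting the condensed column order — mismatch counts per
pair are preserved while positional clustering is destroyed — with add-one
p-values, and the global p-value is the permutation distribution of the
maximum across pairs (exact under the shared null, unlike Bonferroni).
For a two-sequence alignment every whole-alignment polymorphic column is a
pair mismatch, so runs are scored over all gap-free columns instead; the
permutation null remains exact.

## Repertoire–ecotype association

The 2×2 test is uncorrected Pearson chi-square (the continuity correction
is available by flag). The family-size-ratio test is a two-sided one-sample
t test, reporting additionally where a focal family's ratio sits in the
empirical ratio distribution. PCA is centered, unscaled SVD on counts or
row proportions. ANOSIM uses Clarke's statistic on globally ranked
Euclidean distances, `R = (r̄_between − r̄_within) / (n(n−1)/4)`, with
label-permutation p-values (999 permutations by default, seed mandatory);
this normalization bounds R in [−1, 1] and matches the classical
definition.

Phylogenetic logistic regression models the binary ecotype with a latent
logistic liability carrying a Brownian phylogenetic random effect
(covariance `s2 · C`, where C is the tree's scaled covariance matrix) — the
Ives–Garland binary-trait framework. Estimation is Laplace maximum
likelihood over the coefficients and `s2` jointly; the slope test is a
likelihood-ratio test against the intercept-only model referred to an
F(1, n − 3) distribution. The small-sample F reference was chosen because
the χ²₁ reference is anti-conservative at phylogeny-scale sample sizes
(n ≈ 13 species), while penalized-quasi-likelihood Wald tests proved
severely conservative there; the F correction gives honest nominal levels
in the package's own calibration tests. On a star phylogeny the fit reduces
to ordinary logistic regression (with `s2 → 0`). Complete separation —
common when a clade-aligned ecotype meets a strongly boosted predictor —
triggers a flagged ridge-penalized fallback whose slope test is an LRT of
the unpenalized likelihood at the ridge estimates on the same F reference.
The ecotype grouping treats non-ostariophysans as lacking the fright
reaction, and the binary trait is the response with the gene count as
predictor (the method named for the analysis requires a binary response);
both choices are overridable.

## Codon models and selection

The GY94 generator assigns rate `π_j · κ^[transition] · ω^[nonsynonymous]`
to single-position codon changes, zero otherwise, scaled to unit mean rate
at stationarity. Site models M0, M1a, M2a, M7, M8, and M8a and branch-site
model A (with its ω₂ = 1 null) are fitted by the pruning algorithm over
compressed site patterns with bounded quasi-Newton optimization (relative
tolerance 1e-8, 3 random restarts by default, seeds logged). Proportion
pairs use a (sum, ratio) parameterization so the box constraints stay
rectangular. Beta mixtures use 10 equal-probability bins represented by
their exact bin means. Codon frequencies default to F3X4 estimated from the
alignment (F1X4 and F61 available). Branch lengths are estimated under M0
and held fixed for the mixture models, standard two-stage practice.

Within a mixture, all classes share one time scale: per-class rate
matrices are combined with branch-length multipliers `r_k / Σ p_k r_k`
(raw class rates over the proportion-weighted mean), so branch lengths are
expected substitutions per codon under the mixture and ω > 1 sites evolve
proportionally faster — the convention of mainstream codon-model software.
The alternative (scaling every class to unit rate independently) removes
the rate elevation of positively selected sites and measurably weakens the
branch-site test; the simulator uses the same convention as the fitter.

Positive-selection sites are identified by NEB (class posteriors at the
MLEs) and BEB (posteriors averaged over a uniform 10-point grid per free
mixing proportion, weighted by each grid point's marginal likelihood, with
class ω values held at their MLEs). The likelihood-ratio layer clamps tiny
negative statistics to zero and reports χ² tail probabilities; for the
M7-vs-M8 comparison only the statistic is meaningful to third parties'
printed tables, and chemorep always reports the exact χ² tail it computes.
When a gene-conversion result is supplied, affected sequences should be
removed before selection analysis; the pipeline exposes this as an input
filter rather than an implicit step.

## Expression layer

FPKM is `count · 1e9 / (length · library size)` with library size defaulting
to total counts and effective length equal to annotated length (no
fragment-length correction). Activity filtering keeps genes with FPKM above
1 in at least half the samples (`ceiling(0.5 · n)`). TMM factors follow the
trimmed (30% on M, 5% on A), inverse-variance-weighted mean of log ratios
against an upper-quartile-chosen reference; the reported factor is the
effective per-sample scaling (library size × TMM ratio) normalized to
geometric mean 1, so dividing counts by the factors makes samples
comparable. Rank-sum tests are exact for ≤ 20 total untied observations and
normal-approximate with tie and continuity corrections otherwise. The
differential-expression screen is |log2FC| ≥ 1 (on +1-shifted mean FPKM)
with BH-adjustable rank-sum p-values; a negative-binomial exact test is out
of scope, and the headline contrasts (receptor vs non-receptor, expanded vs
non-expanded, levels and absolute changes) are rank-sum throughout.

## Orchestration

`run_pipeline()` executes the synthetic study end to end from a single
seeded configuration (`demo_config()`, or a flat key = value file via
`read_config()`). Stages communicate only through on-disk files in the
declared formats — FASTA, GFF-lite, Newick, delimited tables — so real
external outputs (an ML tree, a real hit table, real count matrices) can
replace any stage's input. Every run writes a `manifest.json` with
parameters, seeds, and output checksums; identical configurations produce
identical manifests. The package's functions and this vignette are the
interface; no shell wrapper is required.

## Problem sizes used in the checks

The test suite's simulation scales are the package's own choices for
desk-scale verification: mining recovery over 100 seeded genomes with four
planted genes each (divergence 0.12); reconciliation against exhaustive
enumeration on 200 instances of ≤ 6 species and ≤ 10 genes; 500 tract-free
permutation-null simulations (4 sequences × 300 nt) and 20 planted-tract
alignments for gene conversion; M0 recovery at 5000 codons on a four-taxon
tree with branch lengths 0.5/0.3 (total tree length ≈ 2.2 substitutions
per codon — long enough that the ω estimator's sampling error is well
inside the ±0.1 recovery band); 50 branch-site null simulations at 150
codons; 500 phylogenetic-regression replicates at 13 tips; 200 structureless
ANOSIM matrices. Bootstrap defaults to 100 replicates (raise `n_reps` to
1000 to match common practice at publication scale).

## Known limitations

- Mining is intronless; multi-exon receptor genes in real genomes need an
  external spliced gene model, importable as GFF-lite.
- The internal homology search is deterministic and sensitive for
  divergences up to ~0.3 substitutions/site at default settings, but it is
  not a drop-in replacement for a tuned translated-BLAST workflow on large
  genomes.
- Branch-site fits with a single short foreground branch are weakly
  identified at small alignment sizes; the LRT is then conservative.
- The Laplace approximation behind the phylogenetic logistic AIC is
  asymptotic; with n ≈ 13 binary observations, AIC differences of ≲ 2
  should not be over-read.
- ANOSIM and the permutation gene-conversion test assume exchangeability
  under the null; strong within-group covariance (deep phylogenetic
  structure inside an ecotype group) is not corrected for — that is what
  the phylogenetic regression is for.
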