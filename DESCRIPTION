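Package: chemorep
Title: Chemoreceptor Gene-Family Repertoires: Mining, Phylogenetics, and
    Ecotype Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of vomeronasal-type-2-receptor-like
    (OlfC) chemoreceptor gene families in fish genomes. Mines receptor loci
    from genome assemblies and classifies each as intact, truncated, or
    pseudogene; builds neighbor-joining gene trees from Poisson protein
    distances with bootstrap support; reconciles gene trees against a species
    tree under duplication-loss parsimony to obtain per-branch gains, losses,
    and ancestral copy numbers; detects gene conversion with a Sawyer-style
    permutation test on polymorphic-site identity fragments; tests
    repertoire-ecotype association with contingency, family-size-ratio, PCA,
    ANOSIM, and phylogenetic logistic regression analyses; fits GY94 codon
    site models (M0, M1a, M2a, M7, M8, M8a) and branch-site model A with
    likelihood-ratio tests and empirical-Bayes site identification; and
    provides an expression-statistics layer (FPKM, activity filtering, TMM,
    rank-sum contrasts). Includes generators for fully synthetic study inputs
    with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    edgeR,
    phangorn,
    pracma,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
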