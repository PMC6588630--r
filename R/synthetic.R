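# Synthetic-data generators. Every generator is a pure function of its seed
# and parameters and returns machine-readable ground truth alongside the
# data, so downstream suites can score recovery without external inputs.

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")

#' Deterministic synthetic receptor-like seed protein
#'
#' Generates a reproducible random protein sequence (starting with M) used as
#' the default seed/query for synthetic genome simulations. This is a
#' synthetic stand-in, not a real receptor sequence.
#'
#' @param length Protein length in residues.
#' @param seed RNG seed.
#' @return Single-element named character vector.
#' @export
synthetic_seed_protein <- function(length = 300L, seed = 42L) {
  with_seed(seed, {
    s <- paste0("M", paste(sample(.AA20, length - 1L, replace = TRUE),
                           collapse = ""))
    stats::setNames(s, "synth_receptor")
  })
}

mutate_protein <- function(protein, divergence) {
  aa <- strsplit(protein, "")[[1]]
  hit <- stats::runif(length(aa)) < divergence
  if (any(hit)) {
    aa[hit] <- vapply(aa[hit], function(a)
      sample(setdiff(.AA20, a), 1L), character(1))
  }
  paste(aa, collapse = "")
}

# Uniform-codon back-translation (avoids codon-bias confounds downstream).
back_translate <- function(protein) {
  tab <- codon_table()
  by_aa <- split(tab$codons, tab$aa)
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    opts <- by_aa[[a]]
    if (is.null(opts)) stop("cannot back-translate residue: ", a)
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Apply one random disruption to a CDS: a nonsense substitution (a sense
# codon one substitution away from a stop) or a 1-2 bp indel. Returns the
# disrupted sequence and (kind, CDS nucleotide position).
disrupt_cds <- function(cds) {
  n_cod <- nchar(cds) %/% 3L
  # keep the disruption away from the ends so it falls inside any alignment
  span <- max(2L, floor(n_cod * 0.15)):floor(n_cod * 0.85)
  kind <- sample(c("nonsense", "frameshift"), 1L)
  if (kind == "nonsense") {
    stops <- c("TAA", "TAG", "TGA")
    for (cod_i in sample(span)) {
      cod <- substr(cds, cod_i * 3L - 2L, cod_i * 3L)
      for (s in sample(stops)) {
        diff <- which(strsplit(cod, "")[[1]] != strsplit(s, "")[[1]])
        if (length(diff) == 1L) {
          substr(cds, cod_i * 3L - 2L, cod_i * 3L) <- s
          return(list(seq = cds, kind = "nonsense", pos = cod_i * 3L - 2L))
        }
      }
    }
    kind <- "frameshift"  # no convertible codon found (rare); fall through
  }
  w <- sample.int(2L, 1L)           # 1-2 bp, never a multiple of 3
  pos <- sample(span, 1L) * 3L - 2L
  if (stats::runif(1) < 0.5) {
    seq <- paste0(substr(cds, 1L, pos - 1L), random_dna(w),
                  substr(cds, pos, nchar(cds)))
  } else {
    seq <- paste0(substr(cds, 1L, pos - 1L),
                  substr(cds, pos + w, nchar(cds)))
  }
  list(seq = seq, kind = "frameshift", pos = pos)
}

#' Simulate a genome with planted receptor genes
#'
#' Plants mutated, back-translated copies of a seed protein into random
#' background sequence. Intact and pseudogenized genes go on one main contig;
#' each truncated gene is emitted on its own contig that cuts the gene at a
#' contig boundary. Pseudogenes carry exactly one nonsense or frameshift
#' disruption.
#'
#' @param seed_protein Named character vector of seed proteins (one is chosen
#'   per gene; its name is recorded as the source subfamily).
#' @param n_intact,n_truncated,n_pseudo Numbers of genes to plant.
#' @param divergence Per-residue amino-acid substitution probability in
#'   \[0, 0.5\].
#' @param contig_len Length of the main contig (bp).
#' @param spacing Minimum intergenic gap (bp) between planted genes; keep it
#'   larger than the mining merge distance so neighboring loci stay distinct.
#' @param seed RNG seed.
#' @return List with `contigs` (named character vector) and `truth`
#'   (data.frame: gene, contig, strand, start, end, status, disruption_kind,
#'   disruption_pos, subfamily).
#' @export
simulate_receptor_genome <- function(seed_protein = synthetic_seed_protein(),
                                     n_intact = 5L, n_truncated = 1L,
                                     n_pseudo = 2L, divergence = 0.1,
                                     contig_len = 20000L, seed = 1L,
                                     spacing = 6000L) {
  if (divergence < 0 || divergence > 0.5) stop("divergence must be in [0, 0.5]")
  if (min(n_intact, n_truncated, n_pseudo) < 0) stop("counts must be >= 0")
  if (min(nchar(seed_protein)) * 3L < 200L) {
    stop("seed protein too short: planted genes must be >= 200 nt")
  }
  with_seed(seed, {
    stops <- c("TAA", "TAG", "TGA")
    make_cds <- function() {
      src <- sample.int(length(seed_protein), 1L)
      cds <- paste0(back_translate(mutate_protein(seed_protein[[src]], divergence)),
                    sample(stops, 1L))
      list(cds = cds, subfamily = names(seed_protein)[src])
    }
    status <- c(rep("intact", n_intact), rep("pseudogene", n_pseudo))
    main_genes <- lapply(status, function(st) {
      g <- make_cds()
      g$status <- st
      g$kind <- ""
      g$pos <- NA_integer_
      if (st == "pseudogene") {
        d <- disrupt_cds(g$cds)
        g$cds <- d$seq
        g$kind <- d$kind
        g$pos <- d$pos
      }
      g
    })
    total <- sum(vapply(main_genes, function(g) nchar(g$cds), numeric(1)))
    min_gap <- as.integer(spacing)
    slack <- contig_len - total - (length(main_genes) + 1L) * min_gap
    if (length(main_genes) > 0 && slack < 0) {
      stop("capacity error: planted genes exceed contig length")
    }
    truth <- list()
    contigs <- character(0)
    if (length(main_genes) > 0 || contig_len > 0) {
      gaps <- min_gap + if (length(main_genes) >= 0 && slack > 0) {
        g <- stats::runif(length(main_genes) + 1L)
        floor(g / sum(g) * slack)
      } else rep(0L, length(main_genes) + 1L)
      pieces <- character(0)
      pos <- 0L
      for (i in seq_along(main_genes)) {
        pieces <- c(pieces, random_dna(gaps[i]))
        pos <- pos + gaps[i]
        g <- main_genes[[i]]
        strand <- sample(c("+", "-"), 1L)
        ins <- if (strand == "+") g$cds else revcomp(g$cds)
        truth[[length(truth) + 1L]] <- data.frame(
          gene = sprintf("gene%d", length(truth) + 1L), contig = "ctg1",
          strand = strand, start = pos + 1L, end = pos + nchar(ins),
          status = g$status, disruption_kind = g$kind,
          disruption_pos = g$pos, subfamily = g$subfamily,
          stringsAsFactors = FALSE)
        pieces <- c(pieces, ins)
        pos <- pos + nchar(ins)
      }
      tail_len <- max(contig_len - pos, gaps[length(gaps)])
      pieces <- c(pieces, random_dna(tail_len))
      contigs <- c(contigs, ctg1 = paste(pieces, collapse = ""))
    }
    for (j in seq_len(n_truncated)) {
      g <- make_cds()
      keep <- stats::runif(1, 0.4, 0.7)
      keep_nt <- max(201L, floor(nchar(g$cds) * keep))
      side <- sample(c("start", "end"), 1L)
      frag <- if (side == "start") substr(g$cds, nchar(g$cds) - keep_nt + 1L, nchar(g$cds))
              else substr(g$cds, 1L, keep_nt)
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "+") frag else revcomp(frag)
      pad <- random_dna(400L)
      cname <- sprintf("ctg_trunc%d", j)
      # the cut end of the gene abuts the contig boundary
      if ((side == "start") == (strand == "+")) {
        contigs[cname] <- paste0(ins, pad)
        start <- 1L
      } else {
        contigs[cname] <- paste0(pad, ins)
        start <- 401L
      }
      truth[[length(truth) + 1L]] <- data.frame(
        gene = sprintf("gene%d", length(truth) + 1L), contig = cname,
        strand = strand, start = start, end = start + keep_nt - 1L,
        status = "truncated", disruption_kind = "contig-edge",
        disruption_pos = NA_integer_, subfamily = g$subfamily,
        stringsAsFactors = FALSE)
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(gene = character(0), contig = character(0),
                 strand = character(0), start = integer(0), end = integer(0),
                 status = character(0), disruption_kind = character(0),
                 disruption_pos = integer(0), subfamily = character(0))
    list(contigs = contigs, truth = truth)
  })
}

#' Simulate gene-family evolution by branch-specific birth-death
#'
#' Gene lineages duplicate and die as independent Poisson processes along
#' each branch of a fixed species tree. Realized per-branch gain (duplication)
#' and loss (death) counts are recorded, together with the induced gene tree
#' of surviving lineages (tips labeled `Species_gN`).
#'
#' @param species_tree [ape::phylo]; edges without lengths default to 1.
#' @param birth,death Rates (events per lineage per unit branch length);
#'   scalar or per-edge vectors in `species_tree$edge` order.
#' @param n_root Number of gene copies at the species-tree root.
#' @param seed RNG seed.
#' @return List with `gene_tree` ([ape::phylo] or `NULL` when the family went
#'   extinct), `extinct` flag, `events` (per-branch data.frame: parent/child
#'   node, gains, losses, entering, leaving), and `tip_counts`.
#' @export
simulate_family_evolution <- function(species_tree, birth, death,
                                      n_root = 1L, seed = 1L) {
  if (n_root < 1L) stop("n_root must be >= 1")
  tr <- species_tree
  if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
  nedge <- nrow(tr$edge)
  b <- rep_len(birth, nedge)
  d <- rep_len(death, nedge)
  if (any(b < 0) || any(d < 0)) stop("rates must be >= 0")
  ntip <- length(tr$tip.label)
  children <- split(seq_len(nedge), tr$edge[, 1])
  env <- new.env()
  env$gains <- env$losses <- env$entering <- env$leaving <- integer(nedge)
  env$i <- 0L
  with_seed(seed, {
    sim_from <- function(e, t_rem) {
      rate <- b[e] + d[e]
      ev <- if (rate > 0) stats::rexp(1, rate) else Inf
      if (ev >= t_rem) {
        env$leaving[e] <- env$leaving[e] + 1L
        node <- tr$edge[e, 2]
        if (node <= ntip) {
          env$i <- env$i + 1L
          return(list(nwk = sprintf("%s_g%d", tr$tip.label[node], env$i),
                      pend = t_rem))
        }
        subs <- lapply(children[[as.character(node)]], sim_edge)
        subs <- subs[!vapply(subs, is.null, logical(1))]
        if (length(subs) == 0L) return(NULL)
        if (length(subs) == 1L) {
          return(list(nwk = subs[[1]]$nwk, pend = t_rem + subs[[1]]$pend))
        }
        return(list(nwk = sprintf("(%s:%.9g,%s:%.9g)",
                                  subs[[1]]$nwk, subs[[1]]$pend,
                                  subs[[2]]$nwk, subs[[2]]$pend),
                    pend = t_rem))
      }
      if (stats::runif(1) < b[e] / rate) {
        env$gains[e] <- env$gains[e] + 1L
        s1 <- sim_from(e, t_rem - ev)
        s2 <- sim_from(e, t_rem - ev)
        alive <- Filter(Negate(is.null), list(s1, s2))
        if (length(alive) == 0L) return(NULL)
        if (length(alive) == 1L) {
          return(list(nwk = alive[[1]]$nwk, pend = ev + alive[[1]]$pend))
        }
        return(list(nwk = sprintf("(%s:%.9g,%s:%.9g)",
                                  alive[[1]]$nwk, alive[[1]]$pend,
                                  alive[[2]]$nwk, alive[[2]]$pend),
                    pend = ev))
      }
      env$losses[e] <- env$losses[e] + 1L
      NULL
    }
    sim_edge <- function(e) {
      env$entering[e] <- env$entering[e] + 1L
      sim_from(e, tr$edge.length[e])
    }
    root <- ntip + 1L
    roots <- list()
    for (k in seq_len(n_root)) {
      subs <- lapply(children[[as.character(root)]], sim_edge)
      subs <- subs[!vapply(subs, is.null, logical(1))]
      rt <- if (length(subs) == 0L) NULL
        else if (length(subs) == 1L) subs[[1]]
        else list(nwk = sprintf("(%s:%.9g,%s:%.9g)", subs[[1]]$nwk,
                                subs[[1]]$pend, subs[[2]]$nwk, subs[[2]]$pend),
                  pend = 0)
      if (!is.null(rt)) roots[[length(roots) + 1L]] <- rt
    }
    gene_tree <- NULL
    if (length(roots) > 0L) {
      nwk <- roots[[1]]$nwk
      for (k in seq_along(roots)[-1]) {
        nwk <- sprintf("(%s:0,%s:%.9g)", nwk, roots[[k]]$nwk, roots[[k]]$pend)
      }
      if (!grepl("(", nwk, fixed = TRUE)) nwk <- sprintf("(%s:0);", nwk)
      else nwk <- paste0(nwk, ";")
      gene_tree <- ape::read.tree(text = nwk)
    }
    events <- data.frame(parent = tr$edge[, 1], child = tr$edge[, 2],
                         branch = ifelse(tr$edge[, 2] <= ntip,
                                         tr$tip.label[tr$edge[, 2]],
                                         paste0("node", tr$edge[, 2])),
                         gains = env$gains, losses = env$losses,
                         entering = env$entering, leaving = env$leaving)
    tips <- if (is.null(gene_tree)) character(0) else gene_tree$tip.label
    counts <- table(factor(sub("_g[0-9]+$", "", tips), levels = tr$tip.label))
    list(gene_tree = gene_tree, extinct = is.null(gene_tree),
         events = events, tip_counts = counts, species_tree = tr)
  })
}

#' Simulate a codon alignment under a GY94 site-class mixture
#'
#' Each codon site draws a class (a proportion/omega pair), then evolves on
#' the tree under the GY94 process. For branch-site simulations a class may
#' carry a distinct foreground omega applied on the designated branches.
#'
#' @param tree [ape::phylo] with branch lengths (expected substitutions per
#'   codon).
#' @param site_classes List of classes: each `list(prop=, omega=)` with
#'   optional `omega_fg`.
#' @param kappa Transition/transversion ratio.
#' @param codon_freqs Stationary codon frequencies (default uniform).
#' @param n_codons Number of codon sites.
#' @param seed RNG seed.
#' @param foreground Optional tip/node labels marking foreground branches.
#' @return List with `alignment` (named character vector of CDS strings) and
#'   `site_class` (integer class index per site).
#' @export
simulate_codon_alignment <- function(tree, site_classes, kappa = 2,
                                     codon_freqs = NULL, n_codons = 300L,
                                     seed = 1L, foreground = NULL) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  props <- vapply(site_classes, `[[`, numeric(1), "prop")
  if (abs(sum(props) - 1) > 1e-9) stop("class proportions must sum to 1")
  if (any(vapply(site_classes, `[[`, numeric(1), "omega") < 0)) {
    stop("omega must be >= 0")
  }
  tab <- codon_table()
  n_state <- length(tab$codons)
  if (is.null(codon_freqs)) codon_freqs <- rep(1 / n_state, n_state)
  plan <- tree_plan(tree, tree$tip.label)
  fg <- if (is.null(foreground)) rep(FALSE, nrow(plan$edge))
        else foreground_edges(plan, foreground)
  with_seed(seed, {
    cls <- sample.int(length(site_classes), n_codons, replace = TRUE,
                      prob = props)
    states <- matrix(NA_integer_, max(plan$edge), n_codons)
    states[plan$root, ] <- sample.int(n_state, n_codons, replace = TRUE,
                                      prob = codon_freqs)
    evolve <- function(parent_states, pmat) {
      out <- integer(length(parent_states))
      for (s in unique(parent_states)) {
        idx <- parent_states == s
        out[idx] <- sample.int(n_state, sum(idx), replace = TRUE,
                               prob = pmat[s, ])
      }
      out
    }
    eig_cache <- list()
    get_eig <- function(omega) {
      key <- sprintf("%.12g", omega)
      if (is.null(eig_cache[[key]])) {
        eig_cache[[key]] <<- gy94_eigen(
          gy94_rate_matrix(kappa, omega, codon_freqs), codon_freqs)
      }
      eig_cache[[key]]
    }
    mult <- class_rate_multipliers(kappa, site_classes, codon_freqs)
    for (i in rev(seq_len(nrow(plan$edge)))) {   # preorder
      parent <- plan$edge[i, 1]
      child <- plan$edge[i, 2]
      for (k in seq_along(site_classes)) {
        idx <- cls == k
        if (!any(idx)) next
        cl <- site_classes[[k]]
        use_fg <- fg[i] && !is.null(cl$omega_fg)
        om <- if (use_fg) cl$omega_fg else cl$omega
        m <- if (use_fg) mult$fg[k] else mult$bg[k]
        pmat <- gy94_pmat(get_eig(om), plan$len[i] * m)
        pmat[pmat < 0] <- 0
        states[child, idx] <- evolve(states[parent, idx], pmat)
      }
    }
    aln <- vapply(seq_len(plan$ntip), function(tp) {
      paste(tab$codons[states[tp, ]], collapse = "")
    }, character(1))
    names(aln) <- plan$tree$tip.label
    list(alignment = aln, site_class = cls)
  })
}

#' Simulate a species-by-subfamily repertoire count matrix
#'
#' Counts are Poisson with a common base mean; in group 1 ("fright") one
#' designated subfamily is boosted by a multiplicative factor, emulating a
#' group effect concentrated in a single subfamily.
#'
#' @param n_group1,n_group2 Species per group (group 1 carries the boost).
#' @param n_subfamilies Number of subfamilies (>= 2).
#' @param base_mean Poisson mean for unboosted cells.
#' @param boosted_subfamily Column index receiving the boost in group 1.
#' @param boost Multiplier (>= 1).
#' @param seed RNG seed.
#' @return Integer matrix (species x subfamilies) with an `ecotype` attribute
#'   (`"fright"`/`"no_fright"` per species).
#' @export
simulate_repertoire_matrix <- function(n_group1 = 5L, n_group2 = 8L,
                                       n_subfamilies = 16L, base_mean = 3,
                                       boosted_subfamily = 9L, boost = 1,
                                       seed = 1L) {
  if (n_subfamilies < 2L) stop("degenerate matrix: need >= 2 subfamilies")
  if (boost < 1) stop("boost must be >= 1")
  with_seed(seed, {
    n <- n_group1 + n_group2
    mu <- matrix(base_mean, n, n_subfamilies)
    mu[seq_len(n_group1), boosted_subfamily] <- base_mean * boost
    m <- matrix(stats::rpois(n * n_subfamilies, as.vector(mu)), n,
                n_subfamilies)
    rownames(m) <- c(sprintf("fright_sp%d", seq_len(n_group1)),
                     sprintf("nofright_sp%d", seq_len(n_group2)))
    colnames(m) <- sprintf("sf%d", seq_len(n_subfamilies))
    attr(m, "ecotype") <- stats::setNames(
      rep(c("fright", "no_fright"), c(n_group1, n_group2)), rownames(m))
    m
  })
}

#' Simulate negative-binomial expression counts with planted fold changes
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per condition (before/after).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param de_fraction Fraction of genes shifted in the second condition.
#' @param log2fc Planted log2 fold change (applied with random sign).
#' @param seed RNG seed.
#' @param base_mean_log Mean of the log-normal gene-mean distribution.
#' @return List with `counts` (genes x samples), `lengths` (bp), `condition`
#'   (per sample, `"before"`/`"after"`), `is_de`, `true_log2fc`.
#' @export
simulate_expression_counts <- function(n_genes = 2000L, n_per_group = 3L,
                                       dispersion = 0.1, de_fraction = 0.1,
                                       log2fc = 2, seed = 1L,
                                       base_mean_log = log(100)) {
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must be in [0,1]")
  with_seed(seed, {
    mu <- exp(stats::rnorm(n_genes, base_mean_log, 1))
    n_de <- round(de_fraction * n_genes)
    is_de <- rep(FALSE, n_genes)
    is_de[sample.int(n_genes, n_de)] <- TRUE
    sign <- ifelse(stats::runif(n_genes) < 0.5, -1, 1)
    lfc <- ifelse(is_de, sign * log2fc, 0)
    mu2 <- mu * 2^lfc
    n_samp <- 2L * n_per_group
    counts <- matrix(0L, n_genes, n_samp)
    size <- 1 / dispersion
    for (j in seq_len(n_per_group)) {
      counts[, j] <- stats::rnbinom(n_genes, mu = mu, size = size)
      counts[, n_per_group + j] <- stats::rnbinom(n_genes, mu = mu2, size = size)
    }
    rownames(counts) <- sprintf("g%d", seq_len(n_genes))
    colnames(counts) <- c(sprintf("before_%d", seq_len(n_per_group)),
                          sprintf("after_%d", seq_len(n_per_group)))
    list(counts = counts,
         lengths = stats::setNames(sample(500:5000, n_genes, replace = TRUE),
                                   rownames(counts)),
         condition = rep(c("before", "after"), each = n_per_group),
         is_de = stats::setNames(is_de, rownames(counts)),
         true_log2fc = stats::setNames(lfc, rownames(counts)))
  })
}
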