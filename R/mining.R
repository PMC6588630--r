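# Receptor-gene mining: homology search (internal six-frame seeded search or
# imported tabular hits), hit merging into candidate loci, frame-aware gene
# models, functional-status classification, and family verification.
#
# The internal search stands in for a translated homology search: exact
# amino-acid k-mer seeds (k = 4) on six-frame translations, gapped local
# extension under BLOSUM62 (gap open 11 / extend 1), and Karlin-Altschul
# e-values with fixed gapped parameters (lambda = 0.267, K = 0.041).

.mining_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.mining_env$b62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .mining_env$b62 <- e$BLOSUM62
  }
  .mining_env$b62
}

aa_indices <- function(aa_chars) {
  alpha <- rownames(blosum62())
  i <- match(aa_chars, alpha)
  i[is.na(i)] <- match("X", alpha)
  i - 1L
}

ka_bitscore <- function(raw, lambda = 0.267, K = 0.041) {
  (lambda * raw - log(K)) / log(2)
}

#' Search a genome for receptor-protein homologs
#'
#' Internal mode runs a self-contained translated homology search: six-frame
#' translation of each contig, exact amino-acid 4-mer seeding against each
#' query, clustering of seeds, gapped local extension with BLOSUM62, and an
#' approximate e-value from the bit score and search-space size. Imported
#' mode parses an external 12-column tabular hit file instead. Both are
#' filtered at `e_cutoff`.
#'
#' @param contigs Named character vector of genome contigs (DNA).
#' @param queries Named character vector of query proteins.
#' @param e_cutoff Maximum e-value retained.
#' @param mode `"internal"` or `"imported"`.
#' @param hits_path Path to the external hit table (imported mode).
#' @param seed_k Seed word size (amino acids).
#' @return Hit `data.frame` (see [read_hits_table()]): subject coordinates on
#'   the forward strand with a `strand` flag.
#' @export
search_homologs <- function(contigs, queries, e_cutoff = 1e-10,
                            mode = c("internal", "imported"),
                            hits_path = NULL, seed_k = 4L) {
  mode <- match.arg(mode)
  if (mode == "imported") {
    if (is.null(hits_path)) stop("imported mode requires hits_path")
    return(read_hits_table(hits_path, e_cutoff))
  }
  if (length(queries) == 0L) stop("queries must be non-empty")
  if (length(contigs) == 0L) return(empty_hits())
  total_nt <- sum(nchar(contigs))
  b62 <- blosum62()
  qk_list <- lapply(queries, function(q) {
    nq <- nchar(q)
    if (nq < seed_k) character(0)
    else unique(substring(q, 1:(nq - seed_k + 1L), seed_k:nq))
  })
  rows <- list()
  for (cname in names(contigs)) {
    fwd <- toupper(contigs[[cname]])
    L <- nchar(fwd)
    for (strand in c("+", "-")) {
      dna <- if (strand == "+") fwd else revcomp(fwd)
      for (f in 0:2) {
        prot <- translate_dna(substr(dna, 1L + f, L))
        np <- nchar(prot)
        if (np < seed_k) next
        kmers <- substring(prot, 1:(np - seed_k + 1L), seed_k:np)
        for (qname in names(queries)) {
          q <- queries[[qname]]
          nq <- nchar(q)
          seeds <- which(kmers %in% qk_list[[qname]])
          if (length(seeds) == 0L) next
          clusters <- split(seeds, cumsum(c(1L, diff(seeds) > 100L)))
          for (grp in clusters) {
            margin <- nq - (max(grp) - min(grp)) + 20L
            a1 <- max(1L, min(grp) - margin)
            a2 <- min(np, max(grp) + margin)
            win <- substr(prot, a1, a2)
            pa <- Biostrings::pairwiseAlignment(
              Biostrings::AAString(q), Biostrings::AAString(win),
              type = "local", substitutionMatrix = b62,
              gapOpening = 11, gapExtension = 1)
            raw <- Biostrings::score(pa)
            bit <- ka_bitscore(raw)
            evalue <- nq * (total_nt / 3) * 2 * 2^(-bit)
            if (evalue > e_cutoff) next
            s_aa1 <- a1 + Biostrings::start(Biostrings::subject(pa)) - 1L
            s_aa2 <- a1 + Biostrings::end(Biostrings::subject(pa)) - 1L
            d1 <- f + 3L * (s_aa1 - 1L) + 1L     # oriented-strand nt coords
            d2 <- f + 3L * s_aa2
            if (strand == "+") { g1 <- d1; g2 <- d2 }
            else { g1 <- L - d2 + 1L; g2 <- L - d1 + 1L }
            alen <- nchar(as.character(Biostrings::pattern(pa)))
            rows[[length(rows) + 1L]] <- data.frame(
              qseqid = qname, sseqid = cname,
              pident = round(Biostrings::pid(pa), 2), length = alen,
              mismatch = Biostrings::nmismatch(pa), gapopen = 0L,
              qstart = Biostrings::start(Biostrings::pattern(pa)),
              qend = Biostrings::end(Biostrings::pattern(pa)),
              sstart = g1, send = g2, evalue = evalue,
              bitscore = round(bit, 1), strand = strand,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(rows) == 0L) return(empty_hits())
  do.call(rbind, rows)
}

#' Merge overlapping hits into candidate gene loci
#'
#' Same-contig, same-strand hits whose subject intervals overlap or lie
#' within `max_gap` are merged into one locus. Merged envelopes shorter than
#' `min_len` nucleotides are discarded. The best query is the hit with the
#' highest bit score.
#'
#' @param hits Hit `data.frame`.
#' @param max_gap Maximum merge distance (bp).
#' @param min_len Minimum envelope length (bp) retained.
#' @return Locus `data.frame`: contig, strand, start, end, best_query,
#'   best_bitscore, n_hits.
#' @export
merge_hits <- function(hits, max_gap = 5000L, min_len = 200L) {
  out <- list()
  if (nrow(hits) == 0L) {
    return(data.frame(contig = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      best_query = character(0), best_bitscore = numeric(0),
                      n_hits = integer(0), stringsAsFactors = FALSE))
  }
  for (key in unique(paste(hits$sseqid, hits$strand))) {
    h <- hits[paste(hits$sseqid, hits$strand) == key, , drop = FALSE]
    h <- h[order(h$sstart, h$send), , drop = FALSE]
    grp <- cumsum(c(1L, h$sstart[-1] > cummax(h$send)[-nrow(h)] + max_gap))
    for (g in unique(grp)) {
      hh <- h[grp == g, , drop = FALSE]
      env_start <- min(hh$sstart)
      env_end <- max(hh$send)
      if (env_end - env_start + 1L < min_len) next
      best <- which.max(hh$bitscore)
      out[[length(out) + 1L]] <- data.frame(
        contig = hh$sseqid[1], strand = hh$strand[1],
        start = env_start, end = env_end,
        best_query = hh$qseqid[best], best_bitscore = hh$bitscore[best],
        n_hits = nrow(hh), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(merge_hits(empty_hits()))
  }
  out[order(out$contig, out$start), , drop = FALSE]
}

#' Build a gene model for a candidate locus
#'
#' Extends the locus by `flank` on both sides (clipped at contig ends),
#' orients the sequence to the hit strand, and aligns the best query protein
#' to the DNA with a frame-aware local dynamic program that allows frame
#' switches at a fixed penalty. In-frame stop codons on the alignment path
#' are recorded as nonsense disruptions, frame switches as frameshift
#' disruptions (switches within 3 codons of each other are merged into one
#' event).
#'
#' @param locus One row of the [merge_hits()] table.
#' @param contigs Named character vector of contigs.
#' @param queries Named character vector of query proteins.
#' @param flank Extension (bp) on each side.
#' @param fs_penalty Frameshift penalty (score units).
#' @param gap_penalty Per-event gap penalty.
#' @param stop_score Score assigned to aligning through a stop codon.
#' @param min_score Score floor below which the model fails.
#' @param ext_min,ext_max Hard bounds on the extension (bp, genomic); used by
#'   [mine_receptors()] to keep neighboring loci's windows disjoint.
#' @return A `gene_model` list: locus fields plus `coverage`, `disruptions`
#'   (data.frame kind/cds_pos/genomic_pos), `protein`, `cds_start`/`cds_end`
#'   (genomic, forward), `contig_edge`, `failed`.
#' @export
build_gene_model <- function(locus, contigs, queries, flank = 10000L,
                             fs_penalty = 15L, gap_penalty = 12L,
                             stop_score = -5L, min_score = 50L,
                             ext_min = 1L, ext_max = NULL) {
  contig <- contigs[[locus$contig]]
  L <- nchar(contig)
  if (is.null(ext_max)) ext_max <- L
  ext_start <- max(1L, ext_min, locus$start - flank)
  ext_end <- min(L, ext_max, locus$end + flank)
  seg <- substr(contig, ext_start, ext_end)
  minus <- locus$strand == "-"
  dna <- if (minus) revcomp(seg) else seg
  n <- nchar(dna)
  query <- queries[[locus$best_query]]
  gc_map <- Biostrings::GENETIC_CODE
  cods <- substring(dna, 1:max(1L, n - 2L), 3:n)
  aa <- gc_map[cods]
  aa_at <- integer(n)
  aa_at[] <- -2L
  valid <- !is.na(aa)
  aa_at[which(valid)] <- ifelse(aa[valid] == "*", -1L,
                                aa_indices(aa[valid]))
  res <- frame_dp(aa_at, aa_indices(strsplit(query, "")[[1]]),
                  blosum62(), stop_score, fs_penalty, gap_penalty)
  failed <- res$score < min_score
  nq <- nchar(query)
  coverage <- if (failed) 0 else (res$q_end - res$q_start + 1L) / nq
  to_genomic <- function(d) {
    if (minus) ext_start + (n - d) else ext_start + d - 1L
  }
  disruptions <- data.frame(kind = character(0), cds_pos = integer(0),
                            genomic_pos = integer(0))
  protein <- ""
  if (!failed) {
    kind <- c("nonsense", "frameshift")[res$event_type]
    pos <- res$event_pos
    if (length(pos)) {
      keep <- rep(TRUE, length(pos))
      ord <- order(pos)
      kind <- kind[ord]; pos <- pos[ord]
      last_fs <- -Inf
      for (k in seq_along(pos)) {
        if (kind[k] == "frameshift") {
          if (pos[k] - last_fs <= 9L) keep[k] <- FALSE else last_fs <- pos[k]
        }
      }
      kind <- kind[keep]; pos <- pos[keep]
      disruptions <- data.frame(kind = kind,
                                cds_pos = pos - res$d_start + 1L,
                                genomic_pos = vapply(pos, to_genomic,
                                                     numeric(1)))
    }
    aa_chars <- ifelse(res$d_pos == 0L, "X",
                       {a <- aa[res$d_pos]; ifelse(is.na(a), "X", a)})
    protein <- paste(aa_chars, collapse = "")
  }
  g1 <- if (failed) NA_integer_ else min(to_genomic(res$d_start),
                                         to_genomic(res$d_end))
  g2 <- if (failed) NA_integer_ else max(to_genomic(res$d_start),
                                         to_genomic(res$d_end))
  contig_edge <- !failed && (g1 <= 3L || g2 >= L - 2L)
  structure(list(contig = locus$contig, strand = locus$strand,
                 locus_start = locus$start, locus_end = locus$end,
                 best_query = locus$best_query,
                 cds_start = g1, cds_end = g2,
                 score = res$score, coverage = coverage,
                 disruptions = disruptions, protein = protein,
                 contig_edge = contig_edge, failed = failed),
            class = "gene_model")
}

#' Classify a gene model as intact, truncated, or pseudogene
#'
#' Any nonsense or frameshift disruption makes a pseudogene. Otherwise the
#' gene is intact when query coverage reaches the completeness threshold and
#' the model does not run into a contig edge, and truncated when the coding
#' region is incomplete.
#'
#' @param model A `gene_model`.
#' @param completeness Minimum query coverage for a complete coding region.
#' @return `"intact"`, `"truncated"`, or `"pseudogene"`.
#' @export
classify_gene <- function(model, completeness = 0.9) {
  if (nrow(model$disruptions) > 0L) return("pseudogene")
  if (model$coverage >= completeness && !model$contig_edge) return("intact")
  "truncated"
}

#' Verify family membership of an inferred protein
#'
#' Aligns the protein against a labeled reference panel (target family plus
#' decoys) with gapped local BLOSUM62 alignment. The protein is accepted iff
#' the single best-scoring reference is labeled target-family; score ties
#' between target and decoy are rejected (conservative).
#'
#' @param protein Protein string.
#' @param references Named character vector of reference proteins.
#' @param labels Character vector (aligned with `references`) of family
#'   labels.
#' @param target Label counting as the target family.
#' @return Logical (accepted), with attribute `best` (reference name).
#' @export
verify_family_membership <- function(protein, references, labels,
                                     target = "target") {
  if (length(references) == 0L) stop("empty reference panel")
  if (length(labels) != length(references)) stop("labels must match references")
  scores <- vapply(references, function(r) {
    Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(protein), Biostrings::AAString(r),
      type = "local", substitutionMatrix = blosum62(),
      gapOpening = 11, gapExtension = 1))
  }, numeric(1))
  best <- max(scores)
  best_labels <- unique(labels[scores == best])
  accepted <- identical(best_labels, target)
  structure(accepted, best = names(references)[which.max(scores)])
}

#' Mine a genome for receptor genes end to end
#'
#' Runs [search_homologs()], [merge_hits()], [build_gene_model()], and
#' [classify_gene()]; optionally verifies family membership against a
#' labeled reference panel.
#'
#' @inheritParams search_homologs
#' @inheritParams merge_hits
#' @inheritParams build_gene_model
#' @inheritParams classify_gene
#' @param references,labels,target Optional verification panel (see
#'   [verify_family_membership()]).
#' @return List with `annotations` (data.frame: contig, strand, start, end,
#'   status, coverage, n_disruptions, best_query, accepted) and `models`.
#' @export
mine_receptors <- function(contigs, queries, e_cutoff = 1e-10,
                           mode = "internal", hits_path = NULL,
                           max_gap = 5000L, flank = 10000L,
                           completeness = 0.9, references = NULL,
                           labels = NULL, target = "target") {
  hits <- search_homologs(contigs, queries, e_cutoff, mode, hits_path)
  loci <- merge_hits(hits, max_gap = max_gap)
  # extensions stop at the midpoint toward any neighboring locus, so each
  # gene model is anchored to its own locus
  loci <- loci[order(loci$contig, loci$start), , drop = FALSE]
  loci$ext_min <- rep(1L, nrow(loci))
  loci$ext_max <- rep(NA_integer_, nrow(loci))
  for (ctg in unique(loci$contig)) {
    idx <- which(loci$contig == ctg)
    if (length(idx) > 1L) {
      for (k in seq_along(idx)[-1]) {
        mid <- (loci$end[idx[k - 1]] + loci$start[idx[k]]) %/% 2L
        loci$ext_min[idx[k]] <- max(loci$ext_min[idx[k]], mid + 1L)
        loci$ext_max[idx[k - 1]] <- mid
      }
    }
  }
  models <- list()
  ann <- list()
  for (i in seq_len(nrow(loci))) {
    model <- build_gene_model(loci[i, ], contigs, queries, flank = flank,
                              ext_min = loci$ext_min[i],
                              ext_max = if (is.na(loci$ext_max[i])) NULL
                                        else loci$ext_max[i])
    if (model$failed) next
    status <- classify_gene(model, completeness)
    accepted <- NA
    if (!is.null(references)) {
      accepted <- as.logical(verify_family_membership(model$protein,
                                                      references, labels,
                                                      target))
      if (!accepted) next
    }
    models[[length(models) + 1L]] <- model
    ann[[length(ann) + 1L]] <- data.frame(
      contig = model$contig, strand = model$strand,
      start = model$cds_start, end = model$cds_end, status = status,
      coverage = round(model$coverage, 4),
      n_disruptions = nrow(model$disruptions),
      best_query = model$best_query, accepted = accepted,
      stringsAsFactors = FALSE)
  }
  ann <- if (length(ann)) do.call(rbind, ann) else
    data.frame(contig = character(0), strand = character(0),
               start = integer(0), end = integer(0), status = character(0),
               coverage = numeric(0), n_disruptions = integer(0),
               best_query = character(0), accepted = logical(0))
  list(annotations = ann, models = models)
}

#' Write mined annotations as GFF-lite
#'
#' @param annotations Annotation table from [mine_receptors()].
#' @param path Output path.
#' @param params Named list echoed into the file header.
#' @return `path`, invisibly.
#' @export
annotations_to_gff <- function(annotations, path, params = NULL) {
  gff <- data.frame(
    seqid = annotations$contig, source = "chemorep", type = "receptor_gene",
    start = annotations$start, end = annotations$end,
    score = annotations$coverage, strand = annotations$strand, frame = ".",
    attributes = sprintf("status=%s;query=%s;disruptions=%d",
                         annotations$status, annotations$best_query,
                         annotations$n_disruptions),
    stringsAsFactors = FALSE)
  hdr <- if (is.null(params)) NULL else
    paste(names(params), unlist(params), sep = "=")
  write_gff_lite(gff, path, header = hdr)
}
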