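# Distance-based gene-tree construction: Poisson protein distances with
# pairwise deletion of gap sites, neighbor-joining, bootstrap supports,
# tree-guided subfamily assignment, and per-column conservation profiles.

aln_matrix <- function(aln) {
  if (length(unique(nchar(aln))) != 1L) stop("sequences must be aligned")
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(m) <- names(aln)
  m
}

is_gap <- function(chars) chars == "-" | chars == "." | chars == "?"

#' Poisson protein distance matrix with pairwise deletion
#'
#' For each sequence pair, the mismatch proportion `p` is computed over the
#' columns where neither sequence has a gap, and the distance is the Poisson
#' correction `d = -ln(1 - p)`. Pairs with `p >= 1` are flagged saturated
#' (`Inf`).
#'
#' @param aln Named character vector: aligned protein sequences (>= 2).
#' @return A symmetric numeric matrix with a logical `"saturated"` attribute.
#' @export
poisson_distance_matrix <- function(aln) {
  if (length(aln) < 2L) stop("need >= 2 sequences")
  m <- aln_matrix(aln)
  n <- nrow(m)
  gaps <- is_gap(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- !gaps[i, ] & !gaps[j, ]
      ns <- sum(shared)
      if (ns == 0L) {
        stop("incomparable pair (no shared non-gap columns): ",
             rownames(m)[i], " vs ", rownames(m)[j])
      }
      p <- sum(m[i, shared] != m[j, shared]) / ns
      if (p >= 1) {
        d[i, j] <- d[j, i] <- Inf
        sat[i, j] <- sat[j, i] <- TRUE
      } else {
        d[i, j] <- d[j, i] <- -log(1 - p)
      }
    }
  }
  attr(d, "saturated") <- sat
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical neighbor-joining ([ape::nj()]); negative branch lengths are
#' clamped to zero. Saturated (infinite) distances are refused unless
#' `allow_saturated = TRUE`.
#'
#' @param dm Symmetric distance matrix (>= 3 taxa).
#' @param allow_saturated Proceed despite saturated entries (they are
#'   replaced by twice the largest finite distance).
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dm, allow_saturated = FALSE) {
  if (nrow(dm) < 3L) stop("need >= 3 taxa")
  if (any(!is.finite(dm))) {
    if (!allow_saturated) {
      stop("saturated distances present; rerun with allow_saturated = TRUE")
    }
    mx <- max(dm[is.finite(dm)])
    dm[!is.finite(dm)] <- 2 * mx
  }
  tr <- ape::nj(as.dist(dm))
  if (any(tr$edge.length < 0)) {
    message("nj_tree: clamped ", sum(tr$edge.length < 0),
            " negative branch length(s) to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

nj_from_alignment <- function(aln, allow_saturated = TRUE) {
  nj_tree(poisson_distance_matrix(aln), allow_saturated = allow_saturated)
}

# Splits of a tree: list over internal edges of the tip-label set on the
# child side.
tree_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  tr <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; c <- tr$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[c]])
  }
  out <- list()
  for (k in seq_len(nrow(tr$edge))) {
    c <- tr$edge[k, 2]
    if (c > ntip) out[[length(out) + 1L]] <- sort(desc[[c]])
  }
  out
}

#' Bootstrap supports for a neighbor-joining protein tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree from
#' Poisson distances for each replicate, and reports, for every internal
#' edge of the point-estimate tree, the percentage of replicates whose tree
#' contains the same bipartition.
#'
#' @param aln Named character vector: aligned protein sequences.
#' @param n_reps Number of bootstrap replicates.
#' @param seed RNG seed (the resample stream is keyed to columns).
#' @return The point-estimate tree with `node.label` support percentages and
#'   a `"support"` attribute (per internal edge).
#' @export
bootstrap_support <- function(aln, n_reps = 100L, seed = 1L) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  point <- nj_from_alignment(aln)
  ncol_aln <- nchar(aln[[1]])
  m <- aln_matrix(aln)
  splits <- tree_splits(point)
  ntip <- length(point$tip.label)
  counts <- numeric(length(splits))
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
      rep_aln <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
      rtree <- nj_from_alignment(rep_aln)
      rsplits <- tree_splits(rtree)
      keys <- vapply(rsplits, paste, character(1), collapse = "\r")
      # compare unrooted bipartitions: a split matches if either side does
      all_tips <- sort(point$tip.label)
      keys2 <- vapply(rsplits, function(s)
        paste(setdiff(all_tips, s), collapse = "\r"), character(1))
      for (k in seq_along(splits)) {
        key <- paste(splits[[k]], collapse = "\r")
        keyc <- paste(setdiff(all_tips, splits[[k]]), collapse = "\r")
        if (key %in% keys || key %in% keys2 || keyc %in% keys ||
            keyc %in% keys2) counts[k] <- counts[k] + 1
      }
    }
  })
  support <- 100 * counts / n_reps
  # attach to internal nodes (postorder internal-edge order of tree_splits)
  tr <- ape::reorder.phylo(point, "postorder")
  lab <- rep(NA_real_, point$Nnode)
  idx <- 1L
  for (k in seq_len(nrow(tr$edge))) {
    c <- tr$edge[k, 2]
    if (c > ntip) {
      lab[c - ntip] <- support[idx]
      idx <- idx + 1L
    }
  }
  point$node.label <- lab
  attr(point, "support") <- support
  point
}

#' Assign a query protein to a subfamily
#'
#' The query joins a combined NJ tree with the labeled reference panel. The
#' assigned label is the subfamily of the smallest non-trivial clade
#' (tree split) containing the query whose reference members all share one
#' subfamily; if no such clade exists the nearest reference by Poisson
#' distance decides; ambiguity (tied labels) yields `NA` (unassigned).
#'
#' @param query Single named aligned protein (same columns as `references`).
#' @param references Named character vector of aligned reference proteins.
#' @param labels Subfamily label per reference (aligned with `references`).
#' @return Subfamily label, or `NA_character_` when unassigned.
#' @export
assign_subfamily <- function(query, references, labels) {
  if (length(references) == 0L) stop("empty reference panel")
  if (is.null(names(query))) names(query) <- "query"
  qname <- names(query)[1]
  if (qname %in% names(references)) {
    return(labels[match(qname, names(references))])
  }
  lab_of <- stats::setNames(labels, names(references))
  aln <- c(references, query)
  dm <- poisson_distance_matrix(aln)
  if (length(references) >= 3L) {
    tr <- nj_tree(dm, allow_saturated = TRUE)
    splits <- tree_splits(tr)
    all_tips <- sort(tr$tip.label)
    best <- NULL
    for (s in splits) {
      side <- if (qname %in% s) s else setdiff(all_tips, s)
      refs <- setdiff(side, qname)
      if (length(refs) == 0L) next
      labs <- unique(lab_of[refs])
      if (length(labs) == 1L && (is.null(best) || length(side) < best$size)) {
        best <- list(label = labs, size = length(side))
      } else if (length(labs) == 1L && !is.null(best) &&
                 length(side) == best$size && labs != best$label) {
        best$tie <- TRUE
      }
    }
    if (!is.null(best) && !isTRUE(best$tie)) {
      return(unname(best$label))
    }
    # tied pure clades fall through to the nearest-reference rule
  }
  dq <- dm[qname, names(references)]
  nearest <- names(references)[dq == min(dq)]
  labs <- unique(lab_of[nearest])
  if (length(labs) != 1L) return(NA_character_)
  unname(labs)
}

#' Per-column conservation profile of a protein alignment
#'
#' Shannon entropy per column over the 20-letter amino-acid alphabet (gaps
#' excluded from the column counts), reported as information content
#' `IC = log2(20) - H` in bits. All-gap columns yield `NA` with a flag.
#'
#' @param aln Named character vector of aligned proteins.
#' @param site_categories Optional per-column category labels (e.g.
#'   proximal-binding / selectivity / structural / other).
#' @return Data frame: `column`, `ic`, `n_residues`, `all_gap`, `category`;
#'   residue frequency matrix attached as attribute `"freqs"`.
#' @export
column_information <- function(aln, site_categories = NULL) {
  if (length(aln) == 0L) stop("empty alignment")
  m <- aln_matrix(aln)
  ncol_aln <- ncol(m)
  if (!is.null(site_categories) && length(site_categories) != ncol_aln) {
    stop("site_categories length must equal alignment length")
  }
  aa20 <- .AA20
  freqs <- matrix(0, ncol_aln, 20L, dimnames = list(NULL, aa20))
  ic <- numeric(ncol_aln)
  nres <- integer(ncol_aln)
  for (j in seq_len(ncol_aln)) {
    col <- m[, j]
    col <- col[!is_gap(col) & col %in% aa20]
    nres[j] <- length(col)
    if (length(col) == 0L) {
      ic[j] <- NA_real_
      next
    }
    f <- table(factor(col, levels = aa20)) / length(col)
    freqs[j, ] <- f
    h <- -sum(f[f > 0] * log2(f[f > 0]))
    ic[j] <- log2(20) - h
  }
  out <- data.frame(column = seq_len(ncol_aln), ic = ic, n_residues = nres,
                    all_gap = nres == 0L,
                    category = if (is.null(site_categories)) NA_character_
                               else site_categories,
                    stringsAsFactors = FALSE)
  attr(out, "freqs") <- freqs
  out
}
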