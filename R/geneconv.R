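# Sawyer-style gene-conversion detection: condense an alignment to its
# polymorphic sites, find maximal identity fragments per sequence pair, and
# assess significance by jointly permuting the order of polymorphic columns
# (which preserves each pair's mismatch count while destroying clustering).

#' Condense an alignment to its polymorphic sites
#'
#' Keeps columns with at least two alleles; columns containing a gap are
#' excluded from the polymorphic set.
#'
#' @param aln Named character vector: aligned nucleotide sequences (>= 2).
#' @return List with `sites` (original column indices) and `matrix`
#'   (sequences x polymorphic columns character matrix).
#' @export
condense_polymorphic <- function(aln) {
  if (length(aln) < 2L) stop("need >= 2 sequences")
  m <- aln_matrix(aln)
  keep <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (any(is_gap(col))) next
    keep[j] <- length(unique(col)) >= 2L
  }
  list(sites = which(keep), matrix = m[, keep, drop = FALSE])
}

# Disjoint maximal-scoring segments of a +1/-penalty match vector, found by
# best-segment extraction and recursion into the flanks.
maximal_segments <- function(score) {
  n <- length(score)
  if (n == 0L) return(NULL)
  best_segment <- function(lo, hi) {
    best <- c(0, NA, NA)
    cur <- 0
    cur_start <- lo
    for (i in lo:hi) {
      cur <- cur + score[i]
      if (cur > best[1]) best <- c(cur, cur_start, i)
      if (cur < 0) {
        cur <- 0
        cur_start <- i + 1L
      }
    }
    best
  }
  recurse <- function(lo, hi) {
    if (lo > hi) return(NULL)
    b <- best_segment(lo, hi)
    if (b[1] <= 0) return(NULL)
    rbind(recurse(lo, b[2] - 1L),
          data.frame(start = b[2], end = b[3], score = b[1]),
          recurse(b[3] + 1L, hi))
  }
  recurse(1L, n)
}

#' Maximal identity fragments for one sequence pair
#'
#' With an infinite mismatch penalty (the default), fragments are maximal
#' runs of identical polymorphic sites and the score is the run length. With
#' a finite penalty, fragments are the disjoint maximal-scoring segments
#' under +1 per match and -penalty per mismatch.
#'
#' @param x,y Character vectors over the condensed polymorphic columns (same
#'   length), or logical `x` of matches with `y` missing.
#' @param mismatch_penalty Positive penalty per mismatch, or `Inf`.
#' @return Data frame `start`, `end` (condensed-site indices), `score`;
#'   zero rows when there are no matching sites.
#' @export
pairwise_fragments <- function(x, y = NULL, mismatch_penalty = Inf) {
  match_vec <- if (is.null(y)) as.logical(x) else x == y
  if (length(match_vec) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), score = numeric(0)))
  }
  if (is.infinite(mismatch_penalty)) {
    r <- rle(match_vec)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    out <- data.frame(start = starts[keep], end = ends[keep],
                      score = r$lengths[keep])
  } else {
    out <- maximal_segments(ifelse(match_vec, 1, -mismatch_penalty))
    if (is.null(out)) {
      out <- data.frame(start = integer(0), end = integer(0),
                        score = numeric(0))
    }
  }
  out[order(-out$score), , drop = FALSE]
}

max_fragment_score <- function(match_vec, mismatch_penalty = Inf) {
  if (length(match_vec) == 0L) return(0)
  if (is.infinite(mismatch_penalty)) {
    r <- rle(match_vec)
    if (!any(r$values)) return(0)
    max(r$lengths[r$values])
  } else {
    best <- 0
    cur <- 0
    for (s in ifelse(match_vec, 1, -mismatch_penalty)) {
      cur <- max(0, cur + s)
      if (cur > best) best <- cur
    }
    best
  }
}

#' Permutation test for gene conversion
#'
#' For every ordered sequence pair, the observed maximal identity-fragment
#' score over polymorphic sites is compared with its null distribution under
#' random permutations of the condensed column order (columns shuffled
#' jointly across all sequences, preserving per-pair mismatch counts).
#' Pairwise p-values use the add-one estimator; the global p-value comes
#' from the permutation distribution of the maximum across pairs (exact
#' multiplicity handling under the shared null).
#'
#' @param aln Named character vector: aligned nucleotide sequences.
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed.
#' @param mismatch_penalty Fragment mismatch penalty (default `Inf`:
#'   mismatch-free fragments).
#' @return A `conversion_test` list: `pairs` (data.frame with fragment
#'   coordinates in original alignment columns, scores and p-values),
#'   `global_p`, `n_polymorphic`, `n_perm`, `seed`.
#' @export
conversion_test <- function(aln, n_perm = 1000L, seed = 1L,
                            mismatch_penalty = Inf) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  cond <- condense_polymorphic(aln)
  if (length(aln) == 2L) {
    # with a single pair every polymorphic column is a pair mismatch, so
    # identity runs are scored over all gap-free columns instead (the joint
    # column permutation null remains exact)
    m <- aln_matrix(aln)
    keep <- which(!apply(is_gap(m), 2, any))
    cond <- list(sites = keep, matrix = m[, keep, drop = FALSE])
  }
  S <- ncol(cond$matrix)
  nseq <- nrow(cond$matrix)
  pair_idx <- utils::combn(nseq, 2L)
  npair <- ncol(pair_idx)
  pair_names <- apply(pair_idx, 2, function(ij)
    paste(rownames(cond$matrix)[ij], collapse = ";"))
  if (S < 2L) {
    pairs <- data.frame(pair = pair_names, start = NA_integer_,
                        end = NA_integer_, length = 0L, score = 0,
                        p = 1, stringsAsFactors = FALSE)
    return(structure(list(pairs = pairs, global_p = 1, n_polymorphic = S,
                          n_perm = n_perm, seed = seed),
                     class = "conversion_test"))
  }
  match_mat <- matrix(FALSE, npair, S)
  for (k in seq_len(npair)) {
    match_mat[k, ] <- cond$matrix[pair_idx[1, k], ] ==
      cond$matrix[pair_idx[2, k], ]
  }
  obs <- numeric(npair)
  frag <- vector("list", npair)
  for (k in seq_len(npair)) {
    f <- pairwise_fragments(match_mat[k, ],
                            mismatch_penalty = mismatch_penalty)
    if (nrow(f) == 0L) {
      obs[k] <- 0
      frag[[k]] <- data.frame(start = NA_integer_, end = NA_integer_,
                              length = 0L)
    } else {
      obs[k] <- f$score[1]
      frag[[k]] <- data.frame(start = cond$sites[f$start[1]],
                              end = cond$sites[f$end[1]],
                              length = f$end[1] - f$start[1] + 1L)
    }
  }
  exceed <- integer(npair)
  exceed_max <- 0L
  obs_max <- max(obs)
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      perm <- sample.int(S)
      null_max <- 0
      for (k in seq_len(npair)) {
        sc <- max_fragment_score(match_mat[k, perm], mismatch_penalty)
        if (sc >= obs[k]) exceed[k] <- exceed[k] + 1L
        if (sc > null_max) null_max <- sc
      }
      if (null_max >= obs_max) exceed_max <- exceed_max + 1L
    }
  })
  pairs <- data.frame(pair = pair_names,
                      start = vapply(frag, function(f) f$start[1], numeric(1)),
                      end = vapply(frag, function(f) f$end[1], numeric(1)),
                      length = vapply(frag, function(f) f$length[1], numeric(1)),
                      score = obs,
                      p = (exceed + 1) / (n_perm + 1),
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, global_p = (exceed_max + 1) / (n_perm + 1),
                 n_polymorphic = S, n_perm = n_perm, seed = seed),
            class = "conversion_test")
}
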