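# GY94 codon-substitution machinery: rate-matrix construction, transition
# probabilities via eigendecomposition of the reversible generator, and the
# pruning (Felsenstein) likelihood over site patterns. Site-class mixtures
# and branch-specific (foreground/background) omega classes are layered on
# top of the same primitives.

#' GY94 codon rate matrix
#'
#' Builds the 61 x 61 Goldman-Yang codon rate generator. Off-diagonal rates
#' are zero for multi-position changes and otherwise proportional to the
#' target codon frequency times `kappa` for transitions and `omega` for
#' nonsynonymous changes. Rows sum to zero and the matrix is scaled so the
#' mean substitution rate at stationarity is 1 (branch lengths are then
#' expected substitutions per codon).
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param freqs Stationary codon frequencies (length 61, positive, sum 1) in
#'   the order of [codon_table()]`$codons`; default uniform.
#' @return 61 x 61 rate matrix with codon dimnames.
#' @export
gy94_rate_matrix <- function(kappa, omega, freqs = NULL) {
  tab <- codon_table()
  n <- length(tab$codons)
  if (is.null(freqs)) freqs <- rep(1 / n, n)
  if (length(freqs) != n || any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-6) {
    stop("freqs must be ", n, " positive values summing to 1")
  }
  if (kappa <= 0 || omega < 0) stop("invalid kappa/omega")
  single <- tab$ndiff == 1L
  rate <- matrix(0, n, n)
  rate[single] <- 1
  rate[single & tab$is_ts] <- kappa
  rate[single & !tab$is_syn] <- rate[single & !tab$is_syn] * omega
  q <- rate * rep(freqs, each = n)   # q_ij = rate_ij * pi_j
  diag(q) <- -rowSums(q)
  scale <- -sum(freqs * diag(q))
  if (scale > 0) q <- q / scale
  dimnames(q) <- list(tab$codons, tab$codons)
  q
}

# Eigendecomposition of a reversible generator via the symmetrized form
# S = D^{1/2} Q D^{-1/2}; returns factors for fast P(t) = A exp(L t) B.
gy94_eigen <- function(q, freqs) {
  sq <- sqrt(freqs)
  s <- q * (sq / rep(sq, each = length(sq)))
  s <- (s + t(s)) / 2
  e <- eigen(s, symmetric = TRUE)
  list(vals = e$values,
       a = e$vectors / sq,             # rows scaled: D^{-1/2} U
       b = t(e$vectors) * rep(sq, each = length(sq)))  # U' D^{1/2}
}

# Transition probability matrix P(t) from cached eigen factors.
gy94_pmat <- function(eig, t) {
  p <- (eig$a * rep(exp(eig$vals * t), each = nrow(eig$a))) %*% eig$b
  p[p < 0] <- 0
  p
}

#' Convert a codon alignment to an index matrix with pattern compression
#'
#' @param seqs Named character vector of equal-length coding sequences
#'   (lengths divisible by 3, no internal stop codons unless `allow_stop`).
#' @param allow_stop Keep columns containing stop/ambiguous codons as missing
#'   data instead of erroring.
#' @return List with `states` (taxa x patterns integer matrix, NA = missing),
#'   `weights` (pattern multiplicities), `index` (site -> pattern map),
#'   `labels` (taxon names), `n_codons`.
#' @export
codon_patterns <- function(seqs, allow_stop = FALSE) {
  if (length(unique(nchar(seqs))) != 1L) stop("sequences must be aligned")
  if (nchar(seqs[[1]]) %% 3L != 0L) stop("alignment length not divisible by 3")
  idx <- vapply(seqs, codon_indices, integer(nchar(seqs[[1]]) %/% 3L))
  idx <- t(idx)   # taxa x sites
  if (!allow_stop && anyNA(idx)) {
    gap <- vapply(seqs, function(s) grepl("-", s, fixed = TRUE), logical(1))
    if (!any(gap)) stop("alignment contains stop or ambiguous codons")
  }
  key <- apply(idx, 2, paste, collapse = ",")
  u <- !duplicated(key)
  states <- idx[, u, drop = FALSE]
  list(states = states, weights = as.vector(table(key)[key[u]]),
       index = match(key, key[u]), labels = rownames(idx),
       n_codons = ncol(idx))
}

# Postorder edge/tip bookkeeping for an ape tree, cached per call site.
tree_plan <- function(tree, labels) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!all(labels %in% tree$tip.label)) stop("alignment taxa missing from tree")
  tree <- ape::reorder.phylo(tree, "postorder")
  list(edge = tree$edge, len = tree$edge.length,
       ntip = length(tree$tip.label),
       root = tree$edge[nrow(tree$edge), 1],
       tipmap = match(tree$tip.label, labels),
       tree = tree)
}

# Per-site log-likelihood under one set of per-edge P matrices.
# pmats: list over edges (postorder). Returns log-lik per pattern.
prune_loglik <- function(plan, states, pmats, freqs) {
  npat <- ncol(states)
  nstate <- length(freqs)
  nnode <- max(plan$edge)
  partial <- vector("list", nnode)
  logscale <- rep(0, npat)
  tip_partial <- function(tip) {
    obs <- states[plan$tipmap[tip], ]
    l <- matrix(0, nstate, npat)
    known <- !is.na(obs)
    l[cbind(obs[known], which(known))] <- 1
    if (any(!known)) l[, !known] <- 1
    l
  }
  edge <- plan$edge
  for (i in seq_len(nrow(edge))) {
    child <- edge[i, 2]
    parent <- edge[i, 1]
    lchild <- if (child <= plan$ntip) tip_partial(child) else partial[[child]]
    up <- pmats[[i]] %*% lchild
    if (is.null(partial[[parent]])) partial[[parent]] <- up
    else partial[[parent]] <- partial[[parent]] * up
    if (child > plan$ntip) partial[child] <- list(NULL)
    if (i %% 8L == 0L || i == nrow(edge)) {
      mx <- apply(partial[[parent]], 2, max)
      mx[mx <= 0] <- 1
      partial[[parent]] <- partial[[parent]] / rep(mx, each = nstate)
      logscale <- logscale + log(mx)
    }
  }
  drop(log(freqs %*% partial[[plan$root]])) + logscale
}

# Mean substitution rate of the unscaled GY94 generator (used to put all
# site classes of a mixture on one common time scale, as codeml does:
# branch lengths are expected substitutions per codon under the mixture, so
# high-omega classes evolve proportionally faster).
gy94_raw_rate <- function(kappa, omega, freqs) {
  tab <- codon_table()
  single <- tab$ndiff == 1L
  rate <- matrix(0, nrow(single), ncol(single))
  rate[single] <- 1
  rate[single & tab$is_ts] <- kappa
  rate[single & !tab$is_syn] <- rate[single & !tab$is_syn] * omega
  q <- rate * rep(freqs, each = nrow(rate))
  sum(freqs * rowSums(q))
}

# Per-class branch-length multipliers for a mixture: class raw rates over
# the proportion-weighted mean background rate.
class_rate_multipliers <- function(kappa, classes, freqs) {
  props <- vapply(classes, `[[`, numeric(1), "prop")
  r_bg <- vapply(classes, function(cl) gy94_raw_rate(kappa, cl$omega, freqs),
                 numeric(1))
  r_fg <- vapply(classes, function(cl) {
    om <- if (is.null(cl$omega_fg)) cl$omega else cl$omega_fg
    gy94_raw_rate(kappa, om, freqs)
  }, numeric(1))
  cbar <- sum(props * r_bg)
  list(bg = r_bg / cbar, fg = r_fg / cbar)
}

# Site log-likelihood matrix for a set of omega classes (rows) given fixed
# kappa, freqs, tree plan and edge lengths. `fg` marks foreground edges; each
# class supplies omega (background) and optionally omega_fg. Classes share a
# common rate scale (see class_rate_multipliers).
class_site_logliks <- function(plan, states, kappa, classes, freqs,
                               lengths = plan$len, fg = NULL) {
  out <- matrix(0, length(classes), ncol(states))
  cache <- list()
  mult <- class_rate_multipliers(kappa, classes, freqs)
  get_eig <- function(om) {
    key <- sprintf("%.12g", om)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- gy94_eigen(gy94_rate_matrix(kappa, om, freqs), freqs)
    }
    cache[[key]]
  }
  for (k in seq_along(classes)) {
    cl <- classes[[k]]
    om_fg <- if (is.null(cl$omega_fg)) cl$omega else cl$omega_fg
    eig_bg <- get_eig(cl$omega)
    eig_fg <- get_eig(om_fg)
    pmats <- vector("list", nrow(plan$edge))
    for (i in seq_len(nrow(plan$edge))) {
      use_fg <- !is.null(fg) && fg[i]
      pmats[[i]] <- if (use_fg) gy94_pmat(eig_fg, lengths[i] * mult$fg[k])
                    else gy94_pmat(eig_bg, lengths[i] * mult$bg[k])
    }
    out[k, ] <- prune_loglik(plan, states, pmats, freqs)
  }
  out
}

# Mixture log-likelihood over patterns: props (K), site_ll (K x npat).
mixture_loglik <- function(props, site_ll, weights) {
  m <- apply(site_ll, 2, max)
  l <- log(colSums(props * exp(sweep(site_ll, 2, m)))) + m
  sum(l * weights)
}

#' Empirical codon frequencies from an alignment
#'
#' @param seqs Aligned coding sequences.
#' @param model `"F61"` (observed codon frequencies), `"F3X4"` (products of
#'   position-specific nucleotide frequencies, renormalized over sense
#'   codons), or `"F1X4"`.
#' @return Length-61 frequency vector.
#' @export
codon_frequencies <- function(seqs, model = c("F3X4", "F1X4", "F61")) {
  model <- match.arg(model)
  tab <- codon_table()
  cods <- unlist(lapply(seqs, split_codons))
  cods <- cods[cods %in% tab$codons]
  if (model == "F61") {
    f <- table(factor(cods, levels = tab$codons))
    f <- as.numeric(f) + 0.5   # small prior keeps frequencies positive
    return(f / sum(f))
  }
  m <- do.call(rbind, strsplit(cods, ""))
  nt <- c("A", "C", "G", "T")
  if (model == "F1X4") {
    p <- table(factor(m, levels = nt)) + 0.5
    p <- as.numeric(p / sum(p))
    pos <- list(p, p, p)
  } else {
    pos <- lapply(1:3, function(j) {
      p <- table(factor(m[, j], levels = nt)) + 0.5
      as.numeric(p / sum(p))
    })
  }
  cm <- do.call(rbind, strsplit(tab$codons, ""))
  f <- pos[[1]][match(cm[, 1], nt)] * pos[[2]][match(cm[, 2], nt)] *
    pos[[3]][match(cm[, 3], nt)]
  f / sum(f)
}
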