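# Shared fixtures and independent oracles used across the suite. Everything
# is generated in code; no stored data files.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
NT4 <- c("A", "C", "G", "T")

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(c("M", sample(AA20, n - 1L, replace = TRUE)), collapse = "")
}

random_dna_str <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(NT4, n, replace = TRUE), collapse = "")
}

# Point-mutate a sequence with per-site probability p (alphabet inferred).
mutate_seq <- function(s, p, alphabet = NT4) {
  v <- strsplit(s, "")[[1]]
  hit <- stats::runif(length(v)) < p
  v[hit] <- vapply(v[hit], function(x) sample(setdiff(alphabet, x), 1L), "")
  paste(v, collapse = "")
}

# Independent duplication-loss parsimony oracle: exhaustive search over all
# valid gene-node -> species-node assignments (each internal gene node may
# map to any ancestor-or-equal of its children's LCA). A node is a
# duplication iff a child maps to the same node or it maps strictly above
# its children's LCA; per-edge losses follow the standard path-length rule.
brute_force_dl_cost <- function(gene_tree, species_tree, species_map) {
  stt <- chemorep:::tree_tables(species_tree)
  gtt <- chemorep:::tree_tables(gene_tree)
  anc <- matrix(FALSE, stt$nnode, stt$nnode)
  for (n in seq_len(stt$nnode)) {
    x <- n
    while (!is.na(x)) { anc[x, n] <- TRUE; x <- stt$parent[x] }
  }
  M0 <- integer(gtt$nnode)
  for (n in rev(gtt$preorder)) {
    ch <- gtt$kids[[as.character(n)]]
    if (is.null(ch)) {
      M0[n] <- match(species_map[[gene_tree$tip.label[n]]],
                     species_tree$tip.label)
    } else {
      M0[n] <- chemorep:::lca_pair(stt, M0[ch[1]], M0[ch[2]])
    }
  }
  internals <- which(seq_len(gtt$nnode) > gtt$ntip)
  cands <- lapply(internals, function(n) which(anc[, M0[n]]))
  dup_of <- function(M, v) {
    ch <- gtt$kids[[as.character(v)]]
    if (is.null(ch)) return(FALSE)
    any(M[ch] == M[v]) ||
      M[v] != chemorep:::lca_pair(stt, M[ch[1]], M[ch[2]])
  }
  best <- Inf
  assign_cost <- function(M) {
    dups <- 0L; losses <- 0L
    for (v in seq_len(gtt$nnode)) {
      if (dup_of(M, v)) dups <- dups + 1L
      u <- gtt$parent[v]
      if (!is.na(u)) {
        if (!anc[M[u], M[v]]) return(Inf)
        l <- stt$depth[M[v]] - stt$depth[M[u]] - 1L + dup_of(M, u)
        if (l < 0) return(Inf)
        losses <- losses + l
      }
    }
    dups + losses
  }
  recurse <- function(i, M) {
    if (i > length(internals)) {
      cst <- assign_cost(M)
      if (cst < best) best <<- cst
      return(invisible())
    }
    for (s in cands[[i]]) {
      M[internals[i]] <- s
      recurse(i + 1L, M)
    }
  }
  recurse(1L, M0)
  best
}

# Brute-force codon likelihood by summing over all internal-state
# combinations (trees with <= 4 leaves).
brute_force_codon_loglik <- function(seqs, tree, kappa, omega, freqs) {
  pat <- codon_patterns(seqs)
  plan <- chemorep:::tree_plan(tree, pat$labels)
  eig <- chemorep:::gy94_eigen(gy94_rate_matrix(kappa, omega, freqs), freqs)
  pmats <- lapply(plan$len, function(t) chemorep:::gy94_pmat(eig, t))
  nnode <- max(plan$edge)
  internal <- (plan$ntip + 1L):nnode
  n_int <- length(internal)
  combos <- as.matrix(do.call(expand.grid, rep(list(seq_len(61L)), n_int)))
  per_site <- function(obs) {
    state_of <- function(node) {
      if (node <= plan$ntip) rep(obs[node], nrow(combos))
      else combos[, match(node, internal)]
    }
    pr <- freqs[state_of(plan$root)]
    for (i in seq_len(nrow(plan$edge))) {
      pr <- pr * pmats[[i]][cbind(state_of(plan$edge[i, 1]),
                                  state_of(plan$edge[i, 2]))]
    }
    log(sum(pr))
  }
  ll <- vapply(seq_len(ncol(pat$states)), function(j) {
    obs <- pat$states[plan$tipmap, j]
    per_site(obs)
  }, numeric(1))
  sum(ll * pat$weights)
}
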