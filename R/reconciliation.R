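# Duplication-loss parsimony reconciliation of a gene tree against a species
# tree via the LCA mapping: a gene node is a duplication iff one of its
# children maps to the same species node; losses are read off the species
# path each gene lineage traverses. Events are aggregated per species branch
# together with ancestral copy numbers, and the per-branch conservation
# identity child = parent + gains - losses holds by construction.

# Lightweight rooted-tree tables from an ape phylo.
tree_tables <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  parent <- integer(nnode)
  parent[] <- NA_integer_
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  depth <- integer(nnode)
  root <- ntip + 1L
  ord <- root
  i <- 1L
  while (i <= length(ord)) {
    n <- ord[i]
    ch <- kids[[as.character(n)]]
    if (!is.null(ch)) {
      depth[ch] <- depth[n] + 1L
      ord <- c(ord, ch)
    }
    i <- i + 1L
  }
  list(ntip = ntip, nnode = nnode, parent = parent, kids = kids,
       depth = depth, root = root, preorder = ord,
       labels = c(tree$tip.label, paste0("node", (ntip + 1L):nnode)))
}

lca_pair <- function(tt, a, b) {
  while (a != b) {
    if (tt$depth[a] >= tt$depth[b]) a <- tt$parent[a] else b <- tt$parent[b]
  }
  a
}

# Default leaf -> species map: strip a trailing _g<digits> copy suffix, else
# take the prefix before the last underscore.
default_species_map <- function(gene_labels) {
  sp <- sub("_g[0-9]+$", "", gene_labels)
  left <- sp == gene_labels & grepl("_", gene_labels)
  sp[left] <- sub("_[^_]*$", "", gene_labels[left])
  stats::setNames(sp, gene_labels)
}

#' Duplication-loss parsimony reconciliation
#'
#' Reconciles a binary gene tree against a binary rooted species tree under
#' the LCA mapping. Returns per-species-branch gains (duplications assigned
#' to the branch above their mapped node), losses, and parent/child-side
#' copy numbers, plus the total event cost. With `rooting = "minimize"` all
#' rootings of the (unrooted) gene tree are tried and the one of minimum
#' duplication+loss cost is kept (ties broken by the lexicographically
#' smallest root split).
#'
#' @param gene_tree Binary gene tree ([ape::phylo]) with species-mappable
#'   leaf labels.
#' @param species_tree Binary rooted species tree.
#' @param rooting `"fixed"` (use the gene tree as given) or `"minimize"`.
#' @param species_map Named character vector mapping gene leaf labels to
#'   species leaf labels; default strips a `_g<number>` suffix (falling back
#'   to the prefix before the last underscore).
#' @param dup_cost,loss_cost Event costs used for the total (rooting choice
#'   and reported cost only; the event counts themselves are cost-free LCA
#'   bookkeeping).
#' @return A `reconciliation` list: `events` (per-branch table including a
#'   synthetic `root` row), `total_dups`, `total_losses`, `cost`,
#'   `ancestral_counts` (copy number at each species node), `mapping`
#'   (species node index per gene node), `root_split`.
#' @export
reconcile_dl <- function(gene_tree, species_tree,
                         rooting = c("fixed", "minimize"),
                         species_map = NULL, dup_cost = 1, loss_cost = 1) {
  rooting <- match.arg(rooting)
  if (!ape::is.binary(species_tree)) stop("species tree must be binary")
  if (length(gene_tree$tip.label) >= 3L && !ape::is.binary(gene_tree)) {
    stop("unsupported topology: gene tree has polytomies")
  }
  if (is.null(species_map)) {
    species_map <- default_species_map(gene_tree$tip.label)
  }
  unmapped <- setdiff(unname(species_map[gene_tree$tip.label]),
                      species_tree$tip.label)
  if (length(unmapped) > 0L) {
    stop("gene leaves map to unknown species: ",
         paste(unique(unmapped), collapse = ", "))
  }
  if (rooting == "fixed") {
    return(reconcile_rooted(gene_tree, species_tree, species_map,
                            dup_cost, loss_cost))
  }
  cands <- all_rootings(gene_tree)
  best <- NULL
  for (cand in cands) {
    r <- reconcile_rooted(cand$tree, species_tree, species_map,
                          dup_cost, loss_cost)
    r$root_split <- cand$key
    if (is.null(best) || r$cost < best$cost ||
        (r$cost == best$cost && cand$key < best$root_split)) {
      best <- r
    }
  }
  best
}

# All rootings of a gene tree: one rooted tree per edge of the unrooted
# topology, keyed by the sorted smaller-side tip set.
all_rootings <- function(tree) {
  if (length(tree$tip.label) < 3L) {
    return(list(list(tree = tree, key = paste(sort(tree$tip.label),
                                              collapse = "|"))))
  }
  un <- ape::unroot(tree)
  if (is.null(un$edge.length)) un$edge.length <- rep(1, nrow(un$edge))
  tt <- tree_tables(un)
  desc <- vector("list", tt$nnode)
  for (i in seq_len(tt$ntip)) desc[[i]] <- un$tip.label[i]
  for (n in rev(tt$preorder)) {
    ch <- tt$kids[[as.character(n)]]
    if (!is.null(ch)) desc[[n]] <- sort(unlist(desc[ch]))
  }
  all_tips <- sort(un$tip.label)
  out <- list()
  seen <- character(0)
  for (k in seq_len(nrow(un$edge))) {
    child <- un$edge[k, 2]
    side <- desc[[child]]
    other <- setdiff(all_tips, side)
    small <- if (length(side) < length(other) ||
                 (length(side) == length(other) &&
                  paste(side, collapse = "|") < paste(other, collapse = "|")))
      side else other
    key <- paste(small, collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    rooted <- if (length(side) == 1L) {
      ape::root(un, outgroup = side, resolve.root = TRUE)
    } else {
      tryCatch(ape::root(un, outgroup = side, resolve.root = TRUE),
               error = function(e) NULL)
    }
    if (is.null(rooted) || !ape::is.rooted(rooted)) next
    out[[length(out) + 1L]] <- list(tree = rooted, key = key)
  }
  out
}

reconcile_rooted <- function(gene_tree, species_tree, species_map,
                             dup_cost, loss_cost) {
  st <- tree_tables(species_tree)
  gt <- tree_tables(gene_tree)
  # LCA mapping, postorder
  M <- integer(gt$nnode)
  for (n in rev(gt$preorder)) {
    ch <- gt$kids[[as.character(n)]]
    if (is.null(ch)) {
      sp <- species_map[[gene_tree$tip.label[n]]]
      M[n] <- match(sp, species_tree$tip.label)
    } else {
      M[n] <- lca_pair(st, M[ch[1]], M[ch[2]])
    }
  }
  is_dup <- rep(FALSE, gt$nnode)
  for (n in gt$preorder) {
    ch <- gt$kids[[as.character(n)]]
    if (!is.null(ch)) is_dup[n] <- any(M[ch] == M[n])
  }
  nsp <- st$nnode
  gains <- losses <- alive <- integer(nsp)
  # gains: duplications assigned to the branch above their mapped node
  for (n in which(is_dup)) gains[M[n]] <- gains[M[n]] + 1L
  sibling <- function(t, child) {
    ch <- st$kids[[as.character(t)]]
    ch[ch != child]
  }
  tips_per_species <- integer(st$ntip)
  for (n in seq_len(gt$ntip)) {
    tips_per_species[M[n]] <- tips_per_species[M[n]] + 1L
  }
  origin <- M[gt$root]   # events are counted at/below the gene root's mapping
  for (v in seq_len(gt$nnode)) {
    u <- gt$parent[v]
    mv <- M[v]
    top <- if (is.na(u)) mv else M[u]
    top_inclusive <- if (is.na(u)) FALSE else is_dup[u]
    # crossings at species nodes t with mv < t (strict), t <= top
    # (inclusive only when the edge starts inside the branch above top)
    t <- mv
    while (t != top) {
      t <- st$parent[t]
      if (is.na(t)) break
      if (t == top && !top_inclusive) break
      alive[t] <- alive[t] + 1L
      # loss on the off-path child branch
      path_child <- path_child_toward(st, t, mv)
      off <- sibling(t, path_child)
      losses[off] <- losses[off] + 1L
    }
    # edge terminates at mv (alive at that speciation) unless v is a dup
    if (!is_dup[v] && mv > st$ntip) alive[mv] <- alive[mv] + 1L
  }
  # per-branch table: copy numbers at species nodes are counted directly
  # (crossings + terminations), so the conservation identity is checkable.
  rows <- list()
  counts <- integer(nsp)
  counts[st$root] <- if (origin == st$root) alive[st$root] else 0L
  for (n in st$preorder[-1]) {
    t <- st$parent[n]
    child_count <- if (n <= st$ntip) tips_per_species[n] else alive[n]
    parent_side <- if (n == origin) 1L else counts[t]
    rows[[length(rows) + 1L]] <- data.frame(
      parent = t, child = n,
      branch = if (n <= st$ntip) species_tree$tip.label[n] else
        paste0("node", n),
      gains = gains[n], losses = losses[n],
      parent_count = parent_side, child_count = child_count,
      stringsAsFactors = FALSE)
    counts[n] <- child_count
  }
  events <- do.call(rbind, rows)
  if (origin == st$root) {
    events <- rbind(data.frame(parent = NA_integer_, child = st$root,
                               branch = "root", gains = gains[st$root],
                               losses = 0L, parent_count = 1L,
                               child_count = alive[st$root],
                               stringsAsFactors = FALSE),
                    events)
  }
  total_dups <- sum(is_dup)
  total_losses <- sum(losses)
  structure(list(events = events,
                 total_dups = total_dups, total_losses = total_losses,
                 cost = dup_cost * total_dups + loss_cost * total_losses,
                 ancestral_counts = counts, mapping = M,
                 species_tree = species_tree, gene_tree = gene_tree,
                 root_split = paste(sort(gene_tree$tip.label), collapse = "|")),
            class = "reconciliation")
}

# Child of species node t on the path toward descendant node target.
path_child_toward <- function(st, t, target) {
  x <- target
  while (!is.na(st$parent[x]) && st$parent[x] != t) x <- st$parent[x]
  x
}

#' Per-branch event table of a reconciliation
#'
#' One row per species branch with gains, losses, and parent/child-side copy
#' numbers; the conservation identity `child = parent + gains - losses` is
#' asserted on every row.
#'
#' @param result A `reconciliation` from [reconcile_dl()].
#' @return The `events` data frame.
#' @export
event_table <- function(result) {
  ev <- result$events
  ok <- ev$child_count == ev$parent_count + ev$gains - ev$losses
  if (!all(ok)) stop("conservation identity violated on branch ",
                     ev$branch[which(!ok)[1]])
  if (any(ev$parent_count < 0) || any(ev$child_count < 0)) {
    stop("negative copy number in event table")
  }
  ev
}
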