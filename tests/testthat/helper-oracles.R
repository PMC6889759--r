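# Independent brute-force oracles. These deliberately avoid the package's
# own algorithms: Dollo losses by exhaustive enumeration of loss-edge
# subsets, reconciliation by exhaustive enumeration of valid internal-node
# mappings, and exhaustive generation of small rooted gene trees.

# --- Dollo ----------------------------------------------------------------

# minimum number of losses over all single-gain explanations of `present`
dollo_brute_min_losses <- function(tree, present) {
  n_tip <- ape::Ntip(tree)
  labs <- c(tree$tip.label, tree$node.label)
  par <- integer(n_tip + tree$Nnode)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  present_idx <- match(present, tree$tip.label)
  path_to_root <- function(v) {
    p <- v
    while (par[v] != 0L) { v <- par[v]; p <- c(p, v) }
    p
  }
  best <- Inf
  for (g in seq_len(n_tip + tree$Nnode)) {
    below <- which(vapply(seq_len(n_tip), function(t) g %in% path_to_root(t),
                          logical(1)))
    if (!all(present_idx %in% below)) next
    # edges strictly below g, identified by child node
    children_below <- setdiff(
      which(vapply(seq_along(par), function(v)
        v != g && par[v] != 0L && g %in% path_to_root(v), logical(1))), g)
    k <- length(children_below)
    for (mask in 0:(2^k - 1)) {
      lost <- children_below[bitwAnd(bitwShiftR(mask, seq_len(k) - 1L), 1L) == 1L]
      state <- vapply(seq_len(n_tip), function(t) {
        p <- path_to_root(t)
        if (!(g %in% p)) return(FALSE)
        p_below <- p[seq_len(which(p == g) - 1L)]
        !any(p_below %in% lost)
      }, logical(1))
      if (identical(which(state), sort(present_idx))) {
        best <- min(best, length(lost))
      }
    }
  }
  best
}

# --- reconciliation -------------------------------------------------------

# minimum duplications + losses over all valid mappings of internal gene
# nodes to species nodes (each node mapped to an ancestor-or-equal of its
# children's images; leaves fixed to their species)
reconcile_brute <- function(gene_tree, species_tree, sp_of_leaf) {
  st <- species_tree
  s_ntip <- ape::Ntip(st)
  s_n <- s_ntip + st$Nnode
  s_par <- integer(s_n); s_par[st$edge[, 2]] <- st$edge[, 1]
  s_depth <- integer(s_n)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(st$edge))) {
      p <- st$edge[i, 1]; c <- st$edge[i, 2]
      if (s_depth[c] != s_depth[p] + 1L) { s_depth[c] <- s_depth[p] + 1L; changed <- TRUE }
    }
    if (!changed) break
  }
  is_anc <- function(a, b) {  # a ancestor-or-equal of b
    while (TRUE) {
      if (a == b) return(TRUE)
      if (s_par[b] == 0L) return(FALSE)
      b <- s_par[b]
    }
  }
  gt <- gene_tree
  g_ntip <- ape::Ntip(gt)
  g_n <- g_ntip + gt$Nnode
  g_children <- split(gt$edge[, 2], factor(gt$edge[, 1], levels = seq_len(g_n)))
  internal <- setdiff(seq_len(g_n), seq_len(g_ntip))
  leaf_map <- match(sp_of_leaf, st$tip.label)
  s_lca <- function(a, b) {
    while (a != b) if (s_depth[a] > s_depth[b]) a <- s_par[a] else b <- s_par[b]
    a
  }
  cost_of <- function(map) {
    dups <- 0L; losses <- 0L
    for (v in internal) {
      ch <- g_children[[v]]
      for (c in ch) if (!is_anc(map[v], map[c])) return(Inf)
      # speciation iff the children's images lie strictly below map[v] in
      # distinct child subtrees (their LCA is then exactly map[v]);
      # anything else is a duplication
      l <- Reduce(s_lca, map[ch])
      dup <- !(l == map[v] && all(map[ch] != map[v]))
      if (dup) dups <- dups + 1L
      for (c in ch) {
        l <- s_depth[map[c]] - s_depth[map[v]] - 1L
        if (dup && map[c] != map[v]) l <- l + 1L
        if (l > 0L) losses <- losses + l
      }
    }
    dups + losses
  }
  grids <- rep(list(seq_len(s_n)), length(internal))
  combos <- do.call(expand.grid, grids)
  best <- Inf
  map <- integer(g_n)
  map[seq_len(g_ntip)] <- leaf_map
  for (r in seq_len(nrow(combos))) {
    map[internal] <- as.integer(combos[r, ])
    best <- min(best, cost_of(map))
  }
  best
}

# all rooted binary topologies (as newick strings) on the given leaf labels
all_rooted_topologies <- function(leaves) {
  if (length(leaves) == 1L) return(leaves)
  out <- character()
  n <- length(leaves)
  # split sets containing leaf 1, to count each unordered split once
  for (mask in 0:(2^(n - 1L) - 1L)) {
    left_sel <- c(TRUE, bitwAnd(bitwShiftR(mask, seq_len(n - 1L) - 1L), 1L) == 1L)
    if (all(left_sel)) next
    left <- all_rooted_topologies(leaves[left_sel])
    right <- all_rooted_topologies(leaves[!left_sel])
    for (l in left) for (r in right) {
      out <- c(out, paste0("(", l, ",", r, ")"))
    }
  }
  out
}
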