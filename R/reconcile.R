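# Duplication-loss gene-tree/species-tree reconciliation by LCA mapping,
# and its use to discriminate allo- from autopolyploid origin of extra
# gene copies. The full multi-labelled-tree search of dedicated polyploid
# reconcilers is deliberately reduced here to grafting a single DONOR leaf
# on every edge of the species tree and asking which graft minimises the
# summed duplication + loss cost when the parthenogens' extra copies are
# assigned to the donor: sufficient to separate "the extra copies come
# from an external lineage" (allopolyploidy) from "each species duplicated
# its own copy" (autopolyploidy).

#' LCA duplication-loss reconciliation
#'
#' Maps every gene-tree node to the LCA of its leaves' species. An
#' internal gene node is a duplication iff its mapping equals the mapping
#' of one of its children. Losses are counted per child edge as
#' `depth(M(child)) - depth(M(node)) - 1`, plus one more when the node is
#' a duplication and the child maps strictly below it; each term is
#' floored at zero.
#'
#' @param gene_tree rooted `phylo`; leaves labelled `SPECIES|copyN` or
#'   with bare species names.
#' @param species_tree rooted `phylo` whose tips are species.
#' @param leaf_map optional named character vector mapping gene-tree leaf
#'   labels to species-tree tip labels; by default the text before `|` in
#'   each leaf label is used.
#' @return named integer vector `c(duplications = , losses = )`.
#' @export
lca_reconcile <- function(gene_tree, species_tree, leaf_map = NULL) {
  if (!ape::is.rooted(gene_tree) || !ape::is.rooted(species_tree)) {
    stop("both trees must be rooted")
  }
  tabs <- tree_tables(species_tree)
  sp <- gene_leaf_species(gene_tree, leaf_map)
  sp_idx <- match(sp, species_tree$tip.label)
  if (anyNA(sp_idx)) {
    stop("gene leaves map to unknown species: ",
         paste(unique(sp[is.na(sp_idx)]), collapse = ", "))
  }
  counts <- reconcile_counts(gene_tree, tabs, sp_idx)
  c(duplications = counts[1L], losses = counts[2L])
}

# species of each gene leaf, in tip order
gene_leaf_species <- function(gene_tree, leaf_map = NULL) {
  if (!is.null(leaf_map)) {
    sp <- unname(leaf_map[gene_tree$tip.label])
    if (anyNA(sp)) {
      stop("leaf_map misses gene leaves: ",
           paste(gene_tree$tip.label[is.na(sp)], collapse = ", "))
    }
    sp
  } else {
    sub("\\|.*$", "", gene_tree$tip.label)
  }
}

# fast core: tabs from tree_tables(species_tree); sp_idx = species-tree tip
# number of each gene leaf
reconcile_counts <- function(gene_tree, tabs, sp_idx) {
  edge <- ape::reorder.phylo(gene_tree, "postorder")$edge
  n_tip <- ape::Ntip(gene_tree)
  n <- n_tip + gene_tree$Nnode
  map <- integer(n)
  map[seq_len(n_tip)] <- sp_idx
  dup <- logical(n)
  dups <- 0L; losses <- 0L
  # process internal nodes in postorder via grouped edges
  parents <- edge[, 1L]
  for (i in seq_len(nrow(edge))) {
    # when we hit the last edge of a parent group, its children are mapped
    if (i < nrow(edge) && parents[i + 1L] == parents[i]) next
    v <- parents[i]
    ch <- edge[parents == v, 2L]
    m <- map[ch[1L]]
    for (c in ch[-1L]) m <- tabs$lca[m, map[c]]
    map[v] <- m
    dup[v] <- any(map[ch] == m)
    if (dup[v]) dups <- dups + 1L
    for (c in ch) {
      l <- tabs$depth[map[c]] - tabs$depth[m] - 1L
      if (dup[v] && map[c] != m) l <- l + 1L
      if (l > 0L) losses <- losses + l
    }
  }
  c(dups, losses)
}

#' Enumerate donor-graft hypotheses on a species tree
#'
#' One candidate per edge of the rooted species tree (terminal edges
#' included, the nonexistent edge above the root excluded): a new leaf
#' `DONOR` attached midway along that edge. Edge ids are the labels of
#' each edge's child node, which are stable and deterministic after
#' [ensure_node_labels()]. The input tree is not modified.
#'
#' @param species_tree rooted `phylo` with at least 3 tips.
#' @return named list of grafted `phylo` trees; names are edge ids.
#' @export
graft_candidates <- function(species_tree) {
  stopifnot(ape::Ntip(species_tree) >= 3L)
  tree <- ensure_node_labels(species_tree)
  if (is.null(tree$edge.length)) tree <- ape::compute.brlen(tree, 1)
  labs <- node_labels(tree)
  donor <- ape::read.tree(text = "(DONOR:0.5);")
  out <- lapply(seq_len(nrow(tree$edge)), function(i) {
    child <- tree$edge[i, 2L]
    g <- ape::bind.tree(tree, donor, where = child,
                        position = tree$edge.length[i] / 2)
    g$node.label[!nzchar(g$node.label) | is.na(g$node.label)] <- "GRAFT"
    g
  })
  names(out) <- labs[tree$edge[, 2L]]
  out
}

#' Score donor placements and call the polyploid origin
#'
#' For every graft candidate, every gene tree is reconciled against the
#' grafted species tree with the parthenogens' extra copies (copy index
#' >= 2) re-mapped to the DONOR leaf, at cost duplications + losses. The
#' per-edge cost is summed over gene trees; the minimising edge gives the
#' verdict: `auto` if it lies within the parthenogen clade (a parthenogen
#' terminal edge or any edge below their MRCA), `allo` if it lies outside
#' the congener clade (on the path between the outgroups and the ingroup
#' crown, or on an outgroup lineage), `ambiguous` otherwise or on a tie
#' spanning both classes. Unrooted gene trees are rooted on the species
#' tree's earliest-diverging outgroup; trees without extra copies (or
#' without an outgroup leaf to root on) are skipped with a warning.
#'
#' @param gene_trees list/`multiPhylo` of gene trees with `SPECIES|copyN`
#'   leaf labels.
#' @param species_tree rooted `phylo`.
#' @param parthenogens tip labels of the species carrying extra copies.
#' @param congeners tip labels of the clade of congeneric species
#'   (parthenogens plus their sexual sister species); defaults to the
#'   tips below the parent of the parthenogens' MRCA.
#' @return an object of class `placement_result`: list with `per_edge`
#'   (`data.frame` of `edge_id`, `edge_class`, `total_cost`, `n_trees`),
#'   `best_edge`, `verdict`, `margin`, `n_trees_used`, `n_trees_skipped`.
#' @export
score_placements <- function(gene_trees, species_tree, parthenogens,
                             congeners = NULL) {
  species_tree <- ensure_node_labels(species_tree)
  stopifnot(all(parthenogens %in% species_tree$tip.label))
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)

  candidates <- graft_candidates(species_tree)
  tabs_list <- lapply(candidates, tree_tables)
  tips_list <- lapply(candidates, function(g) g$tip.label)

  # verdict class of each candidate edge, judged on the original tree
  parth_mrca <- mrca_node(species_tree, parthenogens)
  parth_set <- which(in_subtree(species_tree, parth_mrca))
  if (is.null(congeners)) {
    par <- node_parents(species_tree)
    anc <- par[parth_mrca]
    congeners <- if (anc == 0L) species_tree$tip.label
                 else tips_below(species_tree, anc)
  }
  cong_mrca <- mrca_node(species_tree, congeners)
  cong_set <- which(in_subtree(species_tree, cong_mrca))
  edge_child <- node_number(species_tree, names(candidates))
  edge_class <- ifelse(edge_child %in% parth_set, "auto",
                ifelse(!(edge_child %in% setdiff(cong_set, cong_mrca)),
                       "allo", "other"))

  # earliest-diverging outgroup (for rooting unrooted gene trees): the
  # smaller side of the root split
  root_kids <- node_children(species_tree)[[ape::Ntip(species_tree) + 1L]]
  og_tips <- tips_below(species_tree,
                        root_kids[which.min(vapply(root_kids, function(k)
                          length(tips_below(species_tree, k)), integer(1)))])

  totals <- stats::setNames(numeric(length(candidates)), names(candidates))
  used <- 0L; skipped <- 0L
  for (gt in gene_trees) {
    lab <- gt$tip.label
    sp <- sub("\\|.*$", "", lab)
    copy <- suppressWarnings(as.integer(sub("^.*\\|copy", "", lab)))
    copy[is.na(copy)] <- 1L
    extra <- copy >= 2L & sp %in% parthenogens
    if (!any(extra)) {
      warning("gene tree without extra parthenogen copies skipped")
      skipped <- skipped + 1L
      next
    }
    if (!ape::is.rooted(gt)) {
      og <- lab[sp %in% og_tips]
      if (length(og) == 0L) {
        warning("unrooted gene tree without outgroup leaf skipped")
        skipped <- skipped + 1L
        next
      }
      gt <- ape::root(gt, outgroup = og, resolve.root = TRUE)
    }
    sp_mapped <- ifelse(extra, "DONOR", sp)
    for (j in seq_along(candidates)) {
      sp_idx <- match(sp_mapped, tips_list[[j]])
      counts <- reconcile_counts(gt, tabs_list[[j]], sp_idx)
      totals[j] <- totals[j] + counts[1L] + counts[2L]
    }
    used <- used + 1L
  }

  per_edge <- data.frame(edge_id = names(candidates), edge_class = edge_class,
                         total_cost = unname(totals), n_trees = used,
                         stringsAsFactors = FALSE)
  per_edge <- per_edge[order(per_edge$total_cost, per_edge$edge_id), ]
  rownames(per_edge) <- NULL
  if (used == 0L) {
    verdict <- "ambiguous"; best <- NA_character_; margin <- NA_real_
  } else {
    best_cost <- per_edge$total_cost[1L]
    at_best <- per_edge[per_edge$total_cost == best_cost, , drop = FALSE]
    best <- at_best$edge_id[1L]
    classes <- unique(at_best$edge_class)
    verdict <- if (length(classes) == 1L && classes %in% c("allo", "auto"))
      classes else "ambiguous"
    others <- per_edge$total_cost[per_edge$total_cost > best_cost]
    margin <- if (length(others)) min(others) - best_cost else 0
  }
  structure(list(per_edge = per_edge, best_edge = best, verdict = verdict,
                 margin = margin, n_trees_used = used,
                 n_trees_skipped = skipped),
            class = "placement_result")
}

#' @export
print.placement_result <- function(x, ...) {
  cat("Polyploid-origin placement over", x$n_trees_used, "gene trees\n")
  cat("  verdict:", x$verdict, "  best edge:", x$best_edge,
      "  margin:", x$margin, "\n")
  invisible(x)
}
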