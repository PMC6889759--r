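# Rooted-tree utilities shared by the Dollo, reconciliation and simulation
# code. All trees are ape "phylo" objects; functions here assume (and check)
# rootedness where it matters.

#' Deterministically label unlabeled internal nodes
#'
#' Internal nodes without a label are named `N<k>` where `k` is the node's
#' position in a postorder traversal. Existing labels are kept, so repeated
#' application is a no-op. Node labels are used throughout the package as
#' stable identifiers for nodes and for the edges above them.
#'
#' @param tree an ape `phylo` object, rooted.
#' @return the tree with a complete, unique `node.label` vector.
#' @export
ensure_node_labels <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  n_tip <- ape::Ntip(tree)
  labs <- tree$node.label
  if (is.null(labs)) labs <- rep(NA_character_, tree$Nnode)
  labs[!nzchar(labs)] <- NA_character_
  post <- postorder_nodes(tree)
  post_int <- post[post > n_tip]
  for (k in seq_along(post_int)) {
    i <- post_int[k] - n_tip
    if (is.na(labs[i])) labs[i] <- paste0("N", k)
  }
  if (anyDuplicated(c(tree$tip.label, labs))) {
    stop("node labels collide with tip labels or each other")
  }
  tree$node.label <- labs
  tree
}

# Node numbers (tips and internal) in postorder: children before parents.
postorder_nodes <- function(tree) {
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  root <- setdiff(edge[, 1], edge[, 2])
  c(edge[, 2], root)
}

# parent[i] = parent node number of node i (0 for the root)
node_parents <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  par <- integer(n)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

# children as a list indexed by node number
node_children <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  split(tree$edge[, 2], factor(tree$edge[, 1], levels = seq_len(n)))
}

# label for every node number (tips then internals)
node_labels <- function(tree) {
  c(tree$tip.label, tree$node.label)
}

# node number for a tip or internal label; errors on unknown labels
node_number <- function(tree, label) {
  labs <- node_labels(tree)
  idx <- match(label, labs)
  if (anyNA(idx)) {
    stop("unknown node label(s): ", paste(label[is.na(idx)], collapse = ", "))
  }
  idx
}

# logical vector: is node i inside (or equal to) the subtree rooted at `node`
in_subtree <- function(tree, node) {
  n <- ape::Ntip(tree) + tree$Nnode
  par <- node_parents(tree)
  inside <- logical(n)
  inside[node] <- TRUE
  for (v in rev(postorder_nodes(tree))) {   # preorder: parents first
    if (v != node && par[v] != 0 && inside[par[v]]) inside[v] <- TRUE
  }
  inside
}

# MRCA of a set of tip labels; a single tip is its own MRCA
mrca_node <- function(tree, tips) {
  idx <- node_number(tree, tips)
  if (any(idx > ape::Ntip(tree))) stop("mrca_node expects tip labels")
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

# Precomputed tables for fast LCA mapping on a (small) species tree:
# depth from root, full pairwise LCA matrix, and tip index by label.
tree_tables <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n <- n_tip + tree$Nnode
  par <- node_parents(tree)
  root <- which(par == 0L)
  depth <- integer(n)
  for (v in rev(postorder_nodes(tree))) {
    if (par[v] != 0L) depth[v] <- depth[par[v]] + 1L
  }
  kids <- node_children(tree)
  desc <- vector("list", n)
  lca <- matrix(0L, n, n)
  for (v in postorder_nodes(tree)) {
    ch <- kids[[v]]
    if (length(ch) == 0L) {
      desc[[v]] <- v
    } else {
      for (a in seq_along(ch)) {
        for (b in seq_along(ch)) {
          if (a < b) {
            da <- desc[[ch[a]]]; db <- desc[[ch[b]]]
            lca[da, db] <- v
            lca[db, da] <- v
          }
        }
      }
      desc[[v]] <- c(v, unlist(desc[ch]))
      lca[v, desc[[v]]] <- v
      lca[desc[[v]], v] <- v
    }
    lca[v, v] <- v
  }
  list(n_tip = n_tip, n = n, root = root, parent = par, depth = depth,
       lca = lca, labels = node_labels(tree))
}

# One random rooted NNI move: pick an internal (non-root) node c with parent
# p, and swap one child of c with c's sibling. Preserves rootedness.
rooted_nni <- function(tree, moves = 1L) {
  for (m in seq_len(moves)) {
    n_tip <- ape::Ntip(tree)
    par <- node_parents(tree)
    root <- which(par == 0L)
    candidates <- setdiff(which(seq_along(par) > n_tip), root)
    candidates <- candidates[par[candidates] != 0L]
    if (length(candidates) == 0L) return(tree)
    cnode <- candidates[sample.int(length(candidates), 1L)]
    p <- par[cnode]
    sibs <- tree$edge[tree$edge[, 1] == p & tree$edge[, 2] != cnode, 2]
    s <- sibs[sample.int(length(sibs), 1L)]
    ch <- tree$edge[tree$edge[, 1] == cnode, 2]
    x <- ch[sample.int(length(ch), 1L)]
    row_s <- which(tree$edge[, 1] == p & tree$edge[, 2] == s)
    row_x <- which(tree$edge[, 1] == cnode & tree$edge[, 2] == x)
    tree$edge[row_s, 1] <- cnode
    tree$edge[row_x, 1] <- p
    tree <- ape::reorder.phylo(tree, "cladewise")
  }
  tree
}
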