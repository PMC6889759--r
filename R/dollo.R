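# Dollo-parsimony reconstruction of gene-family gain and loss on a fixed
# rooted species tree. Under Dollo each family is gained exactly once —
# multiple independent horizontal acquisitions of the same family are less
# parsimonious than one acquisition in a common ancestor — and may then be
# lost any number of times on edges below the gain.

#' Most recent common ancestor as the Dollo gain node
#'
#' @param tree rooted `phylo` with (or gaining) unique node labels.
#' @param present_leaves non-empty character vector of tip labels where
#'   the family is present.
#' @return the label of the gain node (the MRCA; a single leaf is its own
#'   gain node, allowing species-specific acquisitions).
#' @export
infer_gain_node <- function(tree, present_leaves) {
  tree <- ensure_node_labels(tree)
  if (length(present_leaves) == 0L) stop("present_leaves must be non-empty")
  node_labels(tree)[mrca_node(tree, present_leaves)]
}

#' Minimal Dollo loss set below a gain node
#'
#' Returns the root edges (identified by child-node label) of the maximal
#' subtrees under the gain node that contain no present leaf. This is the
#' minimum set of loss events explaining the observed absences given a
#' single gain at `gain_node`.
#'
#' @param tree rooted `phylo`.
#' @param gain_node label of the gain node.
#' @param present_leaves tip labels where the family is present; must all
#'   descend from `gain_node`.
#' @return character vector of child-node labels of the loss edges.
#' @export
infer_losses <- function(tree, gain_node, present_leaves) {
  tree <- ensure_node_labels(tree)
  labs <- node_labels(tree)
  g <- node_number(tree, gain_node)
  tips <- node_number(tree, present_leaves)
  inside <- in_subtree(tree, g)
  if (!all(inside[tips])) {
    stop("present leaves must descend from the gain node")
  }
  n_tip <- ape::Ntip(tree)
  has_present <- logical(n_tip + tree$Nnode)
  has_present[tips] <- TRUE
  for (v in postorder_nodes(tree)) {
    ch <- tree$edge[tree$edge[, 1] == v, 2]
    if (length(ch)) has_present[v] <- has_present[v] || any(has_present[ch])
  }
  par <- node_parents(tree)
  loss_children <- which(inside & !has_present &
                         par != 0L & has_present[pmax(par, 1L)] &
                         inside[pmax(par, 1L)])
  labs[loss_children]
}

#' Dollo reconstruction of gains and losses for a presence matrix
#'
#' Applies [infer_gain_node()] and [infer_losses()] to every family and
#' summarises per node: families gained at the node, families lost on the
#' edge above it, and the cumulative number of families present, with
#' `cumulative(root) = gains(root)` and
#' `cumulative(n) = cumulative(parent) + gains(n) - losses(n)`.
#'
#' @param matrix logical families-by-species matrix; column names must
#'   equal the tree's tip labels (any order).
#' @param tree rooted `phylo`.
#' @return an object of class `hgt_dollo`: list with `tree`, `families`
#'   (`data.frame` of `family`, `gain_node` and a `loss_edges`
#'   list-column) and `node_summary` (see [node_content_report()]).
#' @export
dollo_reconstruct <- function(matrix, tree) {
  tree <- ensure_node_labels(tree)
  if (!setequal(colnames(matrix), tree$tip.label)) {
    stop("matrix species do not match the tree's tips")
  }
  if (any(rowSums(matrix) == 0L)) {
    stop("families absent from every species cannot be placed")
  }
  labs <- node_labels(tree)
  fams <- rownames(matrix)
  gain <- character(nrow(matrix))
  losses <- vector("list", nrow(matrix))
  for (f in seq_len(nrow(matrix))) {
    present <- colnames(matrix)[matrix[f, ]]
    gain[f] <- infer_gain_node(tree, present)
    losses[[f]] <- infer_losses(tree, gain[f], present)
  }
  n <- length(labs)
  gains_per_node <- tabulate(match(gain, labs), nbins = n)
  losses_per_node <- tabulate(match(unlist(losses), labs), nbins = n)
  par <- node_parents(tree)
  cum <- integer(n)
  for (v in rev(postorder_nodes(tree))) {  # preorder
    cum[v] <- if (par[v] == 0L) gains_per_node[v] else
      cum[par[v]] + gains_per_node[v] - losses_per_node[v]
  }
  families <- data.frame(family = fams, gain_node = gain,
                         stringsAsFactors = FALSE)
  families$loss_edges <- losses
  node_summary <- data.frame(
    node = labs, gains = gains_per_node, losses = losses_per_node,
    cumulative_present = cum, stringsAsFactors = FALSE)
  structure(list(tree = tree, families = families,
                 node_summary = node_summary),
            class = "hgt_dollo")
}

#' Per-node gain/loss/content table of a Dollo reconstruction
#'
#' One row per node of the species tree: families gained at the node,
#' families lost on the edge above it (losses are attributed to the child
#' node of the lost edge), and cumulative families present at the node.
#'
#' @param recon an `hgt_dollo` object from [dollo_reconstruct()].
#' @return the `node_summary` `data.frame`.
#' @export
node_content_report <- function(recon) {
  stopifnot(inherits(recon, "hgt_dollo"))
  recon$node_summary
}

#' @export
print.hgt_dollo <- function(x, ...) {
  cat("Dollo reconstruction:", nrow(x$families), "families on",
      ape::Ntip(x$tree), "species\n")
  total_losses <- sum(x$node_summary$losses)
  cat("  gains:", nrow(x$families), "(one per family), losses:",
      total_losses, "\n")
  invisible(x)
}
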