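# Seeded generator of presence/absence matrices under the Dollo model the
# reconstruction assumes: each gene family is gained exactly once at a
# node of the species tree and can only be lost on edges below that node.

#' Specification for a Dollo gain/loss simulation
#'
#' @param species_tree rooted `phylo`; unlabeled internal nodes are named
#'   deterministically (see [ensure_node_labels()]).
#' @param n_families number of gene families to simulate.
#' @param gain_node_weights named numeric vector of sampling weights over
#'   node labels (tips and internal); default uniform over all nodes.
#' @param loss_rate per-edge loss probability in `[0, 1)` for edges
#'   strictly below the gain node.
#' @param seed integer seed.
#' @return an object of class `gain_loss_sim_spec`.
#' @export
gain_loss_sim_spec <- function(species_tree, n_families,
                               gain_node_weights = NULL, loss_rate = 0.1,
                               seed = 1L) {
  species_tree <- ensure_node_labels(species_tree)
  stopifnot(n_families >= 1, loss_rate >= 0, loss_rate < 1)
  labs <- node_labels(species_tree)
  if (is.null(gain_node_weights)) {
    gain_node_weights <- stats::setNames(rep(1, length(labs)), labs)
  }
  if (!all(names(gain_node_weights) %in% labs)) {
    stop("gain_node_weights name unknown nodes: ",
         paste(setdiff(names(gain_node_weights), labs), collapse = ", "))
  }
  structure(list(species_tree = species_tree,
                 n_families = as.integer(n_families),
                 gain_node_weights = gain_node_weights,
                 loss_rate = loss_rate, seed = as.integer(seed)),
            class = "gain_loss_sim_spec")
}

#' Simulate a presence/absence matrix by single gains plus random losses
#'
#' Each family draws one gain node (by weight), then every edge strictly
#' below the gain node independently loses the family with probability
#' `loss_rate`; a leaf is present iff no edge on its path from the gain
#' node was lost. Families that end up absent everywhere are re-drawn, so
#' every returned family is observable. The true gain node and sampled
#' loss edges are returned for recovery testing.
#'
#' @param spec a [gain_loss_sim_spec()].
#' @return list with `matrix` (logical families x species), `truth`
#'   (`data.frame` of `family`, `gain_node`) and `loss_edges` (list of
#'   child-node labels of lost edges per family).
#' @export
simulate_presence_matrix <- function(spec) {
  stopifnot(inherits(spec, "gain_loss_sim_spec"))
  tree <- spec$species_tree
  labs <- node_labels(tree)
  n_tip <- ape::Ntip(tree)
  withr::with_seed(spec$seed, {
    w <- spec$gain_node_weights
    nodes <- node_number(tree, names(w))
    kids <- node_children(tree)
    m <- matrix(FALSE, spec$n_families, n_tip,
                dimnames = list(sprintf("fam_%04d", seq_len(spec$n_families)),
                                tree$tip.label))
    gain <- character(spec$n_families)
    losses <- vector("list", spec$n_families)
    for (f in seq_len(spec$n_families)) {
      repeat {
        g <- nodes[sample.int(length(nodes), 1L, prob = w)]
        alive <- logical(n_tip + tree$Nnode)
        alive[g] <- TRUE
        lost <- character()
        # preorder walk within the gain subtree
        stack <- g
        while (length(stack)) {
          v <- stack[[1L]]; stack <- stack[-1L]
          for (c in kids[[v]]) {
            if (alive[v] && stats::runif(1) >= spec$loss_rate) {
              alive[c] <- TRUE
            } else if (alive[v]) {
              lost <- c(lost, labs[c])
            }
            stack <- c(stack, c)
          }
        }
        present <- alive[seq_len(n_tip)]
        if (any(present)) break
      }
      m[f, ] <- present
      gain[f] <- labs[g]
      losses[[f]] <- lost
    }
    list(matrix = m,
         truth = data.frame(family = rownames(m), gain_node = gain,
                            stringsAsFactors = FALSE),
         loss_edges = stats::setNames(losses, rownames(m)))
  })
}
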