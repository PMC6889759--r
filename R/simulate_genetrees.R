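# Seeded generator of gene trees under contrasting polyploid-origin
# scenarios. Under allopolyploidy the extra gene copies of the
# parthenogens descend from an external donor lineage and form their own
# clade attached on the donor edge; under autopolyploidy each extra copy
# is a within-lineage duplicate, sister to its conspecific copy.
# Topological noise is added as random rooted NNI moves.

#' Specification for a polyploid-origin gene-tree simulation
#'
#' @param scenario `"allo"` or `"auto"`.
#' @param species_tree rooted `phylo`.
#' @param parthenogens tip labels of the parthenogenetic species (which
#'   carry the extra copies).
#' @param donor_edge for `"allo"`: the edge on which the donor lineage
#'   attaches, identified by the label of its child node.
#' @param n_trees number of gene trees.
#' @param noise_nni number of random nearest-neighbour-interchange moves
#'   applied per tree (0 = exact construction).
#' @param seed integer seed.
#' @return an object of class `origin_sim_spec`.
#' @export
origin_sim_spec <- function(scenario = c("allo", "auto"), species_tree,
                            parthenogens, donor_edge = NULL, n_trees,
                            noise_nni = 0L, seed = 1L) {
  scenario <- match.arg(scenario)
  species_tree <- ensure_node_labels(species_tree)
  stopifnot(all(parthenogens %in% species_tree$tip.label),
            length(parthenogens) >= 1, n_trees >= 1, noise_nni >= 0)
  if (scenario == "allo") {
    if (is.null(donor_edge)) stop("allo scenario requires donor_edge")
    node_number(species_tree, donor_edge)  # validates
  }
  structure(list(scenario = scenario, species_tree = species_tree,
                 parthenogens = parthenogens, donor_edge = donor_edge,
                 n_trees = as.integer(n_trees),
                 noise_nni = as.integer(noise_nni), seed = as.integer(seed)),
            class = "origin_sim_spec")
}

#' Simulate gene trees under an allo- or autopolyploid scenario
#'
#' The base topology mirrors the species tree with one leaf `SP|copy1` per
#' species. Each parthenogen gains a second copy `SP|copy2`: under
#' `"allo"` the extra copies form a clade (mirroring the parthenogen
#' subtree) grafted midway on the designated donor edge; under `"auto"`
#' each extra copy attaches as sister to its own species' first copy.
#' `noise_nni` random NNI moves are then applied per tree.
#'
#' @param spec an [origin_sim_spec()].
#' @return a `multiPhylo` list of rooted gene trees with `SPECIES|copyN`
#'   leaf labels.
#' @export
simulate_gene_trees <- function(spec) {
  stopifnot(inherits(spec, "origin_sim_spec"))
  sp <- spec$species_tree
  withr::with_seed(spec$seed, {
    trees <- vector("list", spec$n_trees)
    for (t in seq_len(spec$n_trees)) {
      g <- sp
      g$node.label <- NULL
      g$tip.label <- paste0(g$tip.label, "|copy1")
      g <- ape::compute.brlen(g, 1)
      if (spec$scenario == "auto") {
        for (p in spec$parthenogens) {
          tip <- ape::read.tree(text = paste0("(", p, "|copy2:0.5);"))
          at <- which(g$tip.label == paste0(p, "|copy1"))
          g <- ape::bind.tree(g, tip, where = at, position = 0.5)
        }
      } else {
        extra <- if (length(spec$parthenogens) == 1L) {
          ape::read.tree(text = paste0("(", spec$parthenogens, "|copy2:0.5);"))
        } else {
          cl <- ape::keep.tip(sp, spec$parthenogens)
          cl$node.label <- NULL
          cl$tip.label <- paste0(cl$tip.label, "|copy2")
          cl <- ape::compute.brlen(cl, 1)
          cl$root.edge <- 0.5  # keep the donor clade intact when grafting
          cl
        }
        # donor edge in the growing gene tree: edge above the clade of
        # copy-1 leaves descending from the donor edge's child node
        child <- spec$donor_edge
        sp_tips <- tips_below(sp, node_number(sp, child))
        at <- if (length(sp_tips) == 1L) {
          which(g$tip.label == paste0(sp_tips, "|copy1"))
        } else {
          ape::getMRCA(g, paste0(sp_tips, "|copy1"))
        }
        g <- ape::bind.tree(g, extra, where = at, position = 0.5)
      }
      if (spec$noise_nni > 0) g <- rooted_nni(g, spec$noise_nni)
      g$edge.length <- NULL
      trees[[t]] <- g
    }
    class(trees) <- "multiPhylo"
    trees
  })
}

# tip labels below a node (the node itself if a tip)
tips_below <- function(tree, node) {
  n_tip <- ape::Ntip(tree)
  if (node <= n_tip) return(tree$tip.label[node])
  tree$tip.label[which(in_subtree(tree, node)[seq_len(n_tip)])]
}
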