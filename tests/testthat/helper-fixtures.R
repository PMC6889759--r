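# Shared fixtures: small trees and a panagrolaimid-like species tree with
# three parthenogens, two sexual congeners and two outgroups.

quartet_tree <- function() {
  panagrokit::ensure_node_labels(ape::read.tree(text = "((A,B),(C,D));"))
}

panagro_tree <- function() {
  panagrokit::ensure_node_labels(ape::read.tree(
    text = "(((((PS1159,PS1579),DAW1),(ES5,superbus)),JU765),redivivus);"))
}

panagro_parthenogens <- c("PS1159", "PS1579", "DAW1")

# child label of the stem edge of the Panagrolaimus clade (the donor edge
# used in allopolyploid simulations: basal to parthenogens + sexuals)
panagro_donor_edge <- function(tree = panagro_tree()) {
  panagrokit::infer_gain_node(tree, c("PS1159", "ES5"))
}

ten_leaf_tree <- function() {
  panagrokit::ensure_node_labels(ape::read.tree(
    text = "((((s1,s2),(s3,s4)),((s5,s6),s7)),((s8,s9),s10));"))
}

write_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# helpers shared by module tests: independent re-derivations that avoid the
# package's tree internals

as_vt <- function(df) {
  class(df) <- c("variant_table", "data.frame")
  df
}

node_number_of <- function(tree, label) {
  match(label, c(tree$tip.label, tree$node.label))
}

tips_under <- function(tree, node) {
  if (node <= ape::Ntip(tree)) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

tips_of_clade <- function(tree, label) {
  tips_under(tree, node_number_of(tree, label))
}

# presence of `tip` given a gain node and loss edges (child labels)
leaf_state <- function(tree, tip, gain, losses) {
  labs <- c(tree$tip.label, tree$node.label)
  par <- integer(length(labs)); par[tree$edge[, 2]] <- tree$edge[, 1]
  v <- match(tip, labs); g <- match(gain, labs)
  path <- v
  while (par[v] != 0L) { v <- par[v]; path <- c(path, v) }
  if (!(g %in% path)) return(FALSE)
  below <- path[seq_len(which(path == g) - 1L)]
  !any(labs[below] %in% losses)
}
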