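#' Edge-incidence decomposition of a rooted tree
#'
#' Precomputes, for each edge of a rooted `phylo` tree, the set of tips
#' descending from it, as an edges x tips logical incidence matrix, plus
#' edge lengths and root-to-tip path lengths. This is the shared substrate
#' for Faith phylogenetic diversity and both UniFrac variants: any
#' presence/abundance vector over tips maps to per-edge occupancy by a
#' single matrix product.
#'
#' @param tree Rooted `ape::phylo` with branch lengths.
#' @return List with `incidence` (edges x tips, logical; columns named by
#'   tip label), `lengths` (edge lengths), and `tip_depth` (root-to-tip
#'   distances, named).
#' @export
tree_edge_matrix <- function(tree) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tr <- stats::reorder(tree, "postorder")
  below <- matrix(FALSE, nnode, ntip) # node x tip: tip descends from node
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]
    chi <- tr$edge[e, 2]
    below[par, ] <- below[par, ] | below[chi, ]
  }
  inc <- below[tr$edge[, 2], , drop = FALSE]
  colnames(inc) <- tree$tip.label
  depth <- colSums(inc * tr$edge.length)
  names(depth) <- tree$tip.label
  list(incidence = inc, lengths = tr$edge.length, tip_depth = depth)
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree connecting the present
#' tips and the root (root-inclusive convention): every edge with at least
#' one present descendant tip contributes its length.
#'
#' @param present_taxa Character vector of present tip labels (nonempty).
#' @param tree Rooted `ape::phylo`, or a precomputed [tree_edge_matrix()]
#'   (cheaper when calling repeatedly on one tree).
#' @return Phylogenetic diversity in branch-length units.
#' @export
faith_pd <- function(present_taxa, tree) {
  em <- if (inherits(tree, "phylo")) tree_edge_matrix(tree) else tree
  if (length(present_taxa) == 0) stop("present_taxa must be nonempty")
  unknown <- setdiff(present_taxa, colnames(em$incidence))
  if (length(unknown)) stop("unknown taxon: ", unknown[[1]])
  hit <- rowSums(em$incidence[, present_taxa, drop = FALSE]) > 0
  sum(em$lengths[hit])
}
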