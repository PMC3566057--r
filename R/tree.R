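## Phylogeny input/validation.  Trees are ape "phylo" objects throughout;
## this file adds the validation the pipeline relies on (branch lengths
## present, binary, ultrametric within tolerance) and clade-membership
## handling.

#' Node heights above the root
#'
#' @param phy an ape \code{phylo} object with branch lengths.
#' @return numeric vector of length \code{Ntip + Nnode}: distance of every
#'   node from the root (root = 0), indexed as in \code{phy$edge}.
#' @export
node_heights <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) abort("tree has no branch lengths")
  ape::node.depth.edgelength(phy)
}

#' Tree height (root-to-tip distance of an ultrametric tree)
#'
#' @param phy an ape \code{phylo} object.
#' @return maximum node height.
#' @export
tree_height <- function(phy) max(node_heights(phy))

#' Validate a pipeline phylogeny
#'
#' Checks that the tree is rooted, binary, has branch lengths on every
#' edge, has unique tip labels, and is ultrametric within
#' \code{tol * tree height} (relative tolerance on tip heights).
#'
#' @param phy an ape \code{phylo} object.
#' @param tol relative ultrametricity tolerance (default \code{1e-6}).
#' @return \code{phy}, invisibly, or an error naming the worst tip.
#' @export
validate_phylogeny <- function(phy, tol = 1e-6) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) abort("tree has no branch lengths")
  if (anyNA(phy$edge.length)) abort("tree has missing branch lengths")
  if (anyDuplicated(phy$tip.label)) abort("duplicate tip labels")
  if (!ape::is.rooted(phy)) abort("tree is not rooted")
  if (!ape::is.binary(phy)) abort("tree has non-binary internal nodes")
  h <- node_heights(phy)
  tip_h <- h[seq_len(ape::Ntip(phy))]
  H <- max(tip_h)
  dev <- abs(tip_h - H)
  if (max(dev) > tol * H)
    abort("tree is not ultrametric: tip '",
          phy$tip.label[which.max(dev)], "' deviates by ",
          signif(max(dev), 4), " (tolerance ", signif(tol * H, 4), ")")
  invisible(phy)
}

#' Read and validate a newick tree
#'
#' @param path newick file containing a single rooted tree with branch
#'   lengths.
#' @param tol ultrametricity tolerance passed to
#'   \code{\link{validate_phylogeny}}.
#' @return a validated ape \code{phylo} object.
#' @export
read_newick <- function(path, tol = 1e-6) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) abort(path, ": could not parse newick")
  if (inherits(phy, "multiPhylo")) abort(path, ": expected a single tree")
  validate_phylogeny(phy, tol = tol)
  phy
}

#' Write a tree to newick
#'
#' @param phy an ape \code{phylo} object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(phy, path) {
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Read and check a taxon-to-clade membership table
#'
#' Expects a CSV with columns \code{taxon} and \code{clade}.  Every tree
#' tip must be assigned exactly one clade, and each clade's taxa must form
#' a monophyletic group on the tree.
#'
#' @param path CSV path.
#' @param phy the phylogeny the membership refers to.
#' @return named character vector: clade label per tip label.
#' @export
read_clade_map <- function(path, phy) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "clade") %in% names(df)))
    abort(path, ": clade CSV must have columns taxon, clade")
  clade_map(stats::setNames(df$clade, df$taxon), phy)
}

#' Validate a taxon-to-clade assignment against a tree
#'
#' @param map named character vector (names = tip labels, values = clade
#'   labels).
#' @param phy an ape \code{phylo} object.
#' @return \code{map}, reordered to match \code{phy$tip.label}.
#' @export
clade_map <- function(map, phy) {
  tips <- phy$tip.label
  if (anyDuplicated(names(map))) abort("taxon assigned to a clade twice")
  missing <- setdiff(tips, names(map))
  if (length(missing))
    abort("tips without clade assignment: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(map), tips)
  if (length(extra))
    abort("clade table lists taxa not in the tree: ",
          paste(extra, collapse = ", "))
  map <- map[tips]
  for (cl in unique(map)) {
    members <- names(map)[map == cl]
    if (length(members) > 1 &&
        !ape::is.monophyletic(phy, members))
      abort("clade '", cl, "' is not monophyletic on the tree")
  }
  map
}
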