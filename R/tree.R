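#' Read a rate-scaled Newick tree
#'
#' Reads a fixed-topology phylogeny whose branch lengths are expected
#' synonymous substitutions per site (the neutral reference rate for
#' non-coding conservation scoring). Every edge must carry a branch length
#' and leaf names must be unique.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] object with validated branch lengths.
#' @export
read_newick_rate_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort("could not parse Newick tree")
  validate_rate_tree(tree)
}

#' Validate a rate tree
#'
#' @param tree An [ape::phylo] object.
#' @return The tree, invisibly checked: >= 2 leaves, unique leaf names,
#'   branch lengths present and non-negative on all edges.
#' @export
validate_rate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("not a phylo object")
  if (length(tree$tip.label) < 2L) abort("tree must have >= 2 leaves")
  if (anyDuplicated(tree$tip.label)) abort("duplicate leaf names")
  if (is.null(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    abort("missing branch length on one or more edges")
  }
  if (any(tree$edge.length < 0)) abort("negative branch length")
  tree
}

#' Rescale a topology by a per-gene synonymous rate
#'
#' Plumbing helper: multiplies all branch lengths of a relative-rate
#' topology by a per-gene synonymous substitution rate `ds`, producing the
#' synonymous-scaled tree the LLR denominator expects.
#'
#' @param tree An [ape::phylo] object with branch lengths.
#' @param ds Positive scalar, synonymous substitutions per site for the gene.
#' @return The rescaled tree.
#' @export
rescale_tree_by_ds <- function(tree, ds) {
  validate_rate_tree(tree)
  if (!is.numeric(ds) || length(ds) != 1L || ds <= 0) {
    abort("ds must be a positive scalar")
  }
  tree$edge.length <- tree$edge.length * ds
  tree
}
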