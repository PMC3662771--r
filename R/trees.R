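#' Read a rooted tree from Newick text or file
#'
#' Thin wrapper around [ape::read.tree()] that accepts either a file path or a
#' Newick string and validates the result: a single rooted tree with at least
#' two uniquely labeled tips.
#'
#' @param x Path to a Newick file, or a Newick string (must contain "(").
#' @return An object of class `phylo`.
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  tr <- if (grepl("\\(", x)) ape::read.tree(text = x) else ape::read.tree(x)
  if (is.null(tr)) stop("could not parse Newick input")
  if (inherits(tr, "multiPhylo")) stop("input contains more than one tree")
  validate_tree(tr)
  tr
}

#' Write a tree as Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional output path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, file = NULL) {
  validate_tree(tree)
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(ape::write.tree(tree))
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (length(tree$tip.label) < 2L) stop("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths")
  invisible(tree)
}

#' Grafen branch lengths
#'
#' Assigns branch lengths from node heights proportional to descendant tip
#' counts: a node with `m` descendant tips on an `n`-tip tree sits at height
#' `((m - 1)/(n - 1))^rho`, tips at height 0, so every root-to-tip path has
#' length 1. This is the standard way to put comparable branch lengths on a
#' cladogram that has none.
#'
#' @param tree A rooted `phylo` object (existing branch lengths are ignored).
#' @param rho Positive exponent applied to the relative heights (default 1).
#' @return The tree with ultrametric, height-1 branch lengths.
#' @export
grafen_branch_lengths <- function(tree, rho = 1) {
  validate_tree(tree)
  stopifnot(is.numeric(rho), length(rho) == 1L, rho > 0)
  ape::compute.brlen(tree, method = "Grafen", power = rho)
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between every pair of tips.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return A symmetric matrix with zero diagonal, dimnames = tip labels.
#' @export
patristic_distances <- function(tree) {
  validate_tree(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  as.matrix(stats::cophenetic(tree))
}

#' Prune a tree to a subset of tips
#'
#' Retains the given tips, suppressing unary internal nodes (branch lengths
#' are summed), so pairwise patristic distances among retained tips are
#' unchanged.
#'
#' @param tree A `phylo` object.
#' @param tips Character vector of tip labels to keep (at least 2).
#' @return The pruned `phylo` object.
#' @export
prune_to <- function(tree, tips) {
  validate_tree(tree)
  tips <- unique(as.character(tips))
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing))
    stop("tips not in tree: ", paste(missing, collapse = ", "))
  if (length(tips) < 2L) stop("need at least 2 tips to prune to")
  ape::keep.tip(tree, tips)
}

# Deterministic polytomy resolution: zero-length branches, input child order.
resolve_polytomies <- function(tree) {
  if (ape::is.binary(tree)) return(tree)
  ape::multi2di(tree, random = FALSE)
}
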