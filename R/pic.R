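#' Phylogenetically independent contrasts
#'
#' Felsenstein's contrasts: at each internal node with daughter values
#' `x1, x2` carried by branches with (extended) lengths `v1, v2`, the
#' standardized contrast is `(x1 - x2)/sqrt(v1 + v2)`; the node is assigned
#' the inverse-variance weighted average of its daughters and its own branch
#' is extended by `v1*v2/(v1 + v2)`. Under Brownian motion the contrasts are
#' independent standard normals.
#'
#' Polytomies are resolved deterministically with zero-length branches in
#' input child order before computing contrasts; the first-listed daughter
#' minus the second fixes the (arbitrary) contrast sign.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param x Numeric vector of tip values, named by tip label (or in
#'   `tree$tip.label` order if unnamed). No missing values: prune first.
#' @return Numeric vector of `n_tips - 1` standardized contrasts.
#' @export
pic_contrasts <- function(tree, x) {
  validate_tree(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ntip <- length(tree$tip.label)
  if (is.null(names(x))) {
    if (length(x) != ntip) stop("length(x) != number of tips")
    names(x) <- tree$tip.label
  }
  if (!all(tree$tip.label %in% names(x)))
    stop("missing tip values: prune the tree to the tips with data first")
  x <- x[tree$tip.label]
  if (anyNA(x)) stop("NA tip values: prune the tree to the tips with data first")

  tree <- resolve_polytomies(tree)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  val <- c(x[tree$tip.label], numeric(nnode))
  extra <- numeric(ntip + nnode)      # branch-length extension per node
  e1 <- tree$edge[, 1L]
  e2 <- tree$edge[, 2L]
  len <- tree$edge.length
  contrasts <- numeric(nnode)
  # postorder on a binary tree: daughter edges of each node are consecutive
  for (k in seq(1L, length(e1), by = 2L)) {
    parent <- e1[k]
    c1 <- e2[k]; c2 <- e2[k + 1L]
    v1 <- len[k] + extra[c1]
    v2 <- len[k + 1L] + extra[c2]
    vs <- v1 + v2
    if (vs > 0) {
      contrasts[parent - ntip] <- (val[c1] - val[c2]) / sqrt(vs)
      val[parent] <- (val[c1] / v1 + val[c2] / v2) / (1 / v1 + 1 / v2)
      extra[parent] <- v1 * v2 / vs
    } else {  # degenerate zero-length cherry: no information in the split
      contrasts[parent - ntip] <- 0
      val[parent] <- mean(c(val[c1], val[c2]))
      extra[parent] <- 0
    }
  }
  contrasts
}

#' Correlation of two traits through phylogenetically independent contrasts
#'
#' Computes standardized contrasts for both traits on the same tree and their
#' Pearson correlation constrained through the origin (the standard treatment
#' for contrasts, whose expected mean is zero). The two-sided p-value uses a
#' t distribution with `df = n_contrasts - 1`.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param x,y Numeric tip values, named by tip label.
#' @return A list with `r`, `df`, `p`, and the contrast vectors.
#' @export
pic_correlation <- function(tree, x, y) {
  cx <- pic_contrasts(tree, x)
  cy <- pic_contrasts(tree, y)
  r <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  df <- length(cx) - 1L
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(r = r, df = df, p = p, contrasts_x = cx, contrasts_y = cy)
}
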