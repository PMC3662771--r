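# Fixtures built in code: a toy checklist/record set with every validation
# case, a balanced 8-tip tree, and small simulators used as oracles.

toy_checklist <- function() {
  data.frame(
    species = c("Papilio alpha", "Papilio beta", "Graphium gamma",
                "Miletus delta", "Poritia epsilon"),
    genus = c("Papilio", "Papilio", "Graphium", "Miletus", "Poritia"),
    subfamily = c("Papilioninae", "Papilioninae", "Papilioninae",
                  "Miletinae", "Poritiinae"),
    family = c("Papilionidae", "Papilionidae", "Papilionidae",
               "Lycaenidae", "Lycaenidae"),
    region = c("OR", "NT", "NT", "AT", "OR"))
}

toy_taxonomy <- function() {
  data.frame(
    name = c("Fabaceae", "Piper", "Piper nigrum", "Poaceae", "Aristolochia"),
    rank = c("family", "genus", "species", "family", "genus"),
    order = c("Fabales", "Piperales", "Piperales", "Poales", "Piperales"),
    family = c(NA, "Piperaceae", "Piperaceae", NA, "Aristolochiaceae"),
    genus = c(NA, NA, "Piper", NA, NA))
}

toy_records <- function() {
  data.frame(
    butterfly_species = c("Papilio alpha", "Papilio alpha", "Papilio beta",
                          "Graphium gamma", "Graphium gamma", "Miletus delta",
                          "Papilio beta", "Unknown species", "Papilio alpha",
                          "Poritia epsilon"),
    host_name = c("Piperales", "Piperales", "Fabaceae", "Piper", "Poaceae",
                  "animal", "grasses", "Fabaceae", "Mysteryplant", "detritus"),
    host_rank = c("order", "order", "family", "genus", "family", "order",
                  "order", "family", "genus", "order"),
    source = "toy")
}

toy_plant_orders <- function() c("Fabales", "Piperales", "Poales", "Rosales")

balanced8 <- function() {
  grafen_branch_lengths(
    read_newick("(((A,B),(C,D)),((E,F),(G,H)));"))
}

# Brownian motion simulated tip values (preorder recursion) -- used as the
# independent generator for PIC calibration checks.
sim_bm <- function(tree, sd0 = 1) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  x <- numeric(n + tree$Nnode)
  for (e in rev(seq_len(nrow(tree$edge))))
    x[tree$edge[e, 2L]] <- x[tree$edge[e, 1L]] +
      stats::rnorm(1, 0, sd0 * sqrt(tree$edge.length[e]))
  stats::setNames(x[seq_len(n)], tree$tip.label)
}

# Independent patristic distance: enumerate the node path between each tip
# pair and sum the lengths of its consecutive edges.
brute_patristic <- function(tree) {
  n <- length(tree$tip.label)
  edge_len <- function(a, b) {
    hit <- which((tree$edge[, 1L] == a & tree$edge[, 2L] == b) |
                   (tree$edge[, 1L] == b & tree$edge[, 2L] == a))
    tree$edge.length[hit]
  }
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    path <- ape::nodepath(tree, i, j)
    D[i, j] <- D[j, i] <- sum(vapply(seq_len(length(path) - 1L), function(k)
      edge_len(path[k], path[k + 1L]), numeric(1)))
  }
  D
}

# Independent root-inclusive PD: union of root-to-tip edge sets via nodepath.
brute_pd <- function(tree, tips) {
  root <- length(tree$tip.label) + 1L
  elen <- stats::setNames(tree$edge.length, tree$edge[, 2L])
  nodes <- unique(unlist(lapply(match(tips, tree$tip.label), function(i)
    setdiff(ape::nodepath(tree, root, i), root))))
  sum(elen[as.character(nodes)])
}
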