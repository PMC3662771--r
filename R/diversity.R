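#' Host-order richness per subfamily
#'
#' Number of plant orders used by each butterfly subfamily: the column sums of
#' the binary association matrix A.
#'
#' @param tables An `association_tables` object.
#' @return Named integer vector `h` per subfamily.
#' @export
order_richness <- function(tables) {
  colSums(tables$A)
}

#' Fisher's log-series alpha
#'
#' Maximum-likelihood alpha of Fisher's log-series fitted to a vector of
#' species counts (here: the positive `c_ij` entries of one subfamily's column
#' of matrix C). With `S` classes among `N` observations the MLE solves
#' `S = alpha * log(1 + N/alpha)`. The standard error comes from the observed
#' information of the Poisson-sampled log-series likelihood at the MLE
#' (class-abundance frequencies as independent Poissons with log-series
#' means): `se = 1/sqrt(S/alpha^2 - N/(alpha*(N + alpha)))`.
#'
#' A vector with a single positive class carries no information about alpha;
#' following the convention used for single-order subfamilies it is reported
#' as `alpha = 0` with no SE. `S == N` (all singletons) makes the MLE diverge
#' and is an error.
#'
#' @param counts Non-negative counts; zeros are dropped.
#' @return List with `alpha`, `se`, `S`, `N`.
#' @export
fisher_alpha <- function(counts) {
  counts <- counts[counts > 0]
  S <- length(counts)
  N <- sum(counts)
  if (S <= 1L) return(list(alpha = 0, se = NA_real_, S = S, N = N))
  if (S == N) stop("all classes are singletons: Fisher's alpha diverges")
  f <- function(a) a * log1p(N / a) - S
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  alpha <- stats::uniroot(f, lower = 1e-12, upper = upper, tol = 1e-12)$root
  # observed information of lnL = S log(a) + N log(N/(N+a)) - a log(1 + N/a)
  info <- S / alpha^2 - N / (alpha * (N + alpha))
  se <- if (info > 0) 1 / sqrt(info) else NA_real_
  list(alpha = alpha, se = se, S = S, N = N)
}

#' Faith's phylogenetic diversity (root-inclusive)
#'
#' Total branch length of the minimal subtree connecting a set of tips *and
#' the root*. Root-inclusive PD makes the PD of a single tip equal its depth
#' (1 on a Grafen tree), matching how single-order subfamilies are reported.
#'
#' @param tree A `phylo` with branch lengths (typically the plant-order tree
#'   with Grafen lengths).
#' @param tips Character vector of tip labels (non-empty, all in the tree).
#' @return Numeric PD value.
#' @export
faith_pd <- function(tree, tips) {
  inc <- .pd_incidence(tree)
  idx <- match(tips, tree$tip.label)
  if (length(idx) == 0L) stop("empty tip subset")
  if (anyNA(idx))
    stop("tips not in tree: ", paste(tips[is.na(idx)], collapse = ", "))
  used <- as.logical(inc$M %*% .tip_indicator(length(tree$tip.label), idx) > 0)
  sum(inc$len[used])
}

# edge x tip incidence: M[e, t] = 1 if edge e lies on the root-to-t path
.pd_incidence <- function(tree) {
  validate_tree(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  edge_of <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  edge_of[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  root <- ntip + 1L
  i <- integer(0); j <- integer(0)
  for (t in seq_len(ntip)) {
    node <- t
    while (node != root) {
      i <- c(i, edge_of[node]); j <- c(j, t)
      node <- parent[node]
    }
  }
  M <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(nrow(tree$edge), ntip))
  list(M = M, len = tree$edge.length)
}

.tip_indicator <- function(ntip, idx) {
  v <- numeric(ntip); v[idx] <- 1; v
}

#' Random-sample null test for Faith's PD
#'
#' Compares an observed PD against the PD of `n_rand` uniform samples (without
#' replacement) of the same number of tips. The p-value is the lower-tail rank
#' probability `(#\{PD_rand <= PD_obs\} + 1)/(n_rand + 1)`: small p means the
#' used orders are more phylogenetically clumped than a random draw.
#'
#' @param tree Plant-order tree with branch lengths.
#' @param pd_obs Observed PD.
#' @param h Sample size (number of orders used), `1 <= h <=` number of tips.
#' @param n_rand Number of random draws (default 999).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `mean`, `sd`, `p`, and the vector `pd_rand`.
#' @export
pd_null_test <- function(tree, pd_obs, h, n_rand = 999, seed = NULL) {
  ntip <- length(tree$tip.label)
  if (h < 1L || h > ntip) stop("h must be between 1 and the number of tips")
  if (!is.null(seed)) set.seed(seed)
  inc <- .pd_incidence(tree)
  draws <- matrix(0, ntip, n_rand)
  for (r in seq_len(n_rand)) draws[sample.int(ntip, h), r] <- 1
  pd_rand <- as.vector(t(inc$len) %*% ((inc$M %*% draws) > 0))
  list(mean = mean(pd_rand), sd = stats::sd(pd_rand),
       p = (sum(pd_rand <= pd_obs) + 1) / (n_rand + 1),
       pd_rand = pd_rand)
}

#' Per-subfamily host diversity table
#'
#' For each subfamily with at least one valid record: worldwide richness `R`,
#' order richness `h`, Fisher's alpha with SE, Faith's PD of the used orders
#' that are tips of the plant tree, and the random-sample PD null (mean, sd,
#' lower-tail p). Null columns are NA when fewer than two tree tips are used
#' (a one-order subfamily always has PD equal to the tree height). Flagged
#' subfamilies (no valid records) get all-NA rows.
#'
#' @param tables An `association_tables` object.
#' @param plant_tree Plant-order tree with branch lengths.
#' @param n_rand Draws for the PD null (default 999).
#' @param seed Optional seed; each subfamily's null uses `seed + column index`
#'   so rows are independently reproducible.
#' @return A data.frame, one row per subfamily.
#' @export
diversity_table <- function(tables, plant_tree, n_rand = 999, seed = NULL) {
  tip_rows <- intersect(tables$orders, plant_tree$tip.label)
  h_all <- order_richness(tables)
  rows <- lapply(seq_along(tables$subfamilies), function(jj) {
    j <- tables$subfamilies[jj]
    out <- data.frame(subfamily = j, R = tables$R[[j]], S = tables$S[[j]],
                      h = NA_integer_, alpha = NA_real_, alpha_se = NA_real_,
                      pd_obs = NA_real_, pd_null_mean = NA_real_,
                      pd_null_sd = NA_real_, p = NA_real_)
    if (j %in% tables$flagged) return(out)
    out$h <- h_all[[j]]
    fa <- tryCatch(fisher_alpha(tables$C[, j]), error = function(e) {
      warning("Fisher's alpha undefined for ", j, ": ", conditionMessage(e))
      list(alpha = NA_real_, se = NA_real_)
    })
    out$alpha <- fa$alpha; out$alpha_se <- fa$se
    used <- tip_rows[tables$A[tip_rows, j] > 0]
    if (length(used)) {
      out$pd_obs <- faith_pd(plant_tree, used)
      if (length(used) >= 2L && length(used) < length(plant_tree$tip.label)) {
        nt <- pd_null_test(plant_tree, out$pd_obs, length(used), n_rand,
                           seed = if (is.null(seed)) NULL else seed + jj)
        out$pd_null_mean <- nt$mean; out$pd_null_sd <- nt$sd; out$p <- nt$p
      }
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlations between host diversity and butterfly species richness
#'
#' Pearson correlations of the natural logarithm of worldwide species richness
#' `R_j` against each host-diversity measure (`h`, `alpha`, `pd_obs`), on the
#' raw values and through phylogenetically independent contrasts on each
#' supplied butterfly cladogram. Subfamilies lacking a measure (or flagged)
#' are dropped pairwise; the tree is pruned to the subfamilies with data.
#'
#' Two degrees-of-freedom conventions are reported for contrasts: `df`
#' (= number of contrasts - 1, used for the p-value) and `df_origin`
#' (= number of contrasts - 2, the origin-regression convention).
#'
#' @param div A [diversity_table()] result.
#' @param butterfly_trees A named list of `phylo` cladograms whose tips are
#'   subfamilies.
#' @param measures Columns of `div` to correlate with `log(R)`.
#' @return A data.frame with columns `measure`, `method` ("raw" or the
#'   cladogram name), `n`, `r`, `df`, `df_origin`, `p`.
#' @export
richness_correlations <- function(div, butterfly_trees,
                                  measures = c("h", "alpha", "pd_obs")) {
  if (inherits(butterfly_trees, "phylo"))
    butterfly_trees <- list(cladogram = butterfly_trees)
  if (is.null(names(butterfly_trees)))
    names(butterfly_trees) <- paste0("cladogram", seq_along(butterfly_trees))
  rows <- list()
  for (m in measures) {
    ok <- !is.na(div[[m]]) & !is.na(div$R) & div$R > 0
    x <- log(div$R[ok]); y <- div[[m]][ok]
    names(x) <- names(y) <- div$subfamily[ok]
    ct <- stats::cor.test(x, y)
    rows[[length(rows) + 1L]] <- data.frame(
      measure = m, method = "raw", n = sum(ok), r = unname(ct$estimate),
      df = unname(ct$parameter), df_origin = NA_integer_, p = ct$p.value)
    for (tn in names(butterfly_trees)) {
      tr <- butterfly_trees[[tn]]
      keep <- intersect(tr$tip.label, names(x))
      if (length(keep) < 3L) next
      ptr <- prune_to(tr, keep)
      pc <- pic_correlation(ptr, x[keep], y[keep])
      rows[[length(rows) + 1L]] <- data.frame(
        measure = m, method = tn, n = length(keep), r = pc$r,
        df = pc$df, df_origin = pc$df - 1L, p = pc$p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
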