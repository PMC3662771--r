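#' Principal coordinates analysis
#'
#' Gower double-centering of a distance matrix followed by eigendecomposition.
#' Axes with eigenvalues at or below `tol` are dropped by default; the
#' Cailliez or Lingoes constants can instead be added to make all eigenvalues
#' non-negative when the input is strongly non-Euclidean.
#'
#' @param D Symmetric distance matrix (or `dist`).
#' @param correction One of "none" (drop non-positive axes), "cailliez"
#'   (additive constant on distances), "lingoes" (additive constant on squared
#'   distances).
#' @param tol Eigenvalue tolerance relative to the largest eigenvalue.
#' @return List with `vectors` (points x axes, scaled so squared distances are
#'   reproduced), `values` (all eigenvalues of the centered matrix),
#'   `trace_sq` (sum of squared retained eigenvalues) and `correction`.
#' @export
pcoa_coords <- function(D, correction = c("none", "cailliez", "lingoes"),
                        tol = 1e-8) {
  correction <- match.arg(correction)
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8))
    stop("D must be a symmetric distance matrix")
  n <- nrow(D)
  gower <- function(D) {
    A <- -0.5 * D^2
    rm <- rowMeans(A); gm <- mean(A)
    sweep(sweep(A, 1L, rm), 2L, rm) + gm
  }
  G <- gower(D)
  e <- eigen(G, symmetric = TRUE)
  if (correction != "none" && min(e$values) < -tol * max(abs(e$values), 1)) {
    if (correction == "lingoes") {
      c1 <- -min(e$values)
      D2 <- sqrt(D^2 + 2 * c1)
    } else {
      delta1 <- gower(D)
      A2 <- -0.5 * D
      rm <- rowMeans(A2); gm <- mean(A2)
      delta2 <- sweep(sweep(A2, 1L, rm), 2L, rm) + gm
      # Cailliez constant: largest real eigenvalue of the 2n x 2n block matrix
      B <- rbind(cbind(matrix(0, n, n), 2 * delta1),
                 cbind(-diag(n), -4 * delta2))
      c2 <- max(Re(eigen(B, only.values = TRUE)$values))
      D2 <- D + c2
    }
    diag(D2) <- 0
    G <- gower(D2)
    e <- eigen(G, symmetric = TRUE)
  }
  keep <- e$values > tol * max(abs(e$values), .Machine$double.eps)
  vec <- if (any(keep)) {
    e$vectors[, keep, drop = FALSE] %*%
      diag(sqrt(e$values[keep]), nrow = sum(keep))
  } else matrix(0, n, 1L)
  rownames(vec) <- rownames(D)
  list(vectors = vec, values = e$values,
       trace_sq = sum(e$values[keep]^2), correction = correction)
}

# Core ParaFit engine. links: binary matrix, rows = plant orders (matching
# D_plants), columns = butterfly subfamilies (matching D_butterflies). The
# null permutes each column independently (each subfamily keeps its number of
# host orders, which orders it uses is randomized).
.parafit_engine <- function(D_plants, D_butterflies, links, n_perm = 999,
                            seed = NULL, test_links = FALSE,
                            correction = "none") {
  links <- as.matrix(links)
  if (all(links == 0)) stop("links matrix has no links")
  D_plants <- as.matrix(D_plants); D_butterflies <- as.matrix(D_butterflies)
  if (!is.null(rownames(links))) {
    if (!all(rownames(links) %in% rownames(D_plants)) ||
        !all(colnames(links) %in% rownames(D_butterflies)))
      stop("links dimnames not covered by the distance matrices")
    D_plants <- D_plants[rownames(links), rownames(links)]
    D_butterflies <- D_butterflies[colnames(links), colnames(links)]
  }
  if (nrow(links) != nrow(D_plants) || ncol(links) != nrow(D_butterflies))
    stop("dimension mismatch between links and distance matrices")

  pcp <- pcoa_coords(D_plants, correction = correction)
  pcb <- pcoa_coords(D_butterflies, correction = correction)
  B <- pcp$vectors       # orders x axes
  Cm <- pcb$vectors      # subfamilies x axes
  tracemax <- max(pcp$trace_sq, pcb$trace_sq)
  stat <- function(L) sum((crossprod(B, L %*% Cm))^2)
  global <- stat(links)

  n_o <- nrow(links); n_s <- ncol(links)
  perms <- NULL
  global_perm <- numeric(0)
  global_p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    perms <- lapply(seq_len(n_perm), function(i)
      replicate(n_s, sample.int(n_o)))
    permute_cols <- function(L, P) {
      Lp <- L
      for (j in seq_len(n_s)) Lp[, j] <- L[P[, j], j]
      Lp
    }
    global_perm <- vapply(perms, function(P) stat(permute_cols(links, P)),
                          numeric(1))
    global_p <- (sum(global_perm >= global) + 1) / (n_perm + 1)
  }

  link_table <- NULL
  if (test_links) {
    idx <- which(links > 0, arr.ind = TRUE)
    eps <- sqrt(.Machine$double.eps)
    den_obs <- tracemax - global
    den_perm <- tracemax - global_perm
    link_table <- do.call(rbind, lapply(seq_len(nrow(idx)), function(k) {
      Lk <- links
      Lk[idx[k, 1L], idx[k, 2L]] <- 0
      trace_k <- stat(Lk)
      stat1 <- global - trace_k
      stat2 <- if (den_obs > eps) stat1 / den_obs else NA_real_
      p1 <- p2 <- NA_real_
      if (n_perm > 0) {
        trace_k_perm <- vapply(perms, function(P) {
          Lkp <- Lk
          for (j in seq_len(n_s)) Lkp[, j] <- Lk[P[, j], j]
          stat(Lkp)
        }, numeric(1))
        stat1_perm <- global_perm - trace_k_perm
        p1 <- (sum(stat1_perm >= stat1) + 1) / (n_perm + 1)
        if (!is.na(stat2)) {
          ok <- den_perm > eps
          stat2_perm <- stat1_perm[ok] / den_perm[ok]
          p2 <- (sum(stat2_perm >= stat2) + 1) / (sum(ok) + 1)
        }
      }
      data.frame(order = rownames(links)[idx[k, 1L]],
                 subfamily = colnames(links)[idx[k, 2L]],
                 stat1 = stat1, p1 = p1, stat2 = stat2, p2 = p2)
    }))
    rownames(link_table) <- NULL
  }
  structure(list(global_stat = global, global_p = global_p,
                 links = link_table, n_perm = n_perm, seed = seed,
                 pcoa_correction = correction, tracemax = tracemax,
                 global_perm = global_perm),
            class = "parafit_result")
}

#' Global ParaFit test of cophylogenetic congruence
#'
#' Tests whether butterflies and their host plants occupy corresponding
#' positions in their phylogenies. Both patristic distance matrices are
#' converted to principal coordinates (B for plants, C for butterflies); with
#' L the binary links matrix (orders x subfamilies), the global statistic is
#' the sum of squared entries of `t(B) L C` (the ParaFitGlobal trace). The
#' null distribution permutes, independently within each subfamily column,
#' which orders the subfamily is linked to;
#' `p = (#\{stat_perm >= stat_obs\} + 1)/(n_perm + 1)`.
#'
#' @param D_plants,D_butterflies Patristic distance matrices whose dimnames
#'   cover the rows/columns of `links`.
#' @param links Binary association matrix, plant orders x butterfly
#'   subfamilies.
#' @param n_perm Number of permutations (default 999); 0 computes the
#'   statistic only.
#' @param seed Optional integer seed.
#' @param correction PCoA negative-eigenvalue handling, see [pcoa_coords()].
#' @return A `parafit_result` (global part).
#' @export
parafit_global <- function(D_plants, D_butterflies, links, n_perm = 999,
                           seed = NULL, correction = "none") {
  .parafit_engine(D_plants, D_butterflies, links, n_perm, seed,
                  test_links = FALSE, correction = correction)
}

#' Per-link ParaFit tests
#'
#' For each observed link k, `stat1` is the drop in the global statistic when
#' the link is deleted (ParaFitLink1) and `stat2` normalizes it by the
#' residual trace, `stat1 / (tracemax - global_stat)` with `tracemax` the
#' larger of the two PCoAs' sums of squared positive eigenvalues
#' (ParaFitLink2). Each is tested against the same within-column permutation
#' null as the global test, using permutations coupled with the global ones.
#'
#' @inheritParams parafit_global
#' @return A `parafit_result` with a `links` data.frame
#'   (order, subfamily, stat1, p1, stat2, p2).
#' @export
parafit_links <- function(D_plants, D_butterflies, links, n_perm = 999,
                          seed = NULL, correction = "none") {
  .parafit_engine(D_plants, D_butterflies, links, n_perm, seed,
                  test_links = TRUE, correction = correction)
}

#' @export
print.parafit_result <- function(x, ...) {
  cat("ParaFit congruence test\n")
  cat("  global statistic:", format(x$global_stat), "  p =",
      format(x$global_p), " (", x$n_perm, "permutations )\n")
  if (!is.null(x$links))
    cat("  links tested:", nrow(x$links), "\n")
  invisible(x)
}

#' Run the congruence test on association tables
#'
#' Wraps [parafit_links()] for a plant tree, a butterfly cladogram, and one of
#' the binary association matrices (A, all links; or X, important links only).
#' Matrix rows that are not tips of the plant tree (e.g. a non-angiosperm
#' label) and columns that are not tips of the cladogram are dropped with a
#' message.
#'
#' @param plant_tree,butterfly_tree `phylo` objects with branch lengths.
#' @param tables An `association_tables` object.
#' @param matrix `"A"` or `"X"`.
#' @param n_perm,seed,correction Passed to the ParaFit engine.
#' @param alpha Significance level for counting significant links (on the
#'   ParaFitLink2 p-value).
#' @param test_links Set `FALSE` to skip per-link tests.
#' @return A `parafit_result` with extra fields `n_links`, `n_significant`,
#'   `frac_significant`, `matrix`, `alpha`.
#' @export
run_congruence <- function(plant_tree, butterfly_tree, tables,
                           matrix = c("A", "X"), n_perm = 999, seed = NULL,
                           alpha = 0.05, correction = "none",
                           test_links = TRUE) {
  matrix <- match.arg(matrix)
  L <- tables[[matrix]]
  drop_r <- setdiff(rownames(L), plant_tree$tip.label)
  if (length(drop_r)) {
    message("dropping ", length(drop_r),
            " matrix row(s) absent from the plant tree: ",
            paste(drop_r, collapse = ", "))
    L <- L[setdiff(rownames(L), drop_r), , drop = FALSE]
  }
  drop_c <- setdiff(colnames(L), butterfly_tree$tip.label)
  if (length(drop_c)) {
    message("dropping ", length(drop_c),
            " matrix column(s) absent from the butterfly tree: ",
            paste(drop_c, collapse = ", "))
    L <- L[, setdiff(colnames(L), drop_c), drop = FALSE]
  }
  res <- .parafit_engine(patristic_distances(plant_tree),
                         patristic_distances(butterfly_tree),
                         L, n_perm, seed, test_links, correction)
  res$matrix <- matrix
  res$alpha <- alpha
  if (!is.null(res$links)) {
    res$n_links <- nrow(res$links)
    # significance by the normalized link statistic; when its denominator is
    # undefined (dense matrices can push the global trace past tracemax) fall
    # back to the raw link statistic
    if (all(is.na(res$links$p2))) {
      message("ParaFitLink2 undefined (global statistic exceeds tracemax); ",
              "link significance counted on the ParaFitLink1 statistic")
      res$significance_stat <- "F1"
      res$n_significant <- sum(res$links$p1 <= alpha, na.rm = TRUE)
    } else {
      res$significance_stat <- "F2"
      res$n_significant <- sum(res$links$p2 <= alpha, na.rm = TRUE)
    }
    res$frac_significant <- res$n_significant / res$n_links
  } else {
    res$n_links <- sum(L > 0)
  }
  res
}
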