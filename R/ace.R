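#' @title Ancestral host estimation under constrained Mk models
#' @description Maximum-likelihood estimation of ancestral host-plant states
#'   on a butterfly cladogram. Hosts are coded as six states: the four major
#'   angiosperm clades (magnoliids, monocots, basal-eudicots, core-eudicots),
#'   non-angiosperm plants, and animal food (entomophagy). Non-angiosperm and
#'   animal feeding are treated as derived, absorbing states: transitions out
#'   of them are fixed at zero, and all angiosperm-to-derived transitions
#'   share a single rate. Transitions among angiosperm clades follow one of
#'   three nested rate structures compared by AIC.
#' @name ace-module
NULL

#' Host character states, in fixed order
#' @export
HOST_STATES <- c("magnoliids", "monocots", "basal-eudicots", "core-eudicots",
                 "non-angiosperm", "animal")

DERIVED_STATES <- c("non-angiosperm", "animal")
BASAL_STATES <- c("magnoliids", "monocots", "basal-eudicots")

#' Constrained Mk rate model
#'
#' Builds the parameter-class matrix over the six host states. Entry `[i, j]`
#' is the index of the free rate governing the `i -> j` transition, or 0 for
#' transitions fixed at zero. In every model the two derived states are
#' absorbing and all angiosperm-to-derived transitions share one free rate.
#' The angiosperm block differs:
#' \describe{
#'   \item{one-rate}{all angiosperm-angiosperm transitions equal
#'     (2 free parameters in total).}
#'   \item{two-rate}{transitions from the basal clades (magnoliids, monocots,
#'     basal-eudicots) into core-eudicots get their own rate; all other
#'     angiosperm transitions share one (3 parameters).}
#'   \item{three-rate}{within-basal transitions, basal-to-core and
#'     core-to-basal each get a rate (4 parameters).}
#' }
#'
#' @param kind `"one-rate"`, `"two-rate"` or `"three-rate"`.
#' @return An object of class `mk_rate_model`: the 6x6 index matrix with
#'   attributes `kind`, `n_free` and `param_names`.
#' @export
rate_model <- function(kind = c("one-rate", "two-rate", "three-rate")) {
  kind <- match.arg(kind)
  k <- length(HOST_STATES)
  M <- matrix(0L, k, k, dimnames = list(HOST_STATES, HOST_STATES))
  ang <- setdiff(HOST_STATES, DERIVED_STATES)
  if (kind == "one-rate") {
    M[ang, ang] <- 1L
    M[ang, DERIVED_STATES] <- 2L
    pn <- c("angiosperm", "to_derived")
  } else if (kind == "two-rate") {
    M[ang, ang] <- 1L
    M[BASAL_STATES, "core-eudicots"] <- 2L
    M[ang, DERIVED_STATES] <- 3L
    pn <- c("angiosperm_other", "basal_to_core", "to_derived")
  } else {
    M[BASAL_STATES, BASAL_STATES] <- 1L
    M[BASAL_STATES, "core-eudicots"] <- 2L
    M["core-eudicots", BASAL_STATES] <- 3L
    M[ang, DERIVED_STATES] <- 4L
    pn <- c("within_basal", "basal_to_core", "core_to_basal", "to_derived")
  }
  diag(M) <- 0L
  structure(M, kind = kind, n_free = length(pn), param_names = pn,
            class = c("mk_rate_model", "matrix"))
}

#' Assemble the instantaneous rate matrix Q
#'
#' @param model An `mk_rate_model`.
#' @param rates Non-negative rate values, one per free parameter class.
#' @return The 6x6 rate matrix (rows sum to zero).
#' @export
build_Q <- function(model, rates) {
  if (length(rates) != attr(model, "n_free"))
    stop("expected ", attr(model, "n_free"), " rates")
  if (any(rates < 0)) stop("negative rate")
  Q <- matrix(0, nrow(model), ncol(model), dimnames = dimnames(model))
  nz <- model > 0L
  Q[nz] <- rates[model[nz]]
  diag(Q) <- -rowSums(Q)
  Q
}

.prior_vec <- function(root_prior, Q, logpart = NULL) {
  k <- nrow(Q)
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == k)
    return(root_prior / sum(root_prior))
  }
  switch(root_prior,
    uniform = rep(1 / k, k),
    stationary = {
      # limiting distribution from a uniform start (the derived states are
      # absorbing, so the chain has no unique stationary law; this is the
      # long-run law of the fitted process)
      scale <- max(abs(diag(Q)), 1e-8)
      as.vector(rep(1 / k, k) %*% as.matrix(Matrix::expm(Q * 50 / scale)))
    },
    fitzjohn = {
      w <- exp(logpart - max(logpart))
      w / sum(w)
    },
    stop("unknown root prior: ", root_prior))
}

.prep_tree_states <- function(tree, states) {
  validate_tree(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (is.null(names(states))) {
    if (length(states) != length(tree$tip.label))
      stop("states must be named by tip or match the tip count")
    names(states) <- tree$tip.label
  }
  if (!all(tree$tip.label %in% names(states)))
    stop("missing states for tips: ",
         paste(setdiff(tree$tip.label, names(states)), collapse = ", "))
  s <- as.character(states[tree$tip.label])
  bad <- !is.na(s) & !(s %in% HOST_STATES)
  if (any(bad)) stop("unknown state(s): ", paste(unique(s[bad]), collapse = ", "))
  tree <- ape::reorder.phylo(tree, "postorder")
  idx <- match(s, HOST_STATES)
  idx[is.na(idx)] <- 0L   # ambiguous
  list(tree = tree, tip_state = as.integer(idx))
}

#' Log-likelihood of an Mk model on a tree
#'
#' Felsenstein pruning with per-branch transition matrices `expm(Q t)`.
#' Polytomies are handled directly; zero-length branches give an identity
#' transition matrix. The root is handled with a prior over states (uniform
#' by default).
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param states Character vector of tip states (values in [HOST_STATES]),
#'   named by tip label; `NA` = ambiguous.
#' @param rates Rate values, one per free parameter of `model`.
#' @param model An `mk_rate_model`.
#' @param root_prior `"uniform"`, `"stationary"`, `"fitzjohn"`, or a numeric
#'   vector of six weights.
#' @return The log-likelihood (finite unless the data have zero probability).
#' @export
mk_loglik <- function(tree, states, rates, model, root_prior = "uniform") {
  pr <- .prep_tree_states(tree, states)
  Q <- build_Q(model, rates)
  lp <- .mk_root_logpartials(pr$tree$edge, pr$tree$edge.length, pr$tip_state, Q)
  prior <- .prior_vec(root_prior, Q, logpart = lp)
  lw <- log(prior) + lp
  m <- max(lw[is.finite(lw)], -Inf)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lw - m)))
}

#' Fit a constrained Mk model by maximum likelihood
#'
#' Bounded quasi-Newton optimization of the log-likelihood over log-rates,
#' from several log-spaced starting values (deterministic grid). Standard
#' errors come from the inverse observed information (numeric Hessian of the
#' negative log-likelihood at the MLE, on the rate scale).
#'
#' @inheritParams mk_loglik
#' @param kind Model kind, see [rate_model()].
#' @param n_starts Number of log-spaced starting rate values (>= 1; 5 by
#'   default).
#' @return An object of class `ace_fit`: list with `model`, `kind`, `rates`
#'   (named), `se`, `lnL`, `AIC`, `root_prior`, `convergence`.
#' @export
fit_mk <- function(tree, states, kind = c("one-rate", "two-rate", "three-rate"),
                   root_prior = "uniform", n_starts = 5) {
  kind <- match.arg(kind)
  model <- rate_model(kind)
  npar <- attr(model, "n_free")
  pr <- .prep_tree_states(tree, states)
  negll <- function(logr) {
    Q <- build_Q(model, exp(logr))
    lp <- .mk_root_logpartials(pr$tree$edge, pr$tree$edge.length,
                               pr$tip_state, Q)
    prior <- .prior_vec(root_prior, Q, logpart = lp)
    lw <- log(prior) + lp
    m <- max(lw[is.finite(lw)], -Inf)
    if (!is.finite(m)) return(1e10)
    -(m + log(sum(exp(lw - m))))
  }
  starts <- log(10^seq(-1.5, 1, length.out = max(1L, n_starts)))
  best <- NULL
  for (s0 in starts) {
    opt <- try(stats::optim(rep(s0, npar), negll, method = "L-BFGS-B",
                            lower = -18, upper = 8,
                            control = list(factr = 1e7, maxit = 500)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("optimization failed from every start")
  rates <- stats::setNames(exp(best$par), attr(model, "param_names"))
  lnL <- -best$value
  se <- rep(NA_real_, npar)
  H <- try(stats::optimHess(rates, function(r) negll(log(pmax(r, 1e-12)))),
           silent = TRUE)
  if (!inherits(H, "try-error")) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error") && all(diag(V) > 0)) {
      se <- sqrt(diag(V))
    } else {
      warning("observed information not positive definite; ",
              "likelihood may be flat in some rate -- SEs reported as NA")
    }
  }
  names(se) <- attr(model, "param_names")
  structure(list(model = model, kind = kind, rates = rates, se = se,
                 lnL = lnL, AIC = -2 * lnL + 2 * npar,
                 root_prior = root_prior, convergence = best$convergence),
            class = "ace_fit")
}

#' @export
print.ace_fit <- function(x, ...) {
  cat("Constrained Mk fit (", x$kind, "), root prior: ",
      if (is.character(x$root_prior)) x$root_prior else "custom", "\n", sep = "")
  est <- data.frame(rate = x$rates, se = x$se)
  print(est)
  cat("lnL =", format(x$lnL), "  AIC =", format(x$AIC), "\n")
  invisible(x)
}

#' Marginal ancestral state reconstruction
#'
#' Scaled likelihoods of each host state at every internal node: the marginal
#' (re-rooting / up-down) reconstruction under the fitted model, normalized to
#' sum to one per node. A `"conditional"` variant returns the normalized
#' downward (subtree-only) partial likelihoods for comparison.
#'
#' @inheritParams mk_loglik
#' @param fit An `ace_fit`.
#' @param method `"marginal"` (default) or `"conditional"`.
#' @return Matrix of scaled likelihoods, internal nodes x states; row names
#'   are node numbers in `tree$edge` numbering (root first).
#' @export
marginal_ancestral_states <- function(tree, states, fit,
                                      method = c("marginal", "conditional")) {
  method <- match.arg(method)
  pr <- .prep_tree_states(tree, states)
  tree <- pr$tree
  Q <- build_Q(fit$model, fit$rates)
  down <- .mk_down_partials(tree$edge, tree$edge.length, pr$tip_state, Q)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  k <- nrow(Q)
  L <- down$L
  if (method == "conditional") {
    out <- L[(ntip + 1):(ntip + nnode), , drop = FALSE] /
      rowSums(L[(ntip + 1):(ntip + nnode), , drop = FALSE])
    dimnames(out) <- list((ntip + 1):(ntip + nnode), HOST_STATES)
    return(out)
  }
  lp <- log(L[ntip + 1L, ]) + down$logscale[ntip + 1L]
  prior <- .prior_vec(fit$root_prior, Q, logpart = lp)
  # per-edge contribution of each child into its parent: P_e %*% L_child
  E <- nrow(tree$edge)
  contrib <- matrix(0, E, k)
  for (e in seq_len(E))
    contrib[e, ] <- down$P[, , e] %*% L[tree$edge[e, 2L], ]
  up <- matrix(0, ntip + nnode, k)
  up[ntip + 1L, ] <- prior
  for (e in rev(seq_len(E))) {   # preorder
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    sib_edges <- setdiff(which(tree$edge[, 1L] == p), e)
    above_p <- up[p, ]
    for (se_ in sib_edges) above_p <- above_p * contrib[se_, ]
    v <- as.vector(above_p %*% down$P[, , e])  # sum_s above[s] P[s, s']
    tot <- sum(v)
    up[ch, ] <- if (tot > 0) v / tot else v
  }
  marg <- up[(ntip + 1):(ntip + nnode), , drop = FALSE] *
    L[(ntip + 1):(ntip + nnode), , drop = FALSE]
  marg <- marg / rowSums(marg)
  dimnames(marg) <- list((ntip + 1):(ntip + nnode), HOST_STATES)
  marg
}

#' Compare the three constrained Mk models by AIC
#'
#' Fits the one-, two- and three-rate models and tabulates log-likelihood,
#' number of free parameters, AIC and delta-AIC relative to the best model.
#'
#' @inheritParams fit_mk
#' @param kinds Model kinds to fit.
#' @return List with `table` (data.frame sorted as given) and `fits` (named
#'   list of `ace_fit` objects).
#' @export
compare_models <- function(tree, states,
                           kinds = c("one-rate", "two-rate", "three-rate"),
                           root_prior = "uniform", n_starts = 5) {
  fits <- lapply(kinds, function(kk)
    fit_mk(tree, states, kk, root_prior = root_prior, n_starts = n_starts))
  names(fits) <- kinds
  tab <- data.frame(model = kinds,
                    lnL = vapply(fits, `[[`, numeric(1), "lnL"),
                    n_params = vapply(fits, function(f)
                      attr(f$model, "n_free"), integer(1)),
                    AIC = vapply(fits, `[[`, numeric(1), "AIC"))
  tab$dAIC <- tab$AIC - min(tab$AIC)
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}

#' Assign each subfamily its observed host state
#'
#' Aggregates the count matrix C by major plant clade and assigns each
#' subfamily the clade used by most of its recorded species. Ties are broken
#' toward the earlier state in [HOST_STATES] with a warning. Subfamilies
#' listed in `animal_subfamilies` (entomophagous groups whose records are
#' non-plant) are assigned `"animal"`; flagged subfamilies with no valid
#' records and no animal assignment get `NA`.
#'
#' @param tables An `association_tables` object.
#' @param clade_map Named character vector mapping every order in the tables
#'   to a major clade (see [read_clade_map()]).
#' @param animal_subfamilies Character vector of subfamilies to code as
#'   `"animal"`.
#' @return Named character vector of states per subfamily.
#' @export
assign_states <- function(tables, clade_map, animal_subfamilies = character()) {
  miss <- setdiff(tables$orders, names(clade_map))
  if (length(miss))
    stop("orders missing from clade map: ", paste(miss, collapse = ", "))
  clades <- factor(clade_map[tables$orders],
                   levels = setdiff(HOST_STATES, "animal"))
  out <- stats::setNames(rep(NA_character_, length(tables$subfamilies)),
                         tables$subfamilies)
  ties <- character(0)
  for (j in tables$subfamilies) {
    if (j %in% animal_subfamilies) { out[j] <- "animal"; next }
    if (j %in% tables$flagged) next
    tot <- tapply(tables$C[, j], clades, sum, default = 0)
    mx <- max(tot)
    top <- names(tot)[tot == mx]
    if (length(top) > 1L) ties <- c(ties, j)
    out[j] <- top[1L]   # tot is ordered by HOST_STATES levels
  }
  if (length(ties))
    warning("state ties broken toward the earlier-listed state for: ",
            paste(ties, collapse = ", "))
  out
}
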