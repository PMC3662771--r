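#' Configuration for the synthetic association generator
#'
#' Bundles the parameters controlling the statistical structure of a simulated
#' butterfly-host dataset:
#' \describe{
#'   \item{n_orders, n_subfamilies}{sizes of the plant and butterfly trees.}
#'   \item{congruence}{pi in [0, 1]: probability that a subfamily's focal host
#'     order is taken from the congruent (mirrored-position) map rather than
#'     at random. pi = 0 gives independent phylogenies, pi = 1 perfect
#'     congruence of focal hosts.}
#'   \item{clade_fidelity}{lambda >= 0: host orders are drawn with probability
#'     proportional to `exp(-lambda * patristic distance to the focal order)`;
#'     large lambda concentrates use on the focal order's clade.}
#'   \item{polyphagy}{g in (0, 1): each species uses `1 + Geometric(g)` host
#'     orders; g near 1 gives monophagy.}
#'   \item{beta0, beta1, sigma}{richness coupling: subfamily species counts
#'     are `round(exp(beta0 + beta1 * d_j + Normal(0, sigma)))` where `d_j` is
#'     a standard-normal latent host-breadth driver that also widens the
#'     subfamily's host range; beta1 = 0 decouples richness from diversity.}
#'   \item{retention}{optional named per-region record-retention probability
#'     (a crude regional sampling-bias knob); default keeps everything.}
#'   \item{seed}{master seed; every dataset is reproducible from (config).}
#' }
#'
#' @param n_orders,n_subfamilies Tree sizes (defaults 48 plant orders, 42
#'   butterfly subfamilies, the scale of a subfamily-level compilation).
#'   The default concentration and polyphagy values (`clade_fidelity = 30`,
#'   `polyphagy = 0.8` on height-1 trees) are calibrated so the generated
#'   association matrices match the gross structure of a real subfamily-level
#'   compilation: binary density of A near 15-25%, about 3 important links
#'   per subfamily, and host use concentrated on a focal clade with a tail of
#'   minor orders.
#' @param congruence,clade_fidelity,polyphagy,beta0,beta1,sigma,retention,seed
#'   See description.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_orders = 48, n_subfamilies = 42,
                             congruence = 0.5, clade_fidelity = 30,
                             polyphagy = 0.8, beta0 = 5, beta1 = 0.8,
                             sigma = 0.7, retention = NULL, seed = 1) {
  stopifnot(n_orders >= 3, n_subfamilies >= 3,
            congruence >= 0, congruence <= 1,
            clade_fidelity >= 0,
            polyphagy > 0, polyphagy < 1,
            sigma >= 0)
  structure(list(n_orders = n_orders, n_subfamilies = n_subfamilies,
                 congruence = congruence, clade_fidelity = clade_fidelity,
                 polyphagy = polyphagy, beta0 = beta0, beta1 = beta1,
                 sigma = sigma, retention = retention, seed = seed),
            class = "synthetic_config")
}

#' Simulate a Yule (pure-birth) tree topology
#'
#' Equal-rates Markov topology grown by repeatedly splitting a uniformly
#' chosen extant tip, with Grafen branch lengths applied afterward so the
#' output matches what the pipeline expects of any input cladogram.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Optional integer seed.
#' @param tip_prefix Tip label prefix (labels are `prefix1..prefixN`).
#' @return A `phylo` with Grafen branch lengths.
#' @export
simulate_yule_tree <- function(n_tips, seed = NULL, tip_prefix = "t") {
  stopifnot(n_tips >= 2)
  if (!is.null(seed)) set.seed(seed)
  # children[[i]]: integer pair of children of internal node i; tips negative
  children <- list(c(-1L, -2L))
  tips <- c(1L, 2L)         # current tip ids
  tip_owner <- c(1L, 1L)    # internal node and slot of each tip
  tip_slot <- c(1L, 2L)
  n <- 2L
  while (n < n_tips) {
    pick <- sample.int(n, 1L)
    node <- length(children) + 1L
    children[[node]] <- c(-tips[pick], n + 1L)
    children[[node]][2L] <- -(n + 1L)
    children[[tip_owner[pick]]][tip_slot[pick]] <- node
    n <- n + 1L
    tips[pick] <- tips[pick]          # old tip moves under new node
    tip_owner[pick] <- node; tip_slot[pick] <- 1L
    tips <- c(tips, n)
    tip_owner <- c(tip_owner, node); tip_slot <- c(tip_slot, 2L)
  }
  lab <- paste0(tip_prefix, seq_len(n_tips))
  nw <- function(v) {
    if (v < 0L) lab[-v]
    else paste0("(", nw(children[[v]][1L]), ",", nw(children[[v]][2L]), ")")
  }
  tree <- ape::read.tree(text = paste0(nw(1L), ";"))
  grafen_branch_lengths(tree)
}

#' Simulate Mk character evolution on a tree
#'
#' Waiting-time (Gillespie) simulation of the continuous-time Markov chain
#' along every branch; returns tip states and the true internal-node states
#' for recovery scoring.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param model An `mk_rate_model`.
#' @param rates Rate values for the model's free parameters.
#' @param root_state State at the root (one of [HOST_STATES]).
#' @param seed Optional integer seed.
#' @return List with `tip_states` (named character) and `node_states`.
#' @export
simulate_mk <- function(tree, model, rates, root_state = "magnoliids",
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- build_Q(model, rates)
  k <- nrow(Q)
  root_state <- match.arg(root_state, HOST_STATES)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  state <- integer(ntip + tree$Nnode)
  state[ntip + 1L] <- match(root_state, HOST_STATES)
  for (e in rev(seq_len(nrow(tree$edge)))) {  # preorder
    s <- state[tree$edge[e, 1L]]
    t_left <- tree$edge.length[e]
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      dt <- stats::rexp(1L, rate)
      if (dt > t_left) break
      t_left <- t_left - dt
      s <- sample.int(k, 1L, prob = Q[s, ] * (seq_len(k) != s))
    }
    state[tree$edge[e, 2L]] <- s
  }
  list(tip_states = stats::setNames(HOST_STATES[state[seq_len(ntip)]],
                                    tree$tip.label),
       node_states = HOST_STATES[state[(ntip + 1L):(ntip + tree$Nnode)]])
}

#' Simulate species counts from Fisher's log-series
#'
#' Hoppe-urn scheme: the i-th of N individuals founds a new species with
#' probability `alpha / (alpha + i - 1)`, otherwise it joins an existing
#' species proportionally to its abundance. The resulting abundance
#' distribution is the classical log-series with diversity parameter alpha;
#' the total count is exactly N.
#'
#' @param alpha Positive diversity parameter.
#' @param N Total number of individuals.
#' @param seed Optional integer seed.
#' @return Integer vector of species counts summing to N.
#' @export
simulate_logseries <- function(alpha, N, seed = NULL) {
  stopifnot(alpha > 0, N >= 1)
  if (!is.null(seed)) set.seed(seed)
  counts <- integer(0)
  for (i in seq_len(N)) {
    if (stats::runif(1L) < alpha / (alpha + i - 1)) {
      counts <- c(counts, 1L)
    } else {
      kk <- sample.int(length(counts), 1L, prob = counts)
      counts[kk] <- counts[kk] + 1L
    }
  }
  counts
}

#' Simulate a butterfly checklist and host-use records
#'
#' Generates the two delimited-text inputs the pipeline consumes, with
#' controllable co-phylogenetic signal. Each subfamily gets a focal host
#' order: with probability `congruence` the order in the mirrored tree
#' position (tips of both trees ranked by their appearance order, matched
#' proportionally), otherwise uniformly at random. Each species of the
#' subfamily uses `1 + Geometric(polyphagy)` orders drawn without replacement
#' with probability proportional to `exp(-clade_fidelity * patristic distance
#' to the focal order)`. Subfamily species counts follow the log-linear
#' richness coupling in [synthetic_config()].
#'
#' @param plant_tree,butterfly_tree `phylo` objects with branch lengths
#'   (tips: plant orders / butterfly subfamilies).
#' @param config A `synthetic_config`.
#' @return List with `checklist`, `records` (data.frames in the formats of
#'   [read_checklist()] / [read_host_records()]), `focal` (named focal order
#'   per subfamily), `breadth_driver` (the latent per-subfamily host-breadth
#'   driver `d_j`, kept for recovery scoring) and `config`.
#' @export
simulate_associations <- function(plant_tree, butterfly_tree, config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  orders <- plant_tree$tip.label
  subfams <- butterfly_tree$tip.label
  n_o <- length(orders); n_s <- length(subfams)
  Dp <- patristic_distances(plant_tree)

  # congruent focal map: rank tips in appearance order, match proportionally
  congruent <- orders[pmin(n_o, ceiling(seq_len(n_s) * n_o / n_s))]
  use_congruent <- stats::runif(n_s) < config$congruence
  focal <- ifelse(use_congruent, congruent, sample(orders, n_s, replace = TRUE))
  names(focal) <- subfams

  d_j <- stats::rnorm(n_s)   # latent host-breadth / richness driver
  R_j <- pmax(1L, as.integer(round(exp(
    config$beta0 + config$beta1 * d_j + stats::rnorm(n_s, 0, config$sigma)))))
  # wider-breadth subfamilies (larger d_j) get smaller geometric g
  g_j <- 1 / (1 + ((1 - config$polyphagy) / config$polyphagy) * exp(d_j))

  fam_of <- paste0("Fam", ceiling(seq_len(n_s) / 6))
  checklist <- list(); records <- list()
  for (j in seq_len(n_s)) {
    n_gen <- max(1L, round(sqrt(R_j[j])))
    genus <- paste0("Gen", j, "_", ((seq_len(R_j[j]) - 1L) %% n_gen) + 1L)
    species <- paste0("Sp", j, "_", seq_len(R_j[j]))
    region <- sample(REGION_CODES, R_j[j], replace = TRUE,
                     prob = c(0.2, 0.1, 0.3, 0.2, 0.15, 0.05))
    checklist[[j]] <- data.frame(species = species, genus = genus,
                                 subfamily = subfams[j], family = fam_of[j],
                                 region = region)
    w <- exp(-config$clade_fidelity * Dp[, focal[j]])
    n_hosts <- pmin(n_o, 1L + stats::rgeom(R_j[j], g_j[j]))
    hosts <- lapply(n_hosts, function(kk)
      sample(orders, kk, replace = FALSE, prob = w))
    records[[j]] <- data.frame(
      butterfly_species = rep(species, n_hosts),
      host_name = unlist(hosts), host_rank = "order", source = "synthetic")
  }
  checklist <- do.call(rbind, checklist)
  records <- do.call(rbind, records)
  if (!is.null(config$retention)) {
    keep_p <- config$retention[checklist$region[
      match(records$butterfly_species, checklist$species)]]
    keep_p[is.na(keep_p)] <- 1
    records <- records[stats::runif(nrow(records)) < keep_p, , drop = FALSE]
  }
  rownames(checklist) <- rownames(records) <- NULL
  list(checklist = checklist, records = records, focal = focal,
       breadth_driver = stats::setNames(d_j, subfams), config = config)
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: grows the plant and butterfly trees (Yule topologies
#' with Grafen lengths), simulates checklist and records, and builds a total
#' order-to-clade map by splitting the plant tree's tip order into the four
#' angiosperm clades plus a non-angiosperm block.
#'
#' @param config A `synthetic_config`.
#' @return List with `plant_tree`, `butterfly_tree`, `checklist`, `records`,
#'   `clade_map`, `focal`, `config`.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  plant_tree <- simulate_yule_tree(config$n_orders, seed = config$seed,
                                   tip_prefix = "Order")
  butterfly_tree <- simulate_yule_tree(config$n_subfamilies,
                                       seed = config$seed + 1L,
                                       tip_prefix = "Subfam")
  sim <- simulate_associations(plant_tree, butterfly_tree, config)
  clades <- setdiff(HOST_STATES, c("animal", "non-angiosperm"))
  breaks <- ceiling(seq_len(config$n_orders) * length(clades) /
                      config$n_orders)
  clade_map <- stats::setNames(clades[breaks], plant_tree$tip.label)
  c(list(plant_tree = plant_tree, butterfly_tree = butterfly_tree),
    sim["checklist"], sim["records"],
    list(clade_map = clade_map, focal = sim$focal, config = config))
}
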