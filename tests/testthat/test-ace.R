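test_that("rate model structures encode the constrained transition classes", {
  m1 <- rate_model("one-rate"); m2 <- rate_model("two-rate")
  m3 <- rate_model("three-rate")
  expect_equal(attr(m1, "n_free"), 2L)
  expect_equal(attr(m2, "n_free"), 3L)
  expect_equal(attr(m3, "n_free"), 4L)
  for (m in list(m1, m2, m3)) {
    # derived states are absorbing: whole rows fixed at zero
    expect_true(all(m["non-angiosperm", ] == 0L))
    expect_true(all(m["animal", ] == 0L))
    # all angiosperm -> derived transitions share one parameter
    ang <- setdiff(HOST_STATES, c("non-angiosperm", "animal"))
    expect_equal(length(unique(as.vector(m[ang, c("non-angiosperm", "animal")]))),
                 1L)
  }
  # two-rate: basal->core distinct from the rest of the angiosperm block
  expect_equal(unique(m2[c("magnoliids", "monocots", "basal-eudicots"),
                         "core-eudicots"]), 2L)
  expect_equal(m2["core-eudicots", "magnoliids"], 1L)

  Q <- build_Q(m3, c(0.1, 0.5, 0.2, 0.05))
  expect_equal(rowSums(Q), rep(0, 6), ignore_attr = TRUE, tolerance = 1e-14)
  expect_error(build_Q(m3, c(-0.1, 0.5, 0.2, 0.05)), "negative")
  expect_error(build_Q(m3, c(0.1, 0.5)), "expected")
})

test_that("pruning likelihood matches the symmetric-chain closed form", {
  # cherry (A:t, B:0): root state is pinned to B's state, so
  # L = (1/6) * P[state_B -> state_A](t); with derived rate 0 the four
  # angiosperm states form a symmetric 4-state chain with off-rate r:
  # P(stay) = 1/4 + 3/4 exp(-4 r t), P(move) = 1/4 - 1/4 exp(-4 r t)
  m <- rate_model("one-rate")
  for (tt in c(0.3, 1, 2.5)) for (r in c(0.2, 1)) {
    tr <- read_newick(sprintf("(A:%f,B:%f);", tt, 0))
    ll_move <- mk_loglik(tr, c(A = "monocots", B = "magnoliids"),
                         c(r, 0), m)
    expect_equal(ll_move, log((1 / 6) * (1 / 4 - exp(-4 * r * tt) / 4)),
                 tolerance = 1e-10)
    ll_stay <- mk_loglik(tr, c(A = "magnoliids", B = "magnoliids"),
                         c(r, 0), m)
    expect_equal(ll_stay, log((1 / 6) * (1 / 4 + 3 * exp(-4 * r * tt) / 4)),
                 tolerance = 1e-10)
  }
})

test_that("pruning equals brute-force enumeration and respects limits", {
  tr <- grafen_branch_lengths(read_newick("((A,B),(C,D));"))
  st <- c(A = "magnoliids", B = "monocots", C = "core-eudicots",
          D = "non-angiosperm")
  m <- rate_model("three-rate")
  rates <- c(0.3, 1.2, 0.15, 0.08)
  Q <- build_Q(m, rates)
  tr2 <- ape::reorder.phylo(tr, "postorder")
  P <- lapply(seq_len(nrow(tr2$edge)), function(e)
    as.matrix(Matrix::expm(Q * tr2$edge.length[e])))
  tipidx <- match(st[tr2$tip.label], HOST_STATES)
  tot <- 0
  for (s5 in 1:6) for (s6 in 1:6) for (s7 in 1:6) {
    ns <- c(tipidx, s5, s6, s7); pr <- 1 / 6
    for (e in seq_len(nrow(tr2$edge)))
      pr <- pr * P[[e]][ns[tr2$edge[e, 1]], ns[tr2$edge[e, 2]]]
    tot <- tot + pr
  }
  expect_equal(mk_loglik(tr, st, rates, m), log(tot), tolerance = 1e-12)

  # rates -> 0 with monomorphic tips: lnL -> log(prior) = log(1/6)
  mono <- c(A = "monocots", B = "monocots", C = "monocots", D = "monocots")
  expect_equal(mk_loglik(tr, mono, c(1e-12, 1e-12, 1e-12, 1e-12), m),
               log(1 / 6), tolerance = 1e-6)
  # likelihood invariant under relabeling the angiosperm states (one-rate
  # symmetry; the derived tip keeps its state)
  m1 <- rate_model("one-rate")
  st2 <- c(A = "core-eudicots", B = "basal-eudicots", C = "magnoliids",
           D = "non-angiosperm")
  expect_equal(mk_loglik(tr, st, c(0.4, 0.1), m1),
               mk_loglik(tr, st2, c(0.4, 0.1), m1), tolerance = 1e-12)
})

test_that("fit_mk matches an independent Mk fitter on the same model", {
  tr <- simulate_yule_tree(60, seed = 21)
  m <- rate_model("two-rate")
  sim <- simulate_mk(tr, m, c(0.3, 1.5, 0.2), root_state = "monocots",
                     seed = 22)
  f <- suppressWarnings(fit_mk(tr, sim$tip_states, "two-rate"))
  X <- matrix(0, length(tr$tip.label), 6,
              dimnames = list(tr$tip.label, HOST_STATES))
  X[cbind(tr$tip.label, sim$tip_states[tr$tip.label])] <- 1
  M <- matrix(as.integer(m), 6, 6, dimnames = list(HOST_STATES, HOST_STATES))
  ref <- suppressWarnings(phytools::fitMk(tr, X, model = M, pi = "equal"))
  expect_equal(f$lnL, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
  expect_equal(unname(f$rates), unname(ref$rates), tolerance = 1e-3)
  expect_equal(f$AIC, -2 * f$lnL + 2 * 3)
})

test_that("model comparison respects nesting and the AIC identity", {
  tr <- simulate_yule_tree(80, seed = 31)
  sim <- simulate_mk(tr, rate_model("two-rate"), c(0.15, 1.5, 0.1),
                     root_state = "magnoliids", seed = 32)
  cmp <- suppressWarnings(compare_models(tr, sim$tip_states))
  tab <- cmp$table
  expect_equal(tab$AIC, -2 * tab$lnL + 2 * tab$n_params)
  l <- stats::setNames(tab$lnL, tab$model)
  expect_gte(l["three-rate"], l["two-rate"] - 1e-6)
  expect_gte(l["two-rate"], l["one-rate"] - 1e-6)
  expect_equal(min(tab$dAIC), 0)
})

test_that("marginal reconstruction matches enumeration and its limits", {
  tr <- grafen_branch_lengths(read_newick("((A,B),(C,D));"))
  st <- c(A = "magnoliids", B = "monocots", C = "core-eudicots",
          D = "non-angiosperm")
  m <- rate_model("three-rate")
  rates <- c(0.3, 1.2, 0.15, 0.08)
  fit <- structure(list(model = m, rates = rates, root_prior = "uniform"),
                   class = "ace_fit")
  marg <- marginal_ancestral_states(tr, st, fit)
  expect_equal(unname(rowSums(marg)), rep(1, 3), tolerance = 1e-12)

  Q <- build_Q(m, rates)
  tr2 <- ape::reorder.phylo(tr, "postorder")
  P <- lapply(seq_len(nrow(tr2$edge)), function(e)
    as.matrix(Matrix::expm(Q * tr2$edge.length[e])))
  tipidx <- match(st[tr2$tip.label], HOST_STATES)
  joint <- function(ns) {
    pr <- 1 / 6
    for (e in seq_len(nrow(tr2$edge)))
      pr <- pr * P[[e]][ns[tr2$edge[e, 1]], ns[tr2$edge[e, 2]]]
    pr
  }
  for (node in 5:7) {
    bf <- sapply(1:6, function(sv) {
      tot <- 0
      for (s5 in 1:6) for (s6 in 1:6) for (s7 in 1:6) {
        ns <- c(tipidx, s5, s6, s7)
        if (ns[node] == sv) tot <- tot + joint(ns)
      }
      tot
    })
    expect_equal(unname(marg[as.character(node), ]), bf / sum(bf),
                 tolerance = 1e-10)
  }
  # conditional variant also normalizes
  cond <- marginal_ancestral_states(tr, st, fit, method = "conditional")
  expect_equal(unname(rowSums(cond)), rep(1, 3), tolerance = 1e-12)

  # rates -> 0 with monomorphic tips: ancestral state certain everywhere
  mono <- c(A = "monocots", B = "monocots", C = "monocots", D = "monocots")
  fit0 <- structure(list(model = m, rates = rep(1e-10, 4),
                         root_prior = "uniform"), class = "ace_fit")
  marg0 <- marginal_ancestral_states(tr, mono, fit0)
  expect_true(all(marg0[, "monocots"] > 1 - 1e-6))

  # root marginals invariant to child ordering
  trR <- ape::rotate(tr, 5)
  margR <- marginal_ancestral_states(trR, st, fit)
  expect_equal(unname(margR["5", ]), unname(marg["5", ]), tolerance = 1e-10)
})

test_that("derived states are absorbing in simulated histories", {
  tr <- simulate_yule_tree(10, seed = 41)
  m <- rate_model("one-rate")
  # with the root in a derived state nothing can ever leave it
  sim <- simulate_mk(tr, m, c(0.8, 0.5), root_state = "animal", seed = 42)
  expect_true(all(sim$tip_states == "animal"))
  # across many histories: any derived internal node has all-derived tips below
  set.seed(43)
  viol <- 0L
  for (i in 1:400) {
    sim <- simulate_mk(tr, m, c(0.8, 0.6), root_state = "magnoliids")
    post <- ape::reorder.phylo(tr, "postorder")
    all_states <- c(sim$tip_states[post$tip.label], sim$node_states)
    for (e in seq_len(nrow(post$edge))) {
      p <- post$edge[e, 1]; ch <- post$edge[e, 2]
      if (all_states[p] %in% c("non-angiosperm", "animal") &&
          !(all_states[ch] %in% c("non-angiosperm", "animal")))
        viol <- viol + 1L
    }
  }
  expect_equal(viol, 0L)
})

test_that("state assignment picks the dominant clade with deterministic ties", {
  cl <- data.frame(species = paste0("s", 1:6), genus = "G",
                   subfamily = rep(c("SubA", "SubB"), each = 3),
                   family = "F", region = "OR")
  recs <- data.frame(
    butterfly_species = c("s1", "s2", "s3", "s4", "s5", "s6"),
    host_name = c("OrdCore1", "OrdCore1", "OrdMono", "OrdMag", "OrdCore2",
                  "OrdMono"),
    host_rank = "order", source = "t")
  part <- validate_records(recs, cl, NULL,
                           c("OrdCore1", "OrdCore2", "OrdMono", "OrdMag"))
  tab <- build_matrices(part$valid, cl)
  cmap <- c(OrdCore1 = "core-eudicots", OrdCore2 = "core-eudicots",
            OrdMono = "monocots", OrdMag = "magnoliids")
  st <- suppressWarnings(assign_states(tab, cmap))
  expect_equal(unname(st["SubA"]), "core-eudicots")  # 2 core vs 1 monocot
  # SubB: 1 magnoliid, 1 core, 1 monocot -- three-way tie, earliest state wins
  expect_warning(st2 <- assign_states(tab, cmap), "tie")
  expect_equal(unname(st2["SubB"]), "magnoliids")
  # animal override
  st3 <- suppressWarnings(assign_states(tab, cmap,
                                        animal_subfamilies = "SubB"))
  expect_equal(unname(st3["SubB"]), "animal")
  expect_error(assign_states(tab, cmap[-1]), "missing from clade map")
})
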