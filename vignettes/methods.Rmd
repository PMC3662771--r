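---
title: "Methods: butterfly-host plant association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: butterfly-host plant association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery in `lepihost`: the models
and their assumptions, the tunable parameters and their defaults, the
numerical choices, what the synthetic-data generator does and does not
emulate, and the known limitations.

## Data model and association matrices

The pipeline starts from three delimited-text inputs: a species checklist
(species, genus, subfamily, family, region code among OR, NC, NT, AT, PA,
W), raw host-use records (butterfly species x host name at order, family,
genus or species rank), and a taxonomy map resolving sub-order host names to
plant orders. `validate_records()` partitions records into *valid*
(butterfly in the checklist, host resolvable to a plant order or the
non-angiosperm label), *non-plant* (detritus or animal resources), and
*discarded* (with machine-readable reasons: stop-list generic terms such as
"grasses" or "palms", blank hosts, unknown butterflies, unresolvable or
unknown host names). The three parts always partition the input; that is a
tested invariant.

`build_matrices()` counts *distinct species*, not records: `c_ij` is the
number of butterfly species of subfamily `j` with at least one valid record
on order `i`, so duplicated records are idempotent. `S_j` counts a
subfamily's recorded species, `R_j` its checklist (worldwide) species.
Proportions `z_ij = c_ij/S_j` can exceed 1 in column sum because species are
polyphagous. Both classification thresholds are strict as printed
conventions: *important* means `z_ij > 0.1`, *primary* means `z_ij > 0.9`,
and a `z_ij` exactly at a threshold does not qualify. Argmax ties for the
most important resource are broken by lexicographic order name and flagged.
Subfamilies with no valid plant records (e.g. strictly entomophagous groups)
keep an all-zero column, are flagged, and are excluded from the diversity
and correlation stages.

## Trees

All cladograms are calibrated with Grafen branch lengths: node height equals
`((m - 1)/(n - 1))^rho` for a node with `m` descendant tips on an `n`-tip
tree (`rho = 1` by default), giving an ultrametric tree of height 1. The
exponent is exposed but there is no reason to move it for rank-based
cladograms. Patristic distances, pruning and Newick I/O are delegated to
`ape`; every downstream statistic consumes only the distance matrix or the
edge list, so any externally calibrated tree can be substituted.

Soft polytomies are resolved deterministically (input child order) with
zero-length branches before computing contrasts; with Grafen lengths all
internal branches above the inserted nodes are strictly positive, so
contrast variances stay finite, and the Mk pruning likelihood is unchanged
by the resolution because a zero-length branch has an identity transition
matrix.

## Host diversity

Three measures per subfamily, deliberately spanning "taxon counting" to
"phylogeny-aware":

* **h** — number of plant orders used (column sums of **A**).
* **Fisher's log-series alpha** — fitted to the positive `c_ij` entries of a
  **C** column. The MLE solves `S = alpha log(1 + N/alpha)` (bisection-grade
  root finding via `uniroot` at tolerance 1e-12). The standard error uses
  the observed information of the Poisson-sampled log-series likelihood,
  `lnL = S log a + N log(N/(N+a)) - a log(1 + N/a)`, i.e.
  `se = 1/sqrt(S/a^2 - N/(a(N+a)))`. This convention is calibrated: in the
  test suite the mean reported SE matches the empirical sampling standard
  deviation of the estimator. Columns with a single positive entry carry no
  information and are reported as `alpha = 0` with no SE; all-singleton
  columns make the MLE diverge and are reported as missing in the diversity
  table with a warning.
* **Faith's PD** — total branch length of the minimal subtree connecting the
  used orders *and the root*. Root-inclusive PD makes a single-order
  subfamily's PD equal the tree height (1 on a Grafen tree), which keeps
  single-order rows interpretable; it is also the convention under which a
  one-order subfamily prints PD = 1.

The PD null draws `n_rand` (default 999, seedable) uniform samples of `h`
tips without replacement and reports the lower-tail rank probability
`p = (#{PD_rand <= PD_obs} + 1)/(n_rand + 1)`. Small p therefore means the
used orders are more phylogenetically *clumped* than a random sample of the
same size — the direction of interest for host-plant conservatism. The
one-tailed rule (rather than two-tailed) is the one under which subfamilies
whose PD sits above the null mean report large p rather than small p. The
null is exact in distribution (no asymptotics); its p-values are
super-uniform by construction and that calibration is asserted in the tests.

Correlations with species richness use `log R_j` (natural log) against each
measure, raw and through phylogenetically independent contrasts. Contrasts
follow Felsenstein's pruning recursion; the correlation of two contrast
vectors is computed through the origin, since contrasts have expectation
zero. Degrees of freedom are reported in both conventions — `df` =
(number of contrasts − 1), used for the p-value, and `df_origin` = one less,
the origin-regression convention — because published tables differ in which
accounting they print and the two cannot be distinguished from a printed
table alone.

## ParaFit congruence test

The global statistic uses principal coordinates of the two patristic
distance matrices (Gower double-centering; axes with non-positive
eigenvalues dropped by default, Cailliez or Lingoes corrections available —
patristic distances on trees are ordinarily representable, so corrections
are rarely needed). With **B** (orders x axes), **C** (subfamilies x axes)
and binary links **L**, the global statistic is `sum((B' L C)^2)`. The null
permutes each subfamily's column independently, preserving how many orders
each subfamily uses while randomizing which; `p = (#{stat_perm >= stat_obs}
+ 1)/(n_perm + 1)` with `n_perm = 999` by default. Per-link tests delete one
link at a time: F1 is the drop in the global statistic, F2 normalizes F1 by
`tracemax - global`, where `tracemax` is the larger of the two PCoAs' sums
of squared positive eigenvalues, following the cited method's reference
implementation; permutations for the link tests are coupled to the global
ones. The implementation is checked against `ape::parafit` to numerical
identity (statistics and p-values) and against exhaustive enumeration of all
within-column arrangements on a 3 x 3 system.

Two behaviors of the method worth knowing:

* **Dense link matrices degenerate F2.** When links are numerous the global
  trace can exceed `tracemax`, making the F2 denominator negative; F2 is
  then undefined (the reference implementation behaves identically).
  `run_congruence()` falls back to counting significant links on F1 with a
  message. The per-link normalization was designed for sparse host-parasite
  systems (about one link per parasite).
* **The null tests random association, not "no congruence given clumping".**
  If a subfamily's links are phylogenetically clumped on the plant tree, the
  within-column permutation null is violated even when the two phylogenies
  are unrelated, and rejection rates rise above nominal. The type-I
  calibration in the test suite therefore uses uniform host draws
  (`clade_fidelity = 0`); with clumping but no cross-tree signal the test is
  anticonservative by design of the original method.

The test is run on both **A** (all links) and **X** (important links only),
per candidate butterfly cladogram; link significance uses a caller-set
`alpha` (default 0.05), with no automatic multiplicity correction — tighter
thresholds are the caller's choice.

## Ancestral host estimation

Subfamily states aggregate **C** by major angiosperm clade (magnoliids,
monocots, basal-eudicots, core-eudicots — the last covering fabids, malvids
and asterids — plus non-angiosperm), taking the clade used by most species;
ties break toward the earlier-listed state with a warning, and entomophagous
subfamilies are assigned the animal state explicitly.

The Mk model has six states. Non-angiosperm and animal feeding are treated
as *derived, absorbing* states: all transitions out of them are fixed at
zero, and a single free rate is shared by every angiosperm-to-derived
transition (both derived states, all four sources). Sharing one rate keeps
the parameter counts at 2 (one-rate), 3 (two-rate) and 4 (three-rate), which
is the accounting under which the simplified and full models differ by
exactly one parameter. The angiosperm block varies: one-rate (all equal),
two-rate (basal-to-core distinct), three-rate (within-basal, basal-to-core,
core-to-basal).

Likelihoods use Felsenstein pruning with per-branch transition matrices
`P(t) = expm(Q t)`, implemented in C++ (RcppArmadillo). For speed, `Q` is
eigendecomposed once per likelihood evaluation and `P(t)` assembled per
branch (cached by branch length); when the eigenvector matrix is
ill-conditioned (reciprocal condition below 1e-3) the code falls back to the
Pade scaling-and-squaring matrix exponential per branch. The pruning value
is checked against exhaustive enumeration over all internal-state
assignments on small trees at 1e-12, and against a closed-form symmetric
chain on a single branch. The root uses a uniform prior over the six states
by default (`stationary` and `fitzjohn` priors are available behind a flag;
the absorbing states make the stationary law degenerate, so the uniform
prior is the sensible default for this model family).

Fitting maximizes over log-rates with bounded L-BFGS-B from five log-spaced
deterministic starts (1e-8-scale convergence tolerance); standard errors
come from the inverse observed information at the MLE on the rate scale.
When the information matrix is singular — typically a boundary rate
estimated at zero, e.g. no derived-state tips — SEs are reported as missing
with a warning rather than fabricated. AIC is `-2 lnL + 2k`; `compare_models()`
tabulates all three structures with delta-AIC.

Ancestral states are *marginal* scaled likelihoods from the up-down
(re-rooting) recursion, normalized to sum to one per node; a `conditional`
(subtree-only) variant is available behind a flag because published
"scaled likelihood" figures do not always say which of the two they show.
Marginals are checked against brute-force enumeration at 1e-10.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure of a subfamily-level
host-use compilation: Yule tree topologies with Grafen lengths; per-subfamily
species counts `R_j = round(exp(beta0 + beta1 d_j + N(0, sigma)))` with a
latent standard-normal breadth driver `d_j`; a focal host order per
subfamily, congruent (mirrored tree position) with probability `pi` and
uniform otherwise; per-species host sets of size `1 + Geometric(g)` drawn
without replacement with weight `exp(-lambda * patristic distance to the
focal order)`; and an optional per-region record-retention probability as a
crude sampling-bias knob.

Defaults (48 orders, 42 subfamilies, `pi = 0.5`, `lambda = 30`, `g = 0.8`,
`beta0 = 5`, `beta1 = 0.8`, `sigma = 0.7`) were calibrated once so the
generated matrices match the gross structure of a real compilation — binary
density of **A** around 15-25%, roughly three important links per subfamily,
host use concentrated on a focal clade with a tail of minor orders — and
then left alone. Two honest caveats:

* The `beta1 = 0` switch removes the *planted* richness-diversity coupling
  (the latent driver is returned for recovery scoring, and its decoupling is
  the tested invariant). Realized diversity measures retain a residual
  correlation with species number through sampling depth — more species
  means more draws, hence more orders observed and larger counts. Real
  compilations have exactly this effort artifact, so the generator
  reproduces it rather than hiding it; but it means a "null" synthetic
  dataset is null in mechanism, not in every realized statistic.
* The generator does not emulate taxonomic error, name-resolution noise,
  region-biased host identification, or the literature's duplication
  structure. Passing tests on synthetic data therefore validate the
  *computations*, not robustness to dirty real-world inputs beyond the
  validation stage's explicit rules.

Log-series counts for the estimator-recovery tests come from a Hoppe-urn
scheme (the i-th individual founds a new species with probability
`alpha/(alpha + i - 1)`), which yields exact totals and log-series abundance
structure with a single parameter.

## Problem sizes and reproducibility

Every stochastic routine takes an explicit seed and is bit-reproducible
given one; the pipeline's `run_all()` derives per-stage seeds from a master
seed and records them in a manifest. The test and acceptance runs use
moderate, fixed problem sizes chosen to estimate each property with
comfortable Monte-Carlo error: 200-tip trees for rate-recovery and
AIC-recovery simulations (100 and 30-50 replicates), 8 x 8 toys with 199
permutations for ParaFit calibration (100-400 replicates), 999
randomizations for PD nulls, and 500-1000 replicates for type-I error
estimates.

## Known limitations

* Host-name resolution is strictly table-driven; no fuzzy matching or live
  taxonomic services, by design.
* ParaFit's per-link F2 statistic degenerates on dense link matrices (see
  above); F1 is the fallback.
* The Mk model's derived states are permanently absorbing; reversals from
  non-angiosperm or animal feeding back to angiosperms cannot be estimated
  under this constraint (they are excluded by construction, not tested).
* Marginal scaled likelihoods condition on the fitted rate point estimates;
  uncertainty in the rates is not propagated into the node reconstructions.
* The importer for deposited R-data objects trusts object naming
  conventions (A/C/Z/X prefixes, `phylo` class) and verifies, but does not
  repair, matrix invariants.
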