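#' Pipeline run configuration
#'
#' Collects the inputs and settings for a full analysis run. Inputs may be
#' file paths (delimited text / Newick) or in-memory objects of the types the
#' readers return. Defaults reproduce the analysis settings: importance
#' threshold 0.1, primary threshold 0.9, 999 randomizations/permutations,
#' link significance 0.05, uniform root prior, all three Mk models.
#'
#' @param checklist,records,taxonomy,clade_map Paths or objects (see
#'   [read_checklist()], [read_host_records()], [read_taxonomy_map()],
#'   [read_clade_map()]); `taxonomy` may be `NULL`.
#' @param plant_tree Path or `phylo`.
#' @param butterfly_trees Named list of paths or `phylo` cladograms.
#' @param important,primary Resource-classification thresholds.
#' @param n_rand PD-null draws; `n_perm` ParaFit permutations.
#' @param alpha Link significance level.
#' @param ace_models Mk model kinds to fit.
#' @param root_prior Root prior for the Mk fits.
#' @param animal_subfamilies Subfamilies coded as animal-feeding.
#' @param seed Master seed; stage seeds are derived as documented offsets.
#' @param out_dir Output directory, or `NULL` for no files.
#' @return A list of class `run_config`.
#' @export
run_config <- function(checklist, records, plant_tree, butterfly_trees,
                       clade_map, taxonomy = NULL, important = 0.1,
                       primary = 0.9, n_rand = 999, n_perm = 999,
                       alpha = 0.05,
                       ace_models = c("one-rate", "two-rate", "three-rate"),
                       root_prior = "uniform",
                       animal_subfamilies = character(), seed = 1,
                       out_dir = NULL) {
  if (inherits(butterfly_trees, "phylo") || is.character(butterfly_trees))
    butterfly_trees <- list(cladogram = butterfly_trees)
  if (is.null(names(butterfly_trees)))
    names(butterfly_trees) <- paste0("cladogram", seq_along(butterfly_trees))
  structure(list(checklist = checklist, records = records,
                 taxonomy = taxonomy, plant_tree = plant_tree,
                 butterfly_trees = butterfly_trees, clade_map = clade_map,
                 important = important, primary = primary, n_rand = n_rand,
                 n_perm = n_perm, alpha = alpha, ace_models = ace_models,
                 root_prior = root_prior,
                 animal_subfamilies = animal_subfamilies, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

.load_input <- function(x, reader, what) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("missing input file for ", what, ": ", x)
    return(reader(x))
  }
  x
}

#' Run the full analysis pipeline
#'
#' Stage order: validate records, build association matrices, diversity table,
#' richness-diversity correlations, ParaFit congruence (matrices A and X, each
#' butterfly cladogram), ancestral-state estimation (each model kind, each
#' cladogram). A failure in one stage stops the run with a message naming the
#' stage. When `config$out_dir` is set, every stage writes TSV/JSON outputs
#' plus a manifest recording configuration, derived stage seeds and the
#' package version.
#'
#' Stage seeds are derived from the master seed: diversity uses `seed`,
#' ParaFit runs use `seed + 1000*i` for the i-th (cladogram x matrix)
#' combination.
#'
#' @param config A [run_config()].
#' @return A result bundle (list) with elements `partition`, `tables`,
#'   `classification`, `representativeness`, `usage`, `diversity`,
#'   `correlations`, `parafit`, `ace`, `states`, `manifest`, invisibly.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    message("[lepihost] stage: ", name)
    tryCatch(force(expr),
             error = function(e) stop("stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }
  checklist <- stage("read checklist",
                     .load_input(config$checklist, read_checklist, "checklist"))
  records <- stage("read records",
                   .load_input(config$records, read_host_records, "records"))
  taxonomy <- stage("read taxonomy",
                    .load_input(config$taxonomy, read_taxonomy_map, "taxonomy"))
  plant_tree <- stage("read plant tree",
                      .load_input(config$plant_tree, read_newick, "plant tree"))
  btrees <- stage("read butterfly trees", lapply(
    config$butterfly_trees,
    function(x) .load_input(x, read_newick, "butterfly tree")))
  clade_map <- stage("read clade map",
                     .load_input(config$clade_map, read_clade_map, "clade map"))
  if (is.null(plant_tree$edge.length))
    plant_tree <- grafen_branch_lengths(plant_tree)
  btrees <- lapply(btrees, function(tr)
    if (is.null(tr$edge.length)) grafen_branch_lengths(tr) else tr)

  part <- stage("validate records",
                validate_records(records, checklist, taxonomy,
                                 plant_orders = plant_tree$tip.label))
  tables <- stage("association matrices",
                  build_matrices(part$valid, checklist,
                                 important = config$important))
  classification <- stage("resource classification",
                          classify_resources(tables, config$important,
                                             config$primary))
  represent <- stage("representativeness",
                     representativeness_summary(checklist, part$valid))
  usage <- stage("usage frequencies", usage_frequency_summary(part$valid))
  div <- stage("diversity table",
               diversity_table(tables, plant_tree, n_rand = config$n_rand,
                               seed = config$seed))
  corr <- stage("richness correlations", richness_correlations(div, btrees))

  pf <- list(); i <- 0L
  for (tn in names(btrees)) for (m in c("A", "X")) {
    i <- i + 1L
    pf[[paste(tn, m, sep = ".")]] <- stage(
      paste0("parafit (", tn, ", ", m, ")"),
      run_congruence(plant_tree, btrees[[tn]], tables, matrix = m,
                     n_perm = config$n_perm, seed = config$seed + 1000L * i,
                     alpha = config$alpha))
  }

  states <- stage("state assignment",
                  assign_states(tables, clade_map,
                                animal_subfamilies = config$animal_subfamilies))
  ace <- list()
  for (tn in names(btrees)) {
    tr <- btrees[[tn]]
    ok <- names(states)[!is.na(states)]
    keep <- intersect(tr$tip.label, ok)
    tr2 <- prune_to(tr, keep)
    cmp <- stage(paste0("ancestral states (", tn, ")"),
                 compare_models(tr2, states[keep], kinds = config$ace_models,
                                root_prior = config$root_prior))
    best <- cmp$fits[[which.min(cmp$table$AIC)]]
    marg <- stage(paste0("marginal reconstruction (", tn, ")"),
                  marginal_ancestral_states(tr2, states[keep], best))
    ace[[tn]] <- list(comparison = cmp$table, fits = cmp$fits, best = best,
                      node_likelihoods = marg)
  }

  manifest <- list(
    package = "lepihost",
    version = as.character(utils::packageVersion("lepihost")),
    seed = config$seed,
    n_rand = config$n_rand, n_perm = config$n_perm,
    important = config$important, primary = config$primary,
    alpha = config$alpha, ace_models = config$ace_models,
    root_prior = config$root_prior,
    cladograms = names(btrees),
    parafit_runs = names(pf),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  bundle <- list(partition = part, tables = tables,
                 classification = classification,
                 representativeness = represent, usage = usage,
                 diversity = div, correlations = corr, parafit = pf,
                 ace = ace, states = states, manifest = manifest)
  if (!is.null(config$out_dir)) .write_bundle(bundle, config$out_dir)
  invisible(bundle)
}

.write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_association_tables(bundle$tables, file.path(dir, "matrices"))
  wtsv <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wtsv(bundle$diversity, "diversity.tsv")
  wtsv(bundle$correlations, "correlations.tsv")
  wtsv(bundle$classification, "classification.tsv")
  for (nm in names(bundle$parafit)) {
    res <- bundle$parafit[[nm]]
    jsonlite::write_json(
      list(global_stat = res$global_stat, global_p = res$global_p,
           n_perm = res$n_perm, seed = res$seed, matrix = res$matrix,
           n_links = res$n_links, n_significant = res$n_significant,
           frac_significant = res$frac_significant, links = res$links),
      file.path(dir, paste0("parafit_", nm, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  for (nm in names(bundle$ace)) {
    a <- bundle$ace[[nm]]
    jsonlite::write_json(
      list(comparison = a$comparison,
           best_model = a$best$kind,
           rates = as.list(a$best$rates), se = as.list(a$best$se),
           lnL = a$best$lnL, AIC = a$best$AIC,
           node_likelihoods = as.data.frame(a$node_likelihoods)),
      file.path(dir, paste0("ace_", nm, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Import deposited association matrices and trees from an R-data file
#'
#' Converts an `.RData`/`.rda` deposit containing the association matrices
#' (objects whose names contain `A`/`C`/`Z`/`X`, e.g. `Aij`) and `phylo`
#' trees into the pipeline's native TSV and Newick formats, and checks the
#' type invariants (`A = 1[C > 0]`, `0 <= Z <= 1`, `X = 1[Z > 0.1]`).
#' Violations are reported, not fatal: the deposited matrices are treated as
#' authoritative.
#'
#' @param path Path to the R-data file.
#' @param out_dir Optional directory for the converted TSV/Newick files.
#' @param important Threshold used to recompute X for the invariant check.
#' @return List with `matrices` (named list), `trees` (named list of `phylo`)
#'   and `violations` (character vector of messages).
#' @export
import_dataset_s1 <- function(path, out_dir = NULL, important = 0.1) {
  if (!file.exists(path))
    stop("cannot read '", path, "'; supply the deposited R-data file or ",
         "TSV equivalents of the A/C/Z/X matrices and Newick trees")
  env <- new.env(parent = emptyenv())
  ok <- try(load(path, envir = env), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot load '", path, "' as R data; supply TSV equivalents instead")
  objs <- mget(ls(env), envir = env)
  trees <- Filter(function(o) inherits(o, "phylo"), objs)
  mats <- Filter(function(o) is.matrix(o) || is.data.frame(o), objs)
  find_mat <- function(letter) {
    hit <- grep(paste0("^", letter), names(mats), ignore.case = FALSE)
    if (length(hit)) as.matrix(mats[[hit[1L]]]) else NULL
  }
  M <- list(A = find_mat("A"), C = find_mat("C"), Z = find_mat("Z"),
            X = find_mat("X"))
  violations <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    message(msg)
    violations <<- c(violations, msg)
  }
  if (!is.null(M$A) && !is.null(M$C)) {
    if (!all((M$C > 0) == (M$A > 0)))
      note("invariant violation: A != indicator(C > 0) in ",
           sum((M$C > 0) != (M$A > 0)), " cell(s)")
  }
  if (!is.null(M$Z)) {
    if (any(M$Z < 0 | M$Z > 1, na.rm = TRUE))
      note("invariant violation: Z outside [0, 1]")
    if (!is.null(M$X)) {
      Xre <- (M$Z > important) + 0
      if (!all(Xre == (M$X > 0) + 0, na.rm = TRUE))
        note("invariant violation: X != indicator(Z > ", important, ") in ",
             sum(Xre != ((M$X > 0) + 0), na.rm = TRUE),
             " cell(s); deposited X kept as authoritative")
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(M)) if (!is.null(M[[nm]]))
      utils::write.table(M[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, col.names = NA)
    for (nm in names(trees))
      write_newick(trees[[nm]], file.path(out_dir, paste0(nm, ".nwk")))
  }
  list(matrices = M, trees = trees, violations = violations)
}
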