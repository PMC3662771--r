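#' Build the four association matrices
#'
#' From validated records, constructs the plant-order by butterfly-subfamily
#' association tables:
#' \describe{
#'   \item{C}{`c_ij` = number of distinct butterfly species of subfamily `j`
#'     with at least one valid record on order `i` (duplicates collapse).}
#'   \item{A}{binary presence, `a_ij = 1` iff `c_ij > 0`.}
#'   \item{Z}{proportions `z_ij = c_ij / S_j`, where `S_j` is the number of
#'     distinct recorded species of subfamily `j`. Polyphagy means column sums
#'     of Z can exceed 1.}
#'   \item{X}{important links, `x_ij = 1` iff `z_ij > important` (strict).}
#' }
#' All checklist subfamilies are retained as columns; those without any valid
#' record keep an all-zero column (Z set to 0) and are flagged.
#'
#' @param valid Valid records (the `valid` element of [validate_records()]).
#' @param checklist Species checklist; supplies the subfamily set and the
#'   worldwide richness `R_j`.
#' @param important Strict threshold on `z_ij` defining matrix X (default 0.1).
#' @return An object of class `association_tables`: list with `orders`,
#'   `subfamilies`, matrices `A`, `C`, `Z`, `X`, vectors `S`, `R`, and
#'   `flagged` (subfamilies with no valid records).
#' @export
build_matrices <- function(valid, checklist, important = 0.1) {
  if (nrow(valid) == 0L) stop("no valid records")
  checklist <- validate_checklist(checklist)
  if (!all(valid$subfamily %in% checklist$subfamily))
    stop("records with subfamilies absent from the checklist")
  orders <- sort(unique(valid$host_order))
  subfams <- sort(unique(checklist$subfamily))

  pairs <- unique(valid[, c("butterfly_species", "host_order", "subfamily")])
  C <- matrix(0L, length(orders), length(subfams),
              dimnames = list(orders, subfams))
  tab <- table(factor(pairs$host_order, levels = orders),
               factor(pairs$subfamily, levels = subfams))
  C[] <- as.integer(tab)

  sp <- unique(valid[, c("butterfly_species", "subfamily")])
  S <- as.integer(table(factor(sp$subfamily, levels = subfams)))
  names(S) <- subfams
  R <- as.integer(table(factor(checklist$subfamily, levels = subfams)))
  names(R) <- subfams

  flagged <- subfams[S == 0L]
  if (length(flagged))
    warning("subfamilies with no valid records (all-zero columns): ",
            paste(flagged, collapse = ", "))
  Z <- sweep(C, 2L, pmax(S, 1L), `/`)
  A <- (C > 0L) + 0L
  X <- (Z > important) + 0L
  structure(list(orders = orders, subfamilies = subfams,
                 A = A, C = C, Z = Z, X = X, S = S, R = R,
                 important = important, flagged = flagged),
            class = "association_tables")
}

#' @export
print.association_tables <- function(x, ...) {
  cat("Association tables:", length(x$orders), "plant orders x",
      length(x$subfamilies), "butterfly subfamilies\n")
  cat("  recorded species (sum S_j):", sum(x$S),
      "; links in A:", sum(x$A), "; links in X:", sum(x$X), "\n")
  if (length(x$flagged))
    cat("  flagged (no valid records):", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Classify host resources per subfamily
#'
#' Applies the strict proportion thresholds: an order is *important* for a
#' subfamily if `z_ij > important`, the *most important* resource is the order
#' with the highest `z_ij` (ties broken by lexicographic order name and
#' flagged), and a *primary* resource is an order with `z_ij > primary`.
#'
#' @param tables An `association_tables` object.
#' @param important,primary Strict thresholds (defaults 0.1 and 0.9).
#' @return A data.frame with one row per subfamily: `most_important`,
#'   `max_z`, `tie` (logical), `primary` (or NA), `important`
#'   (comma-separated orders), `n_important`.
#' @export
classify_resources <- function(tables, important = tables$important,
                               primary = 0.9) {
  Z <- tables$Z
  out <- lapply(colnames(Z), function(j) {
    z <- Z[, j]
    if (all(z == 0)) {
      return(data.frame(subfamily = j, most_important = NA_character_,
                        max_z = 0, tie = FALSE, primary = NA_character_,
                        important = "", n_important = 0L))
    }
    mx <- max(z)
    top <- sort(names(z)[z == mx])
    imp <- sort(names(z)[z > important])
    prim <- sort(names(z)[z > primary])
    data.frame(subfamily = j, most_important = top[1L], max_z = mx,
               tie = length(top) > 1L,
               primary = if (length(prim)) prim[1L] else NA_character_,
               important = paste(imp, collapse = ","),
               n_important = length(imp))
  })
  out <- do.call(rbind, out)
  if (any(out$tie))
    warning("argmax ties broken lexicographically for: ",
            paste(out$subfamily[out$tie], collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Representativeness of the compilation
#'
#' Summarizes how completely the host-record compilation covers the checklist:
#' species counts and proportions with records per region x family (with a
#' totals row), and genera/species worldwide versus in the compilation per
#' subfamily.
#'
#' @param checklist Species checklist.
#' @param valid Valid records.
#' @return A list with data.frames `region_family` and `subfamily`.
#' @export
representativeness_summary <- function(checklist, valid) {
  checklist <- validate_checklist(checklist)
  has_rec <- checklist$species %in% valid$butterfly_species

  rf <- stats::aggregate(cbind(n_species = rep(1L, nrow(checklist)),
                               n_with_records = as.integer(has_rec)),
                         by = list(region = checklist$region,
                                   family = checklist$family), FUN = sum)
  rf$proportion <- rf$n_with_records / rf$n_species
  total <- data.frame(region = "Total", family = "Total",
                      n_species = sum(rf$n_species),
                      n_with_records = sum(rf$n_with_records))
  total$proportion <- total$n_with_records / total$n_species
  rf <- rbind(rf, total)

  sf <- do.call(rbind, lapply(split(checklist, checklist$subfamily), function(d) {
    rec <- d$species %in% valid$butterfly_species
    data.frame(subfamily = d$subfamily[1L],
               genera_worldwide = length(unique(d$genus)),
               genera_compilation = length(unique(d$genus[rec])),
               species_worldwide = nrow(d),
               species_compilation = sum(rec))
  }))
  sf$genera_proportion <- sf$genera_compilation / sf$genera_worldwide
  sf$species_proportion <- sf$species_compilation / sf$species_worldwide
  rownames(sf) <- NULL
  list(region_family = rf, subfamily = sf)
}

#' Most used host plants at each rank
#'
#' Ranks plant orders, families, genera and species by the number of distinct
#' butterfly species recorded on them (a butterfly species counts once per
#' host taxon however many records it has).
#'
#' @param valid Valid records, with the resolved `host_*` columns attached by
#'   [validate_records()].
#' @return A list of data.frames (`order`, `family`, `genus`, `species`), each
#'   with columns `name` and `n_species`, sorted by decreasing use.
#' @export
usage_frequency_summary <- function(valid) {
  rank_one <- function(col) {
    d <- valid[!is.na(valid[[col]]), c("butterfly_species", col)]
    if (nrow(d) == 0L)
      return(data.frame(name = character(), n_species = integer()))
    d <- unique(d)
    tb <- sort(table(d[[col]]), decreasing = TRUE)
    data.frame(name = names(tb), n_species = as.integer(tb))
  }
  list(order = rank_one("host_order"), family = rank_one("host_family"),
       genus = rank_one("host_genus"), species = rank_one("host_species"))
}

#' Write association tables to disk
#'
#' Matrices go to TSV (orders as rows, subfamilies as columns); `S_j`, `R_j`
#' and the flagged subfamilies to a JSON sidecar.
#'
#' @param tables An `association_tables` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_association_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in c("A", "C", "Z", "X"))
    utils::write.table(tables[[m]], file.path(dir, paste0(m, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
  jsonlite::write_json(
    list(S = as.list(tables$S), R = as.list(tables$R),
         important = tables$important, flagged = tables$flagged),
    file.path(dir, "tables.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
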