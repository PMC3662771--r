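#' @title Host-use record handling
#' @description Readers and the validation/partition step that turns a raw
#'   compilation of butterfly-host plant records into the valid, non-plant and
#'   discarded sets the rest of the pipeline consumes.
#' @name records
NULL

REGION_CODES <- c("OR", "NC", "NT", "AT", "PA", "W")
NONPLANT_LABELS <- c("detritus", "animal")
NONANGIOSPERM_LABEL <- "non-angiosperm"
DEFAULT_STOP_LIST <- c("grasses", "palms")

# Rename columns of a delimited file according to a user-declared mapping
# (names = canonical, values = names in the file), then check presence.
.read_table <- function(file, required, columns = NULL, sep = "\t") {
  df <- utils::read.delim(file, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!is.null(columns)) {
    for (canon in names(columns)) {
      j <- match(columns[[canon]], names(df))
      if (is.na(j)) stop("declared column '", columns[[canon]], "' not found in ", file)
      names(df)[j] <- canon
    }
  }
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing column(s) in ", file, ": ", paste(miss, collapse = ", "))
  df
}

#' Read a butterfly species checklist
#'
#' One row per species with its genus, subfamily, family and biogeographic
#' region. Region codes outside the six recognized ones (OR, NC, NT, AT, PA,
#' W) are coerced to "W" (widespread) with a warning.
#'
#' @param file Delimited text file.
#' @param columns Optional named character vector mapping the canonical names
#'   (`species`, `genus`, `subfamily`, `family`, `region`) to the column names
#'   used in the file.
#' @param sep Field separator (default tab).
#' @return A data.frame with the five canonical columns.
#' @export
read_checklist <- function(file, columns = NULL, sep = "\t") {
  df <- .read_table(file, c("species", "genus", "subfamily", "family", "region"),
                    columns, sep)
  validate_checklist(df)
}

validate_checklist <- function(df) {
  if (anyDuplicated(df$species))
    stop("checklist has duplicate species names: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  bad <- !(df$region %in% REGION_CODES)
  if (any(bad)) {
    warning(sum(bad), " species with unknown region code set to 'W'")
    df$region[bad] <- "W"
  }
  df
}

#' Read raw host-use records
#'
#' @param file Delimited text file with at least `butterfly_species`,
#'   `host_name` and `host_rank` (one of species/genus/family/order) columns;
#'   a `source` column is kept if present.
#' @inheritParams read_checklist
#' @return A data.frame of raw records.
#' @export
read_host_records <- function(file, columns = NULL, sep = "\t") {
  df <- .read_table(file, c("butterfly_species", "host_name", "host_rank"),
                    columns, sep)
  if (is.null(df$source)) df$source <- NA_character_
  df
}

#' Read a host-name taxonomy map
#'
#' Resolves host names given at species, genus or family rank to a plant
#' order (and optionally to parent genus/family, used by the usage-frequency
#' summaries). Columns: `name`, `rank`, `order`, and optionally `family`,
#' `genus`.
#'
#' @inheritParams read_checklist
#' @return A data.frame.
#' @export
read_taxonomy_map <- function(file, columns = NULL, sep = "\t") {
  df <- .read_table(file, c("name", "rank", "order"), columns, sep)
  if (is.null(df$family)) df$family <- NA_character_
  if (is.null(df$genus)) df$genus <- NA_character_
  df
}

#' Read a plant-order to major-clade map
#'
#' Maps every plant order to one of the major clades used as ancestral-host
#' character states: magnoliids, monocots, basal-eudicots, core-eudicots
#' (fabids, malvids and asterids), or non-angiosperm.
#'
#' @inheritParams read_checklist
#' @return A named character vector (names = orders, values = clades).
#' @export
read_clade_map <- function(file, columns = NULL, sep = "\t") {
  df <- .read_table(file, c("order", "clade"), columns, sep)
  bad <- setdiff(unique(df$clade), setdiff(HOST_STATES, "animal"))
  if (length(bad)) stop("unknown clade label(s): ", paste(bad, collapse = ", "))
  stats::setNames(df$clade, df$order)
}

#' Validate and partition host-use records
#'
#' Splits raw records into three disjoint sets covering the input:
#' \describe{
#'   \item{valid}{butterfly species is in the checklist and the host name
#'     resolves to a plant order (or the non-angiosperm label); the resolved
#'     `host_order` and the butterfly's checklist taxonomy are attached.}
#'   \item{nonplant}{host is a non-plant resource (detritus or animal).}
#'   \item{discarded}{everything else, with a machine-readable `reason`:
#'     `generic_term` (stop-list names such as "grasses"), `blank_host`,
#'     `unknown_butterfly`, `unresolved_host`, or `unknown_order`.}
#' }
#'
#' @param records Raw records (see [read_host_records()]).
#' @param checklist Species checklist (see [read_checklist()]).
#' @param taxonomy Taxonomy map resolving family/genus/species host names to
#'   orders, or `NULL` if all records are already at order rank.
#' @param plant_orders Character vector of plant orders accepted as valid
#'   (normally the tip set of the plant-order phylogeny).
#' @param stop_list Lower-case generic host terms to discard.
#' @param nonplant_labels Host names treated as non-plant resources.
#' @param nonangiosperm_label Host-order label for non-angiosperm plants,
#'   accepted as valid even though it is not a tip of the angiosperm tree.
#' @return A list of class `host_record_partition` with elements `valid`,
#'   `nonplant`, `discarded`.
#' @export
validate_records <- function(records, checklist, taxonomy = NULL, plant_orders,
                             stop_list = DEFAULT_STOP_LIST,
                             nonplant_labels = NONPLANT_LABELS,
                             nonangiosperm_label = NONANGIOSPERM_LABEL) {
  if (is.null(records) || nrow(records) == 0L) stop("no records supplied")
  checklist <- validate_checklist(checklist)
  records$host_order <- NA_character_
  records$host_family <- NA_character_
  records$host_genus <- NA_character_
  records$host_species <- NA_character_

  is_order <- records$host_rank == "order"
  records$host_order[is_order] <- records$host_name[is_order]
  if (!is.null(taxonomy)) {
    m <- match(paste(records$host_name, records$host_rank),
               paste(taxonomy$name, taxonomy$rank))
    hit <- !is.na(m) & !is_order
    records$host_order[hit] <- taxonomy$order[m[hit]]
    records$host_family[hit] <- taxonomy$family[m[hit]]
    records$host_genus[hit] <- taxonomy$genus[m[hit]]
  }
  records$host_family[records$host_rank == "family"] <-
    records$host_name[records$host_rank == "family"]
  records$host_genus[records$host_rank == "genus"] <-
    records$host_name[records$host_rank == "genus"]
  records$host_species[records$host_rank == "species"] <-
    records$host_name[records$host_rank == "species"]

  reason <- rep(NA_character_, nrow(records))
  host_lc <- tolower(trimws(records$host_name))
  reason[host_lc %in% tolower(stop_list)] <- "generic_term"
  reason[is.na(records$host_name) | host_lc == ""] <- "blank_host"
  known_bfly <- records$butterfly_species %in% checklist$species
  reason[is.na(reason) & !known_bfly] <- "unknown_butterfly"

  nonplant <- is.na(reason) &
    (host_lc %in% tolower(nonplant_labels) |
       tolower(records$host_order) %in% tolower(nonplant_labels))
  ok_order <- records$host_order %in% c(plant_orders, nonangiosperm_label)
  reason[is.na(reason) & !nonplant & is.na(records$host_order)] <- "unresolved_host"
  reason[is.na(reason) & !nonplant & !is.na(records$host_order) & !ok_order] <-
    "unknown_order"

  valid <- is.na(reason) & !nonplant
  ix <- match(records$butterfly_species, checklist$species)
  records$subfamily <- checklist$subfamily[ix]
  records$family <- checklist$family[ix]
  records$region <- checklist$region[ix]

  out <- list(
    valid = records[valid, , drop = FALSE],
    nonplant = records[nonplant, , drop = FALSE],
    discarded = cbind(records[!valid & !nonplant, , drop = FALSE],
                      reason = reason[!valid & !nonplant])
  )
  class(out) <- "host_record_partition"
  out
}

#' @export
print.host_record_partition <- function(x, ...) {
  cat("Host-use record partition:\n")
  cat("  valid:    ", nrow(x$valid), "\n")
  cat("  nonplant: ", nrow(x$nonplant), "\n")
  cat("  discarded:", nrow(x$discarded), "\n")
  if (nrow(x$discarded))
    print(table(x$discarded$reason))
  invisible(x)
}
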