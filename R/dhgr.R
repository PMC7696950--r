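#' Reference map for the nine apportionment regions
#'
#' Each of the nine Distinct Human Genetics Regions is represented by three
#' reference populations — the populations of that region sharing the least
#' IBD with the rest of the world, i.e. the least admixed. The selection is
#' empirical, so the map is configuration, not computation.
#'
#' @param refs named list: each of the nine region codes in [DHGR_REGIONS]
#'   mapped to a character vector of exactly 3 population identifiers; no
#'   population may appear twice.
#' @return an object of class `dhgr_reference_map`.
#' @export
dhgr_reference_map <- function(refs) {
  if (!setequal(names(refs), DHGR_REGIONS)) {
    stop_("reference map must cover exactly the nine regions: ",
          paste(DHGR_REGIONS, collapse = ", "))
  }
  refs <- refs[DHGR_REGIONS]
  if (any(lengths(refs) != 3)) {
    stop_("each region needs exactly 3 reference populations")
  }
  all_refs <- unlist(refs, use.names = FALSE)
  if (anyDuplicated(all_refs)) {
    stop_("duplicate reference population(s): ",
          paste(unique(all_refs[duplicated(all_refs)]), collapse = ", "))
  }
  structure(refs, class = "dhgr_reference_map")
}

#' Apportion a population's relatedness over the nine regions
#'
#' For each region the raw sum is the sum, over its three reference
#' populations, of the population's per-pair normalized shared-IBD value,
#' with each per-pair value capped at `cap` (default 100) beforehand. The
#' cap damps the founder-effect inflation of small inbred populations,
#' whose within- and near-neighbour sharing otherwise dwarfs every other
#' signal. Raw sums are then rescaled so the nine percentages total 100.
#'
#' @param J_row named numeric vector: the population's row of the normalized
#'   count matrix (must contain every reference population; a population
#'   that is itself a reference includes its own intra-population cell
#'   unless `include_self = FALSE`).
#' @param refs a [dhgr_reference_map()].
#' @param cap per-pair upper threshold applied before summation.
#' @param population_id optional identifier recorded in the result.
#' @param include_self logical; drop the population's own cell from its
#'   region's reference triple when `FALSE`.
#' @return an object of class `dhgr_profile`: list with `population_id`,
#'   `raw_sums` and `percentages` (both named by region).
#' @export
apportion <- function(J_row, refs, cap = 100, population_id = NULL,
                      include_self = TRUE) {
  stopifnot(inherits(refs, "dhgr_reference_map"))
  miss <- setdiff(unlist(refs), names(J_row))
  if (length(miss)) {
    stop_("J_row lacks reference population(s): ", paste(miss, collapse = ", "))
  }
  raw <- vapply(refs, function(r) {
    if (!include_self && !is.null(population_id)) r <- setdiff(r, population_id)
    sum(pmin(J_row[r], cap), na.rm = TRUE)
  }, numeric(1))
  total <- sum(raw)
  if (total <= 0) {
    stop_("all regional sums are zero for '", population_id %||% "?",
          "'; percentages undefined")
  }
  structure(list(population_id = population_id, raw_sums = raw,
                 percentages = 100 * raw / total),
            class = "dhgr_profile")
}

#' @export
print.dhgr_profile <- function(x, ...) {
  cat(sprintf("<dhgr_profile> %s\n", x$population_id %||% ""))
  print(round(x$percentages, 1))
  invisible(x)
}

#' Apportion every population of a J matrix
#'
#' @param J normalized count matrix (populations x populations).
#' @inheritParams apportion
#' @return data.table with `population_id` and one percentage column per
#'   region, rows summing to 100.
#' @export
apportion_all <- function(J, refs, cap = 100, include_self = TRUE) {
  rows <- lapply(rownames(J), function(p) {
    prof <- apportion(J[p, ], refs, cap, population_id = p,
                      include_self = include_self)
    c(list(population_id = p), as.list(prof$percentages))
  })
  rbindlist(rows)
}

#' Rank a population's sharing partners
#'
#' Sorts one row of the normalized count matrix in decreasing order of
#' shared-IBD value, ties broken lexicographically by population identifier.
#' The resulting table mirrors the per-population ranking tables: a
#' population's top partners are itself and its geographic neighbours.
#'
#' @param J_row named numeric vector of shared-IBD values (`NA` entries,
#'   e.g. an undefined self-cell, are ranked last).
#' @param names optional named character vector of display names.
#' @return data.table with columns `ibd` (the value), `population_id`, and
#'   `population_name`.
#' @export
rank_populations <- function(J_row, names = NULL) {
  if (!length(J_row)) stop_("empty row")
  ord <- order(-J_row, names(J_row), na.last = TRUE)
  ids <- names(J_row)[ord]
  data.table(
    ibd = unname(J_row[ord]),
    population_id = ids,
    population_name = if (is.null(names)) ids else unname(names[ids])
  )
}
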