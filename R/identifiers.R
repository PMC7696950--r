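#' Identifier conventions
#'
#' Population identifiers are two three-character triplets joined by an
#' underscore: the first triplet abbreviates the population name, the second
#' is its region code (e.g. `Rus_EUR` for Russians from Europe). Individual
#' identifiers append the sample name with a further underscore, e.g.
#' `Rus_EUR_HG00096`. Prehistoric samples use region `XXX`.
#'
#' @param x character vector of identifiers.
#' @return `is_population_id()` / `is_individual_id()` return logical vectors.
#' @examples
#' is_population_id(c("Rus_EUR", "bad", "LWK_AFR"))
#' parse_individual_id("BEB_SAS_HG03802")
#' @name identifiers
NULL

.pop_id_regex <- "^[A-Za-z0-9]{3}_[A-Z]{3}$"

#' @rdname identifiers
#' @export
is_population_id <- function(x) {
  grepl(.pop_id_regex, x) & sub("^.{4}", "", x) %in% REGION_CODES
}

#' @rdname identifiers
#' @export
is_individual_id <- function(x) {
  ok <- grepl("^[A-Za-z0-9]{3}_[A-Z]{3}_.+$", x)
  ok & substr(x, 5, 7) %in% REGION_CODES
}

#' @rdname identifiers
#' @export
#' @return `parse_individual_id()` returns a data.table with columns
#'   `individual_id`, `population_id`, `region_code`, `sample_name`.
parse_individual_id <- function(x) {
  bad <- x[!is_individual_id(x)]
  if (length(bad)) {
    stop_("malformed individual identifier(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  data.table(
    individual_id = x,
    population_id = substr(x, 1, 7),
    region_code   = substr(x, 5, 7),
    sample_name   = substring(x, 9)
  )
}

#' @rdname identifiers
#' @param population_id population identifier (`Xxx_RRR`).
#' @param sample_name sample name from the source dataset.
#' @export
make_individual_id <- function(population_id, sample_name) {
  bad <- population_id[!is_population_id(population_id)]
  if (length(bad)) {
    stop_("malformed population identifier(s): ", paste(unique(bad), collapse = ", "))
  }
  paste(population_id, sample_name, sep = "_")
}

#' Build a roster from individual identifiers
#'
#' A roster maps individuals to populations and regions; most aggregation
#' functions take one. When identifiers follow the triplet convention the
#' roster is derived by parsing; otherwise supply one explicitly as a
#' data.frame with columns `individual_id`, `population_id`, `region_code`.
#'
#' @param individual_ids character vector of individual identifiers.
#' @return data.table with columns `individual_id`, `population_id`,
#'   `region_code`.
#' @export
roster_from_ids <- function(individual_ids) {
  parse_individual_id(individual_ids)[, .(individual_id, population_id, region_code)]
}

as_roster <- function(roster) {
  roster <- as.data.table(roster)
  need <- c("individual_id", "population_id")
  if (!all(need %in% names(roster))) {
    stop_("roster must have columns 'individual_id' and 'population_id'")
  }
  if (!nrow(roster)) stop_("empty roster")
  if (anyDuplicated(roster$individual_id)) stop_("duplicate individuals in roster")
  if (!"region_code" %in% names(roster)) {
    roster[, region_code := substr(population_id, 5, 7)]
  }
  roster
}
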