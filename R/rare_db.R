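#' Cohort specifications
#'
#' Describes how a genotype cohort enters the very-rare-allele database.
#' The primary cohort defines the frequency threshold; secondary cohorts are
#' too small for reliable frequency estimation and instead use an absolute
#' minor-allele copy-count cap after rejection against the non-rare database;
#' ancient cohorts contribute only alleles matching the modern database.
#'
#' @param name cohort label.
#' @param kind one of `"primary"`, `"secondary"`, `"ancient"`.
#' @param max_minor_count for secondary cohorts, the maximum number of
#'   minor-allele copies at which an allele is still accepted (e.g. 4 for an
#'   SGDP/EGDP-sized cohort, 2 for a still smaller one).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(name, kind = c("primary", "secondary", "ancient"),
                        max_minor_count = NULL) {
  kind <- match.arg(kind)
  if (kind == "secondary") {
    if (is.null(max_minor_count) || max_minor_count < 1) {
      stop_("secondary cohort '", name, "' needs max_minor_count >= 1")
    }
  }
  structure(list(name = name, kind = kind,
                 max_minor_count = max_minor_count),
            class = "cohort_spec")
}

#' Build the core very-rare-allele database from the primary cohort
#'
#' Every observed alternate allele is classified by its frequency (alternate
#' allele copies over called allele copies) into either the very-rare
#' database, with its carrier list, or the complementary non-rare database.
#' The two sets partition the observed alternate alleles; the non-rare set is
#' the rejection filter later applied to secondary cohorts to suppress batch
#' effects between sequencing projects.
#'
#' @param genotypes a [genotype_table()] for the primary cohort.
#' @param rare_threshold frequency at or below which an allele is very rare
#'   (default 0.003, i.e. 0.3%).
#' @return an object of class `rare_allele_db` with components
#'   \describe{
#'     \item{entries}{data.table `chrom, pos, ref, alt, cohort, frequency,
#'       carriers` (list column of individual identifiers)}
#'     \item{non_rare}{data.table `chrom, pos, ref, alt` of rejected alleles}
#'     \item{threshold}{the frequency threshold used}
#'   }
#' @export
build_core_rare_db <- function(genotypes, rare_threshold = 0.003) {
  stopifnot(inherits(genotypes, "genotype_table"))
  if (rare_threshold <= 0 || rare_threshold >= 1) {
    stop_("rare_threshold must be in (0, 1)")
  }
  freq <- site_frequencies(genotypes)
  observed <- freq[copies > 0L]
  rare <- observed[frequency <= rare_threshold,
                   .(chrom, pos, ref, alt, cohort = genotypes$cohort,
                     frequency, carriers)]
  non_rare <- observed[frequency > rare_threshold, .(chrom, pos, ref, alt)]
  setkey(rare, chrom, pos, alt)
  setkey(non_rare, chrom, pos, alt)
  structure(list(entries = rare, non_rare = non_rare,
                 threshold = rare_threshold),
            class = "rare_allele_db")
}

#' @export
print.rare_allele_db <- function(x, ...) {
  cat(sprintf("<rare_allele_db> %d very rare alleles (%d carriers total), %d non-rare alleles, threshold %g\n",
              nrow(x$entries), sum(lengths(x$entries$carriers)),
              nrow(x$non_rare), x$threshold))
  invisible(x)
}

#' Add alleles from a secondary cohort
#'
#' An allele from a secondary cohort is accepted iff (a) its key
#' `(chrom, pos, alt)` is absent from the non-rare database and (b) its
#' minor-allele copy count within this cohort does not exceed
#' `spec$max_minor_count`. Accepted alleles carry the cohort's provenance;
#' when an accepted key is already present (from the primary cohort or an
#' earlier secondary cohort) the carrier lists are merged and the original
#' provenance and frequency are kept. Each cohort's count filter uses only
#' its own counts, so processing order does not change the resulting
#' database.
#'
#' @param db a `rare_allele_db`.
#' @param genotypes a [genotype_table()] for the secondary cohort.
#' @param spec a [cohort_spec()] with `kind = "secondary"`.
#' @return the updated `rare_allele_db`; the number of newly added keys is
#'   available as `attr(, "n_added")`.
#' @export
filter_secondary_cohort <- function(db, genotypes, spec) {
  stopifnot(inherits(db, "rare_allele_db"), inherits(spec, "cohort_spec"))
  if (spec$kind != "secondary") stop_("spec must describe a secondary cohort")
  if (!inherits(genotypes, "genotype_table") || !length(genotypes$individuals)) {
    stop_("secondary cohort '", spec$name, "' has zero individuals")
  }
  if (!nrow(genotypes$calls)) {
    stop_("secondary cohort '", spec$name, "' contributes no genotype calls")
  }
  freq <- site_frequencies(genotypes)[copies > 0L]
  ## reject anything matching the non-rare database, then apply the copy cap
  freq[, key_ := paste(chrom, pos, alt)]
  rejected <- freq$key_ %in% db$non_rare[, paste(chrom, pos, alt)]
  accepted <- freq[!rejected & copies <= spec$max_minor_count]
  accepted[, key_ := NULL]
  add <- accepted[, .(chrom, pos, ref, alt, cohort = spec$name,
                      frequency, carriers)]
  merged <- merge_db_entries(db$entries, add)
  out <- db
  out$entries <- merged$entries
  attr(out, "n_added") <- merged$n_new
  out
}

## union of two entry tables: new keys appended, existing keys keep their
## provenance/frequency and gain the union of carriers
merge_db_entries <- function(entries, add) {
  if (!nrow(add)) return(list(entries = entries, n_new = 0L))
  key <- function(dt) dt[, paste(chrom, pos, alt)]
  idx <- match(key(add), key(entries))
  new_rows <- add[is.na(idx)]
  dup <- which(!is.na(idx))
  if (length(dup)) {
    at <- idx[dup]
    entries$carriers[at] <- Map(function(a, b) sort(union(a, b)),
                                entries$carriers[at], add$carriers[dup])
  }
  entries <- rbind(entries, new_rows)
  setkey(entries, chrom, pos, alt)
  list(entries = entries, n_new = nrow(new_rows))
}

#' Match an ancient genome against the modern very-rare-allele database
#'
#' Ancient and archaic lineages separated from the modern gene pool long
#' enough ago that their own rare-allele spectrum cannot be estimated from a
#' handful of genomes. Instead, every allele an ancient individual carries
#' that matches a key already in the modern database is taken as that
#' individual's "very rare allele"; everything else is ignored. Ancient
#' samples never contribute to frequency estimation.
#'
#' @param genotypes a [genotype_table()] holding one ancient individual's
#'   alleles (the `individual_id` column names the sample).
#' @param db the finalized modern `rare_allele_db`.
#' @param individual_id identifier for the profile; defaults to the single
#'   individual present in `genotypes`.
#' @param population_id population identifier; region defaults to `XXX`.
#' @return an [individual_profile()] of the matched alleles.
#' @export
match_ancient_alleles <- function(genotypes, db, individual_id = NULL,
                                  population_id = NULL) {
  stopifnot(inherits(db, "rare_allele_db"))
  calls <- genotypes$calls
  individual_id <- individual_id %||% unique(calls$individual_id)
  if (length(individual_id) != 1) {
    stop_("genotypes must contain exactly one ancient individual")
  }
  population_id <- population_id %||%
    (if (is_individual_id(individual_id)) substr(individual_id, 1, 7) else "Anc_XXX")
  keys <- db$entries[, paste(chrom, pos, alt)]
  hits <- calls[paste(chrom, pos, alt) %in% keys, .(chrom, pos, alt)]
  individual_profile(individual_id, population_id, region_code = "XXX",
                     markers = hits, db_token = db_token(db))
}

#' Fan the database out into per-individual marker profiles
#'
#' Each individual's profile is the sorted track of very rare alleles it
#' carries — the marker track on which IBD segments are detected. The union
#' of all profiles' markers equals the database's carrier assignments.
#'
#' @param db a `rare_allele_db`.
#' @param roster data.frame mapping `individual_id` to `population_id` (and
#'   optionally `region_code`); every carrier in the database must appear.
#'   Individuals in the roster carrying no rare allele get empty profiles.
#' @return named list of [individual_profile()] objects.
#' @export
build_individual_profiles <- function(db, roster) {
  stopifnot(inherits(db, "rare_allele_db"))
  roster <- as_roster(roster)
  long <- db$entries[, .(individual_id = unlist(carriers)),
                     by = .(chrom, pos, alt)]
  missing <- setdiff(unique(long$individual_id), roster$individual_id)
  if (length(missing)) {
    stop_("carrier(s) missing from roster: ",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  token <- db_token(db)
  split_markers <- split(long[, .(chrom, pos, alt)], long$individual_id)
  profiles <- lapply(seq_len(nrow(roster)), function(i) {
    id <- roster$individual_id[i]
    individual_profile(id, roster$population_id[i], roster$region_code[i],
                       markers = split_markers[[id]] %||%
                         data.table(chrom = character(), pos = integer(),
                                    alt = character()),
                       db_token = token)
  })
  names(profiles) <- roster$individual_id
  profiles
}

## cheap fingerprint tying profiles to the database they came from
db_token <- function(db) {
  sprintf("%d:%d:%.0f", nrow(db$entries), nrow(db$non_rare),
          sum(as.numeric(db$entries$pos)) %% 2^31)
}
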