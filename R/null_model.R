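#' Simulate a random "ancient" genome from the modern rare-allele pool
#'
#' Draws `n_alleles` distinct entries uniformly without replacement from the
#' full modern very-rare-allele pool and packages them as a profile. Such a
#' random genome carries as many "matched" alleles as a real ancient sample
#' but no shared ancestry, so any IBD segments it shares with moderns
#' measure the identical-by-state noise floor of the five-marker rule.
#'
#' @param pool a `rare_allele_db` (the modern pool).
#' @param n_alleles number of alleles to draw (<= pool size).
#' @param seed RNG seed; runs are reproducible for a fixed seed.
#' @param label identifier for the simulated genome (e.g. `Rnd_XXX`).
#' @return an [individual_profile()] with region code `XXX`.
#' @export
simulate_random_ancient <- function(pool, n_alleles, seed = NULL,
                                    label = "Rnd_XXX") {
  stopifnot(inherits(pool, "rare_allele_db"))
  npool <- nrow(pool$entries)
  if (!npool) stop_("empty rare-allele pool")
  if (n_alleles > npool) {
    stop_("n_alleles (", n_alleles, ") exceeds pool size (", npool, ")")
  }
  if (!is.null(seed)) set.seed(seed)
  take <- if (n_alleles > 0) sort(sample.int(npool, n_alleles)) else integer()
  individual_profile(label, population_id = "Rnd_XXX", region_code = "XXX",
                     markers = pool$entries[take, .(chrom, pos, alt)],
                     db_token = db_token(pool))
}

#' Quantify chance-level IBD sharing of random genomes
#'
#' Scans every random-by-modern pair with [detect_shared_segments()] and
#' summarizes the chance-level segment yield. When a real ancient profile is
#' supplied its observed segment total is reported alongside, giving the
#' fraction of that signal attributable to chance.
#'
#' @param random_profiles list of profiles from [simulate_random_ancient()].
#' @param modern_profiles list of modern [individual_profile()] objects.
#' @param min_markers cluster threshold (default 5).
#' @param reference_profile optional real ancient [individual_profile()]
#'   scanned against the same moderns for comparison.
#' @inheritParams detect_shared_segments
#' @return list with `total_segments`, `per_random_genome` (named vector),
#'   `n_pairs_scanned`, and — when a reference is given —
#'   `reference_segments` and `chance_fraction`
#'   (= total chance segments per random genome / reference segments).
#' @export
chance_sharing_report <- function(random_profiles, modern_profiles,
                                  min_markers = 5L,
                                  reference_profile = NULL,
                                  interruption_policy = "strict") {
  count_vs_moderns <- function(p) {
    sum(vapply(modern_profiles, function(m) {
      nrow(detect_shared_segments(p, m, min_markers, interruption_policy))
    }, numeric(1)))
  }
  per_genome <- vapply(random_profiles, count_vs_moderns, numeric(1))
  names(per_genome) <- vapply(random_profiles, `[[`, character(1),
                              "individual_id")
  out <- list(total_segments = sum(per_genome),
              per_random_genome = per_genome,
              n_pairs_scanned = length(random_profiles) * length(modern_profiles))
  if (!is.null(reference_profile)) {
    ref <- count_vs_moderns(reference_profile)
    out$reference_segments <- ref
    out$chance_fraction <- if (ref > 0) mean(per_genome) / ref else NA_real_
  }
  out
}
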