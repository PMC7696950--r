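#' Configuration for a synthetic cohort
#'
#' Describes a desk-scale cohort with the statistical structure the IBD
#' analysis assumes: several populations whose individuals carry
#' individual-private very rare alleles scattered as a Poisson process at
#' about one marker per 10 kb, plus planted IBD segments of known span
#' shared by designated pairs. The default genome is 2 chromosomes of
#' 50 Mb and the default cohort 6 populations of 10 individuals — large
#' enough for population-level statistics, small enough to regenerate in
#' seconds.
#'
#' The `rare_threshold` recorded here is the frequency cutoff the cohort is
#' generated to satisfy. It scales with cohort size: at the default 60
#' diploids a planted allele carried by a pair has frequency
#' 2/120 ≈ 1.7%, so the desk-scale default is 5%; the 0.3% production
#' threshold is only attainable with hundreds of individuals.
#'
#' @param genome named numeric vector of chromosome lengths in bp.
#' @param populations data.frame with columns `population_id`,
#'   `region_code`, `n`; default: six 10-individual populations spanning
#'   six regions.
#' @param marker_density very rare alleles per bp (default `1e-4`, i.e. one
#'   marker per 10 kb).
#' @param rare_threshold frequency cutoff the generated cohort must satisfy.
#' @param planted_segments optional data.frame of segments to plant, with
#'   columns `chrom`, `start`, `length_bp` and either `id_a`/`id_b`
#'   (individual identifiers) or `pop_a`/`pop_b` (a random individual is
#'   drawn from each population).
#' @param seed RNG seed; generation is deterministic per seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(genome = c(chr1 = 50e6, chr2 = 50e6),
                             populations = NULL,
                             marker_density = 1e-4,
                             rare_threshold = 0.05,
                             planted_segments = NULL,
                             seed = 1L) {
  if (is.null(populations)) {
    populations <- data.table(
      population_id = c("Ala_AFE", "Bor_EUR", "Cyn_EAS",
                        "Dru_SAS", "Eya_OCE", "Fir_AMR"),
      region_code   = c("AFE", "EUR", "EAS", "SAS", "OCE", "AMR"),
      n = 10L
    )
  }
  populations <- as.data.table(populations)
  if (marker_density <= 0) stop_("marker_density must be positive")
  if (is.null(names(genome)) || any(genome <= 0)) {
    stop_("genome must be a named vector of positive chromosome lengths")
  }
  if (!is.null(planted_segments)) {
    planted_segments <- as.data.table(planted_segments)
    bad <- planted_segments[!chrom %in% names(genome) | start < 1 |
                              start + length_bp - 1 > genome[chrom]]
    if (nrow(bad)) stop_("planted segment(s) outside chromosome bounds")
  }
  structure(list(genome = genome, populations = populations,
                 marker_density = marker_density,
                 rare_threshold = rare_threshold,
                 planted_segments = planted_segments, seed = seed),
            class = "synthetic_config")
}

#' Generate a synthetic cohort with planted IBD segments
#'
#' Each individual receives private rare alleles as a Poisson process at
#' `marker_density` over every chromosome. Each planted segment receives
#' shared markers at the same density inside its span, assigned to both
#' pair members; the members' own private markers inside the span are
#' suppressed so the planted run is uninterrupted, as expected of a truly
#' identical-by-descent segment. All alleles are heterozygous singletons
#' apart from planted sharing, and the generator verifies that no allele's
#' frequency exceeds the configured `rare_threshold` — erroring with the
#' required minimum cohort size when the cohort is too small.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `synthetic_cohort`: list with
#'   \describe{
#'     \item{genotypes}{a [genotype_table()] of the whole cohort}
#'     \item{roster}{data.table `individual_id, population_id, region_code`}
#'     \item{truth}{list with `planted` (one row per planted segment:
#'       realized marker count and marker span) and `planted_markers`
#'       (every planted marker)}
#'     \item{config}{the configuration used}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  pops <- config$populations
  roster <- pops[, .(individual_id = make_individual_id(
                       population_id, sprintf("S%02d", seq_len(n))),
                     region_code = region_code),
                 by = population_id]
  setcolorder(roster, c("individual_id", "population_id", "region_code"))
  n_ind <- nrow(roster)

  ## individual-private markers: Poisson process per chromosome
  priv <- rbindlist(lapply(roster$individual_id, function(id) {
    rbindlist(lapply(names(config$genome), function(ch) {
      len <- config$genome[[ch]]
      k <- stats::rpois(1, len * config$marker_density)
      data.table(chrom = ch, pos = sort(sample.int(len, k)),
                 individual_id = id)
    }))
  }))
  priv[, ref := sample(.nucs, .N, replace = TRUE)]
  priv[, alt := random_alt(ref)]

  ## planted shared segments
  planted <- resolve_planted_pairs(config$planted_segments, roster)
  truth_rows <- list(); planted_calls <- list()
  if (!is.null(planted) && nrow(planted)) {
    for (s in seq_len(nrow(planted))) {
      seg <- planted[s]
      lo <- seg$start; hi <- seg$start + seg$length_bp - 1
      k <- stats::rpois(1, seg$length_bp * config$marker_density)
      pos <- sort(sample(lo:hi, min(k, seg$length_bp)))
      ref <- sample(.nucs, length(pos), replace = TRUE)
      alt <- random_alt(ref)
      ## suppress the members' private markers inside the span
      priv <- priv[!(individual_id %in% c(seg$id_a, seg$id_b) &
                       chrom == seg$chrom & pos >= lo & pos <= hi)]
      if (length(pos)) {
        planted_calls[[length(planted_calls) + 1L]] <- data.table(
          segment_id = s, chrom = seg$chrom, pos = pos, ref = ref, alt = alt,
          individual_id = rep(c(seg$id_a, seg$id_b), each = length(pos)))
      }
      truth_rows[[s]] <- data.table(
        segment_id = s, id_a = seg$id_a, id_b = seg$id_b, chrom = seg$chrom,
        start = seg$start, length_bp = seg$length_bp,
        n_markers = length(pos),
        marker_start = if (length(pos)) min(pos) else NA_real_,
        marker_end   = if (length(pos)) max(pos) else NA_real_)
    }
  }
  planted_calls <- rbindlist(planted_calls)
  calls <- rbind(priv[, .(chrom, pos, ref, alt, individual_id)],
                 if (nrow(planted_calls)) {
                   planted_calls[, .(chrom, pos, ref, alt, individual_id)]
                 })
  calls <- unique(calls, by = c("chrom", "pos", "alt", "individual_id"))
  calls[, dosage := 1L]

  check_frequency_guarantee(calls, n_ind, config$rare_threshold)

  genotypes <- genotype_table(calls, roster$individual_id, cohort = "synthetic")
  structure(list(genotypes = genotypes, roster = roster,
                 truth = list(planted = rbindlist(truth_rows),
                              planted_markers = planted_calls),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d individuals / %d populations, %d carried alleles, %d planted segment(s)\n",
              nrow(x$roster), length(unique(x$roster$population_id)),
              nrow(x$genotypes$calls),
              if (is.null(x$truth$planted)) 0L else nrow(x$truth$planted)))
  invisible(x)
}

## turn pop_a/pop_b rows into concrete individual pairs (seeded draw)
resolve_planted_pairs <- function(planted, roster) {
  if (is.null(planted) || !nrow(planted)) return(planted)
  planted <- copy(planted)
  if (!"id_a" %in% names(planted)) planted[, `:=`(id_a = NA_character_,
                                                  id_b = NA_character_)]
  for (s in seq_len(nrow(planted))) {
    if (is.na(planted$id_a[s])) {
      if (!all(c("pop_a", "pop_b") %in% names(planted))) {
        stop_("planted segments need id_a/id_b or pop_a/pop_b")
      }
      pick <- function(p) {
        members <- roster[population_id == p, individual_id]
        if (!length(members)) stop_("planted segment names unknown population ", p)
        members[sample.int(length(members), 1)]
      }
      planted$id_a[s] <- pick(planted$pop_a[s])
      planted$id_b[s] <- pick(planted$pop_b[s])
    }
    unknown <- setdiff(c(planted$id_a[s], planted$id_b[s]), roster$individual_id)
    if (length(unknown)) {
      stop_("planted segment names unknown individual(s): ",
            paste(unknown, collapse = ", "))
    }
    if (planted$id_a[s] == planted$id_b[s]) {
      stop_("planted segment pair must be two distinct individuals")
    }
  }
  planted
}

## vectorized draw of an alternate base differing from ref
random_alt <- function(ref) {
  others <- vapply(.nucs, function(r) setdiff(.nucs, r), character(3))
  others[cbind(sample.int(3, length(ref), replace = TRUE),
               match(ref, .nucs))]
}

check_frequency_guarantee <- function(calls, n_ind, threshold) {
  copies <- calls[, .(copies = sum(dosage)), by = .(chrom, pos, alt)]
  worst <- max(copies$copies)
  if (worst / (2 * n_ind) > threshold) {
    need <- ceiling(worst / (2 * threshold))
    stop_("cohort too small for the frequency guarantee: an allele reaches ",
          worst, " copies among ", n_ind, " diploids (frequency ",
          signif(worst / (2 * n_ind), 3), " > ", threshold,
          "); at least ", need, " individuals are required")
  }
  invisible(TRUE)
}

#' Sample shared-IBD segment lengths for a known age
#'
#' Draws lengths from an exponential distribution whose median equals the
#' calibrated clock's prediction `C/(2 g r)` Mb for a modern pair `g`
#' generations from their last common ancestor (rate
#' `lambda = log(2) * 2 g r / C` per Mb). Inverting the sample median with
#' [lca_time()] therefore recovers `g`, which is how the dating formulas
#' are validated end to end.
#'
#' @param g generations since the last common ancestor.
#' @param r recombination rate per Mb.
#' @param C calibration constant.
#' @param n number of lengths to draw.
#' @param seed optional RNG seed.
#' @return numeric vector of lengths in bp.
#' @export
sample_ibd_lengths <- function(g, r = 0.0118, C = 2, n, seed = NULL) {
  if (g <= 0 || r <= 0 || C <= 0 || n <= 0) stop_("all inputs must be positive")
  if (!is.null(seed)) set.seed(seed)
  median_mb <- C / (2 * g * r)
  stats::rexp(n, rate = log(2) / median_mb) * 1e6
}

#' Plant a synthetic ancient genome sharing runs with modern individuals
#'
#' Emulates an ancient sample whose alleles are a subset of the modern
#' rare-allele pool: a configured fraction of its alleles are copied as
#' runs of consecutive markers from designated modern donor individuals
#' (so detection yields ancient-by-modern segments), and the remainder are
#' ancient-private alleles at fresh positions that never match the modern
#' pool — mirroring how frequent alleles of a long-separated lineage were
#' diluted into the modern rare pool only along admixed ancestries.
#'
#' @param cohort a [generate_cohort()] result.
#' @param label identifier for the ancient sample (e.g. `Anc_XXX_A1`).
#' @param donors individual or population identifiers the shared runs are
#'   copied from.
#' @param n_alleles total alleles the ancient sample carries.
#' @param shared_fraction fraction of `n_alleles` shared with donors, in
#'   `[0, 1]`.
#' @param run_len markers per shared run (default 6).
#' @param seed optional RNG seed.
#' @return list with `genotypes` (a [genotype_table()] for the ancient
#'   sample) and `truth` (data.table of planted runs: donor, chrom, span,
#'   marker count).
#' @export
plant_ancient <- function(cohort, label, donors, n_alleles,
                          shared_fraction, run_len = 6L, seed = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop_("shared_fraction must be in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  roster <- cohort$roster
  donor_ids <- unique(c(
    intersect(donors, roster$individual_id),
    roster[population_id %in% donors, individual_id]))
  if (!length(donor_ids)) stop_("no donor individuals found for: ",
                                paste(donors, collapse = ", "))
  calls <- cohort$genotypes$calls
  n_shared <- round(n_alleles * shared_fraction)
  n_runs <- if (n_shared > 0) ceiling(n_shared / run_len) else 0L

  shared <- list(); truth <- list()
  for (k in seq_len(n_runs)) {
    donor <- donor_ids[sample.int(length(donor_ids), 1)]
    track <- calls[individual_id == donor][order(chrom, pos)]
    ch <- sample(unique(track$chrom), 1)
    track <- track[chrom == ch]
    if (nrow(track) < run_len) next
    i0 <- sample.int(nrow(track) - run_len + 1L, 1)
    run <- track[i0:(i0 + run_len - 1L)]
    shared[[length(shared) + 1L]] <- run[, .(chrom, pos, ref, alt)]
    truth[[length(truth) + 1L]] <- data.table(
      donor = donor, chrom = ch, start = min(run$pos), end = max(run$pos),
      n_markers = run_len)
  }
  shared <- unique(rbindlist(shared))
  truth <- rbindlist(truth)

  ## ancient-private alleles: fresh positions absent from the modern pool,
  ## kept out of the planted run spans so runs stay uninterrupted
  n_priv <- max(n_alleles - nrow(shared), 0L)
  priv <- draw_private_ancient(n_priv, cohort, truth)
  g_calls <- rbind(shared, priv)[, `:=`(individual_id = label, dosage = 1L)]
  list(genotypes = genotype_table(g_calls, individuals = label,
                                  cohort = "ancient"),
       truth = truth)
}

draw_private_ancient <- function(n_priv, cohort, runs) {
  out <- data.table(chrom = character(), pos = integer(),
                    ref = character(), alt = character())
  if (n_priv <= 0) return(out)
  genome <- cohort$config$genome
  modern_keys <- cohort$genotypes$sites[, paste(chrom, pos, alt)]
  while (nrow(out) < n_priv) {
    need <- n_priv - nrow(out)
    ch <- sample(names(genome), need, replace = TRUE,
                 prob = genome / sum(genome))
    cand <- data.table(chrom = ch,
                       pos = ceiling(stats::runif(need) * genome[ch]))
    cand[, ref := sample(.nucs, .N, replace = TRUE)]
    cand[, alt := random_alt(ref)]
    cand <- cand[!paste(chrom, pos, alt) %in% modern_keys]
    if (nrow(runs)) {
      for (r in seq_len(nrow(runs))) {
        cand <- cand[!(chrom == runs$chrom[r] & pos >= runs$start[r] &
                         pos <= runs$end[r])]
      }
    }
    out <- unique(rbind(out, cand), by = c("chrom", "pos"))
  }
  out[seq_len(n_priv)]
}
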