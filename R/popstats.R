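#' Raw population-by-population mean shared-segment counts
#'
#' For populations A and B the cell value is the total number of shared
#' segments between A-individuals and B-individuals divided by the number of
#' A-by-B individual pairs. Diagonal cells use the `n(n-1)/2` distinct pairs
#' within the population and are `NA` for populations of a single individual
#' (self-sharing is biologically meaningless).
#'
#' @param catalog a [segment_catalog()].
#' @param roster data.frame mapping `individual_id` to `population_id`;
#'   every individual appearing in the catalog must be present.
#' @return symmetric numeric matrix `I` with population identifiers as
#'   dimnames.
#' @export
pair_count_matrix <- function(catalog, roster) {
  prep <- pop_segments(catalog, roster)
  pops <- prep$pops
  sizes <- prep$sizes
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  if (nrow(prep$segs)) {
    counts <- prep$segs[, .N, by = .(pop_a, pop_b)]
    for (r in seq_len(nrow(counts))) {
      m[counts$pop_a[r], counts$pop_b[r]] <-
        m[counts$pop_a[r], counts$pop_b[r]] + counts$N[r]
    }
    m <- m + t(m) - diag(diag(m), nrow = nrow(m))
  }
  denom <- outer(sizes, sizes)
  diag(denom) <- sizes * (sizes - 1) / 2
  m <- m / denom
  diag(m)[sizes < 2] <- NA_real_
  m
}

## segments annotated with the population of each endpoint (pop_a <= pop_b)
pop_segments <- function(catalog, roster) {
  stopifnot(inherits(catalog, "segment_catalog"))
  roster <- as_roster(roster)
  segs <- copy(catalog$segments)
  ids <- unique(c(segs$id_a, segs$id_b))
  missing <- setdiff(ids, roster$individual_id)
  if (length(missing)) {
    stop_("catalog individual(s) missing from roster: ",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  lookup <- stats::setNames(roster$population_id, roster$individual_id)
  if (nrow(segs)) {
    pa <- lookup[segs$id_a]; pb <- lookup[segs$id_b]
    segs[, `:=`(pop_a = pmin(pa, pb), pop_b = pmax(pa, pb))]
  } else {
    segs[, `:=`(pop_a = character(), pop_b = character())]
  }
  pops <- sort(unique(roster$population_id))
  sizes <- vapply(pops, function(p) sum(roster$population_id == p), numeric(1))
  list(segs = segs, pops = pops, sizes = sizes, roster = roster)
}

#' Per-population normalization coefficients
#'
#' Sequencing projects differ in how many very rare alleles they detect per
#' genome, which inflates or deflates shared-segment counts for whole
#' cohorts. The coefficient `N_A` for population A is the mean marker count
#' per individual in A divided by the unweighted mean of those
#' per-population means over all populations, so the coefficients average
#' to 1.
#'
#' @param profiles list of [individual_profile()] objects.
#' @return an object of class `normalization_table`: named numeric vector of
#'   coefficients, one per population.
#' @export
normalization_coefficients <- function(profiles) {
  roster <- profiles_roster(profiles)
  counts <- vapply(profiles, n_markers, numeric(1))
  per_pop <- tapply(counts, roster$population_id, mean)
  if (any(is.na(per_pop))) stop_("population with zero individuals")
  N <- as.numeric(per_pop) / mean(per_pop)
  names(N) <- names(per_pop)
  structure(N, class = "normalization_table")
}

#' @export
print.normalization_table <- function(x, ...) {
  cat("<normalization_table>\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Normalize a raw count matrix
#'
#' Applies `J_AB = I_AB / sqrt(N_A * N_B)`: the geometric mean of the two
#' populations' normalization coefficients. The square root is what frees
#' shared-IBD counts from per-dataset rare-allele abundance — dividing by
#' the plain product over-normalizes.
#'
#' @param I raw mean count matrix from [pair_count_matrix()].
#' @param N a [normalization_coefficients()] table covering every population
#'   in `I`.
#' @return the normalized matrix `J`; `NA` cells propagate.
#' @export
normalize_counts <- function(I, N) {
  pops <- rownames(I)
  miss <- setdiff(pops, names(N))
  if (length(miss)) {
    stop_("missing normalization coefficient(s) for: ",
          paste(miss, collapse = ", "))
  }
  v <- unclass(N)[pops]
  I / sqrt(outer(v, v))
}

#' Mean and median shared-segment length matrices
#'
#' Pools all segment lengths per population pair. The mean is reported
#' whenever at least one segment exists; the median only when the pooled
#' count reaches `min_for_median` (default 5) — below that a median is too
#' unstable to print, and the cell is `NA`.
#'
#' @inheritParams pair_count_matrix
#' @param min_for_median minimum pooled segment count for a median.
#' @return list with symmetric matrices `mean_len` and `median_len` (bp) and
#'   `n_segments` (pooled counts).
#' @export
length_stats <- function(catalog, roster, min_for_median = 5L) {
  prep <- pop_segments(catalog, roster)
  pops <- prep$pops
  empty <- matrix(NA_real_, length(pops), length(pops),
                  dimnames = list(pops, pops))
  nseg <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  mean_len <- median_len <- empty
  if (nrow(prep$segs)) {
    st <- prep$segs[, .(n = .N, m = mean(length_bp),
                        md = stats::median(length_bp)),
                    by = .(pop_a, pop_b)]
    for (r in seq_len(nrow(st))) {
      i <- st$pop_a[r]; j <- st$pop_b[r]
      nseg[i, j] <- nseg[j, i] <- st$n[r]
      mean_len[i, j] <- mean_len[j, i] <- st$m[r]
      if (st$n[r] >= min_for_median) {
        median_len[i, j] <- median_len[j, i] <- st$md[r]
      }
    }
  }
  list(mean_len = mean_len, median_len = median_len, n_segments = nseg)
}

#' Pool segment lengths to region-by-region medians
#'
#' Each region cell pools the raw segment lengths over all population pairs
#' with one population in each region and reports their median in kb;
#' `NA` below `min_for_median` pooled segments. Pooling raw lengths (rather
#' than taking a median of per-pair medians) is the only reading consistent
#' with the 5-fragment rule. The Oceania region can be restricted to a
#' subset of its populations (`oce_subset`): island Southeast Asian
#' populations with recent mainland admixture otherwise dominate the OCE
#' cells with long recent segments, so the deep-ancestry signal is carried
#' by the Papua and Australia populations only.
#'
#' @inheritParams length_stats
#' @param region_map optional named character vector `population_id ->`
#'   region/group code; defaults to each individual's roster `region_code`.
#'   Ancient groups (e.g. `NEA`, `ANC`) are assigned here.
#' @param oce_subset population identifiers representing OCE; other OCE
#'   populations are dropped from OCE cells (default: no restriction).
#' @return symmetric matrix of median lengths in kb, regions as dimnames.
#' @export
aggregate_regions <- function(catalog, roster, region_map = NULL,
                              oce_subset = NULL, min_for_median = 5L) {
  prep <- pop_segments(catalog, roster)
  roster <- prep$roster
  if (is.null(region_map)) {
    region_map <- stats::setNames(roster$region_code, roster$population_id)
    region_map <- region_map[!duplicated(names(region_map))]
  }
  miss <- setdiff(prep$pops, names(region_map))
  if (length(miss)) {
    stop_("population(s) without region assignment: ",
          paste(miss, collapse = ", "))
  }
  segs <- prep$segs
  regions <- sort(unique(region_map[prep$pops]))
  out <- matrix(NA_real_, length(regions), length(regions),
                dimnames = list(regions, regions))
  if (nrow(segs)) {
    segs[, `:=`(reg_a = region_map[pop_a], reg_b = region_map[pop_b])]
    keep_oce <- function(reg, pop) reg != "OCE" | is.null(oce_subset) | pop %in% oce_subset
    for (i in seq_along(regions)) {
      for (j in i:length(regions)) {
        R <- regions[i]; S <- regions[j]
        sel <- segs[(reg_a == R & reg_b == S) | (reg_a == S & reg_b == R)]
        if (!is.null(oce_subset)) {
          sel <- sel[keep_oce(reg_a, pop_a) & keep_oce(reg_b, pop_b)]
        }
        if (nrow(sel) >= min_for_median) {
          out[R, S] <- out[S, R] <- stats::median(sel$length_bp) / 1000
        }
      }
    }
  }
  out
}

#' All population-level matrices in one call
#'
#' Convenience wrapper producing the raw count matrix `I`, normalization
#' coefficients `N`, normalized matrix `J`, and mean/median length matrices
#' from one catalog.
#'
#' @inheritParams length_stats
#' @param profiles the profile list the catalog was scanned from (for
#'   normalization coefficients).
#' @return list with elements `I`, `J`, `N`, `mean_len`, `median_len`,
#'   `n_segments`.
#' @export
population_matrices <- function(catalog, profiles, min_for_median = 5L) {
  roster <- profiles_roster(profiles)
  I <- pair_count_matrix(catalog, roster)
  N <- normalization_coefficients(profiles)
  J <- normalize_counts(I, N)
  len <- length_stats(catalog, roster, min_for_median)
  c(list(I = I, J = J, N = N), len)
}
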