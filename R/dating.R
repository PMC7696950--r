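#' Dating parameters
#'
#' The recombination clock converting median shared-IBD length into the age
#' of the last common ancestor (LCA). The theoretical relation for two
#' modern genomes is `L = C/(2 g r)`: `L` the median length (Mb), `g`
#' generations since the LCA, `r` the genome-average recombination rate per
#' Mb per meiosis, and `C` a calibration constant absorbing recombination
#' hotspot reuse (repeated crossovers at the same hotspot do not shorten
#' segments, so uncalibrated theory over-ages every estimate). For an
#' ancient-vs-modern comparison the factor 2 is absent (`L = C/(g r)`): the
#' ancient genome's segment is compared directly rather than through the
#' intersection of two independently inherited segments, which on average
#' halves the observable length between moderns.
#'
#' @param C calibration constant (default 2, fitted from two ~8000-year-old
#'   European genomes; see [calibrate_constant()]).
#' @param r recombination rate per Mb (default 0.0118).
#' @param generation_years years per generation (default 25).
#' @return an object of class `dating_params`.
#' @export
dating_params <- function(C = 2, r = 0.0118, generation_years = 25) {
  if (C <= 0 || r <= 0 || generation_years <= 0) {
    stop_("all dating parameters must be positive")
  }
  structure(list(C = C, r = r, generation_years = generation_years),
            class = "dating_params")
}

#' Date a last common ancestor from a median IBD length
#'
#' Inverts the calibrated recombination clock: `g = C/(2 L r)` for a pair of
#' modern genomes, `g = C/(L r)` for an ancient-vs-modern pair (`L` in Mb).
#' Time is `g` times the generation interval, reported in thousands of
#' years rounded to one decimal.
#'
#' @param median_len median shared-IBD length in kb (> 0).
#' @param params a [dating_params()].
#' @param pair_class `"modern_modern"` or `"ancient_modern"`.
#' @return list with `generations` (unrounded) and `time_ky` (rounded to
#'   0.1 ky).
#' @examples
#' lca_time(157)$time_ky                              # 13.5
#' lca_time(585, pair_class = "ancient_modern")$time_ky  # 7.2
#' @export
lca_time <- function(median_len, params = dating_params(),
                     pair_class = c("modern_modern", "ancient_modern")) {
  pair_class <- match.arg(pair_class)
  stopifnot(inherits(params, "dating_params"))
  if (is.na(median_len)) {
    return(list(generations = NA_real_, time_ky = NA_real_))
  }
  if (median_len <= 0) stop_("median_len must be positive")
  L_mb <- median_len / 1000
  denom <- if (pair_class == "modern_modern") 2 * L_mb * params$r else L_mb * params$r
  g <- params$C / denom
  list(generations = g,
       time_ky = round(g * params$generation_years / 1000, 1))
}

#' Calibrate the clock constant from a dated comparison
#'
#' Solves the pair-class formula for `C` given a known median length and a
#' known number of generations — e.g. a 585 kb median between two
#' ~8000-year-old (320-generation) European ancients and modern Europeans
#' gives `C = 320 * 0.0118 * 0.585 = 2.209 ~ 2`.
#'
#' @param L median IBD length in kb.
#' @param g generations separating the compared genomes from their LCA.
#' @param r recombination rate per Mb.
#' @inheritParams lca_time
#' @return the calibration constant `C`.
#' @export
calibrate_constant <- function(L, g, r = 0.0118,
                               pair_class = c("modern_modern", "ancient_modern")) {
  pair_class <- match.arg(pair_class)
  if (L <= 0 || g <= 0 || r <= 0) stop_("all inputs must be positive")
  L_mb <- L / 1000
  if (pair_class == "modern_modern") 2 * g * r * L_mb else g * r * L_mb
}

#' Region-by-region LCA dating table
#'
#' Converts a region median-length matrix (kb) into LCA times (thousands of
#' years). Cells where either region is an ancient group use the
#' ancient-modern formula; ancient-ancient cells and `NA` medians stay `NA`.
#'
#' @param region_medians symmetric matrix of median lengths in kb (as from
#'   [aggregate_regions()]).
#' @param ancient_groups region codes treated as ancient (default `NEA`,
#'   `ANC`).
#' @param params a [dating_params()].
#' @return symmetric matrix of times in ky, rounded to one decimal.
#' @export
dating_table <- function(region_medians, ancient_groups = c("NEA", "ANC"),
                         params = dating_params()) {
  regs <- rownames(region_medians)
  out <- region_medians
  out[] <- NA_real_
  for (i in seq_along(regs)) {
    for (j in i:length(regs)) {
      anc_i <- regs[i] %in% ancient_groups
      anc_j <- regs[j] %in% ancient_groups
      if (anc_i && anc_j) next            # too few ancient genomes to pool
      L <- region_medians[i, j]
      if (is.na(L)) next
      cls <- if (anc_i || anc_j) "ancient_modern" else "modern_modern"
      out[i, j] <- out[j, i] <- lca_time(L, params, cls)$time_ky
    }
  }
  out
}
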