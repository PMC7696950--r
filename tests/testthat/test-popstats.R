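mk_catalog <- function(pairs, lengths = 50000) {
  segs <- data.table::data.table(
    id_a = pmin(pairs[, 1], pairs[, 2]), id_b = pmax(pairs[, 1], pairs[, 2]),
    chrom = "chr1", start = 1000, end = 1000 + rep_len(lengths, nrow(pairs)) - 1,
    n_markers = 5L, length_bp = rep_len(lengths, nrow(pairs)))
  ids <- unique(c(pairs))
  segment_catalog(segs, n_individuals = length(ids),
                  n_pairs_scanned = n_pairings(length(ids)))
}

test_that("raw counts average over cross-population pairs; singleton diagonals are N/A", {
  # populations of 2 and 3 with 12 cross segments: I = 12/6 = 2.0
  A <- c("Aaa_EUR_I1", "Aaa_EUR_I2")
  B <- c("Bbb_EAS_I1", "Bbb_EAS_I2", "Bbb_EAS_I3")
  C <- "Ccc_SAS_I1"
  cross <- cbind(rep(A, each = 6), rep(B, 4))  # 12 A-B segments
  catalog <- mk_catalog(cross)
  roster <- roster_from_ids(c(A, B, C))
  I <- pair_count_matrix(catalog, roster)

  expect_equal(I["Aaa_EUR", "Bbb_EAS"], 2.0)
  expect_equal(I, t(I))
  expect_true(is.na(I["Ccc_SAS", "Ccc_SAS"]))     # singleton population
  expect_equal(I["Aaa_EUR", "Aaa_EUR"], 0)        # no within segments
  expect_equal(I["Aaa_EUR", "Ccc_SAS"], 0)

  # zero-segment catalog keeps the N/A diagonal and zeros elsewhere
  empty <- segment_catalog(catalog$segments[0], 6, 15)
  I0 <- pair_count_matrix(empty, roster)
  expect_true(all(I0 == 0, na.rm = TRUE))
  expect_true(is.na(I0["Ccc_SAS", "Ccc_SAS"]))
})

test_that("within-population counts use distinct pairs", {
  A <- c("Aaa_EUR_I1", "Aaa_EUR_I2", "Aaa_EUR_I3")
  within <- cbind(c(A[1], A[1], A[2]), c(A[2], A[3], A[3]))  # all 3 pairs
  catalog <- mk_catalog(within)
  I <- pair_count_matrix(catalog, roster_from_ids(A))
  expect_equal(I["Aaa_EUR", "Aaa_EUR"], 1.0)       # 3 segments / 3 pairs
})

test_that("normalization coefficients average to 1 and follow marker abundance", {
  profs <- c(
    lapply(1:2, function(i) mk_profile(sprintf("Aaa_EUR_I%d", i), seq_len(100))),
    lapply(1:2, function(i) mk_profile(sprintf("Bbb_EAS_I%d", i), seq_len(300),
                                       pop = "Bbb_EAS", region = "EAS")))
  N <- normalization_coefficients(profs)
  expect_equal(unclass(N)[["Aaa_EUR"]], 0.5)       # 100 / 200
  expect_equal(unclass(N)[["Bbb_EAS"]], 1.5)       # 300 / 200
  expect_equal(mean(unclass(N)), 1, tolerance = 1e-9)

  # equal abundance: all coefficients 1, and J = I exactly
  eq_profs <- lapply(c("Aaa_EUR_I1", "Bbb_EAS_I1"), function(id) {
    mk_profile(id, seq_len(50), pop = substr(id, 1, 7))
  })
  N1 <- normalization_coefficients(eq_profs)
  expect_true(all(unclass(N1) == 1))
  I <- matrix(c(3, 1, 1, 2), 2, 2,
              dimnames = list(c("Aaa_EUR", "Bbb_EAS"), c("Aaa_EUR", "Bbb_EAS")))
  expect_equal(normalize_counts(I, N1), I)
})

test_that("normalization applies J = I / sqrt(NA * NB) and propagates N/A", {
  pops <- c("Aaa_EUR", "Bbb_EAS")
  I <- matrix(c(NA, 10, 10, 0), 2, 2, dimnames = list(pops, pops))
  N <- structure(c(Aaa_EUR = 4, Bbb_EAS = 1), class = "normalization_table")
  # mean(N) != 1 here on purpose: the formula itself is what is checked
  J <- normalize_counts(I, N)
  expect_equal(J["Aaa_EUR", "Bbb_EAS"], 10 / sqrt(4))
  expect_equal(J["Bbb_EAS", "Bbb_EAS"], 0)
  expect_true(is.na(J["Aaa_EUR", "Aaa_EUR"]))
  expect_error(normalize_counts(I, N[-1, drop = FALSE]), "missing normalization")
})

test_that("median is reported only at five or more pooled segments", {
  A <- "Aaa_EUR_I1"; B <- "Bbb_EAS_I1"
  roster <- roster_from_ids(c(A, B))
  # 4 segments: mean defined, median N/A
  cat4 <- mk_catalog(cbind(rep(A, 4), rep(B, 4)), lengths = c(10, 20, 30, 40) * 1000)
  st4 <- length_stats(cat4, roster)
  expect_equal(st4$mean_len["Aaa_EUR", "Bbb_EAS"], 25000)
  expect_true(is.na(st4$median_len["Aaa_EUR", "Bbb_EAS"]))

  # 5 segments with an outlier: median robust at 30 kb, mean dragged to 220 kb
  cat5 <- mk_catalog(cbind(rep(A, 5), rep(B, 5)),
                     lengths = c(10, 20, 30, 40, 1000) * 1000)
  st5 <- length_stats(cat5, roster)
  expect_equal(st5$median_len["Aaa_EUR", "Bbb_EAS"], 30000)
  expect_equal(st5$mean_len["Aaa_EUR", "Bbb_EAS"], 220000)

  # zero segments: both undefined
  st0 <- length_stats(segment_catalog(cat4$segments[0], 2, 1), roster)
  expect_true(is.na(st0$mean_len["Aaa_EUR", "Bbb_EAS"]))
  expect_true(is.na(st0$median_len["Aaa_EUR", "Bbb_EAS"]))
})

test_that("region medians pool raw lengths and honour the OCE restriction", {
  ids <- c("Aaa_EUR_I1", "Bbb_EUR_I1", "Ccc_OCE_I1", "Ddd_OCE_I1")
  roster <- roster_from_ids(ids)
  # EUR-OCE pairs: Ccc (papua-like) shares short, Ddd (island-asian-like) long
  pairs <- rbind(
    cbind(rep("Aaa_EUR_I1", 5), rep("Ccc_OCE_I1", 5)),
    cbind(rep("Bbb_EUR_I1", 5), rep("Ddd_OCE_I1", 5)))
  catalog <- mk_catalog(pairs, lengths = c(rep(40000, 5), rep(400000, 5)))

  pooled <- aggregate_regions(catalog, roster)
  expect_equal(pooled["EUR", "OCE"],
               stats::median(c(rep(40, 5), rep(400, 5))))
  restricted <- aggregate_regions(catalog, roster, oce_subset = "Ccc_OCE")
  expect_equal(restricted["EUR", "OCE"], 40)

  # single-population regions reduce to the population-level median
  st <- length_stats(catalog, roster)
  expect_equal(restricted["EUR", "OCE"] * 1000,
               st$median_len["Aaa_EUR", "Ccc_OCE"])
  # below five pooled segments the cell is N/A
  thin <- mk_catalog(pairs[1:4, ], lengths = 40000)
  expect_true(is.na(aggregate_regions(thin, roster)["EUR", "OCE"]))
})

test_that("normalization damps cross-cohort differences in marker abundance", {
  planted <- data.frame(pop_a = "Bbb_EUR", pop_b = "Ccc_EAS", chrom = "chr1",
                        start = c(1e6, 2e6, 3e6), length_bp = 3e5)
  cfg <- small_cohort_config(seed = 5, planted = planted)
  co <- generate_cohort(cfg)
  db <- build_core_rare_db(co$genotypes, cfg$rare_threshold)
  profs <- build_individual_profiles(db, co$roster)

  # emulate a lower-coverage sequencing run for EUR and EAS by thinning
  # their detected markers to half; the lenient policy keeps planted
  # segments detectable when thinning de-pairs some shared markers
  set.seed(6)
  thin <- lapply(profs, function(p) {
    if (p$population_id == "Aaa_AFE") return(p)
    keep <- stats::runif(nrow(p$markers)) < 0.5
    individual_profile(p$individual_id, p$population_id, p$region_code,
                       p$markers[keep], db_token = p$db_token)
  })
  J_of <- function(pp) {
    catg <- all_pairs_scan(pp, 2L, "lenient")
    population_matrices(catg, pp)$J["Bbb_EUR", "Ccc_EAS"]
  }
  J_full <- J_of(profs); J_thin <- J_of(thin)
  expect_gt(J_full, 0); expect_gt(J_thin, 0)
  # halving both cohorts' abundance must not move J by more than ~2x,
  # whereas the raw count ratio is uncorrected
  expect_lt(abs(log2(J_thin / J_full)), 1)
})
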