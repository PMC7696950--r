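test_that("generation is deterministic per seed and config", {
  cfg <- small_cohort_config(seed = 12)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_equal(c1$genotypes$calls, c2$genotypes$calls)
  c3 <- generate_cohort(small_cohort_config(seed = 13))
  expect_false(isTRUE(all.equal(c1$genotypes$calls, c3$genotypes$calls)))

  # byte-identical VCF for the same seed
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_vcf(c1, f1); write_vcf(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("marker density and the frequency guarantee hold", {
  cfg <- small_cohort_config(seed = 2)
  co <- generate_cohort(cfg)
  genome_len <- sum(cfg$genome)
  per_ind <- co$genotypes$calls[, .N, by = individual_id]$N
  expect_equal(mean(per_ind), genome_len * cfg$marker_density,
               tolerance = 0.05)

  # no allele exceeds the configured threshold
  copies <- co$genotypes$calls[, .(copies = sum(dosage)),
                               by = .(chrom, pos, alt)]
  n_ind <- nrow(co$roster)
  expect_lte(max(copies$copies) / (2 * n_ind), cfg$rare_threshold)

  # too-small cohort for a pair-shared allele at a strict threshold errors
  tight <- synthetic_config(
    genome = c(chr1 = 1e6),
    populations = data.frame(population_id = c("Aaa_EUR", "Bbb_EAS"),
                             region_code = c("EUR", "EAS"), n = 2L),
    rare_threshold = 0.003,
    planted_segments = data.frame(pop_a = "Aaa_EUR", pop_b = "Bbb_EAS",
                                  chrom = "chr1", start = 1e5,
                                  length_bp = 2e5),
    seed = 1)
  expect_error(generate_cohort(tight), "at least [0-9]+ individuals")
})

test_that("planted segments appear in both members and are detectable", {
  planted <- data.frame(pop_a = "Aaa_AFE", pop_b = "Bbb_EUR", chrom = "chr1",
                        start = 2e6, length_bp = 2e5)
  cfg <- small_cohort_config(seed = 8, planted = planted)
  co <- generate_cohort(cfg)
  truth <- co$truth$planted
  expect_equal(nrow(truth), 1L)
  pm <- co$truth$planted_markers
  for (id in c(truth$id_a, truth$id_b)) {
    carried <- co$genotypes$calls[individual_id == id]
    expect_true(all(paste(pm$chrom, pm$pos, pm$alt) %in%
                      carried[, paste(chrom, pos, alt)]))
  }
  # members have no private markers inside the planted span
  for (id in c(truth$id_a, truth$id_b)) {
    inside <- co$genotypes$calls[individual_id == id & chrom == truth$chrom &
                                   pos >= truth$start &
                                   pos <= truth$start + truth$length_bp - 1]
    expect_equal(nrow(inside), truth$n_markers)
  }
  # the planted segment is recovered with its exact marker span
  db <- build_core_rare_db(co$genotypes, cfg$rare_threshold)
  profs <- build_individual_profiles(db, co$roster)
  segs <- detect_shared_segments(profs[[truth$id_a]], profs[[truth$id_b]], 5)
  hit <- segs[start == truth$marker_start & end == truth$marker_end]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$n_markers, truth$n_markers)
})

test_that("planted segments are validated against the genome and roster", {
  expect_error(small_cohort_config(
    planted = data.frame(pop_a = "Aaa_AFE", pop_b = "Bbb_EUR", chrom = "chr1",
                         start = 4.95e6, length_bp = 2e5)),
    "outside chromosome bounds")
  cfg <- small_cohort_config(
    planted = data.frame(id_a = "Zzz_SIB_S01", id_b = "Aaa_AFE_S01",
                         chrom = "chr1", start = 1e6, length_bp = 1e5))
  expect_error(generate_cohort(cfg), "unknown individual")
})

test_that("sampled IBD lengths follow the calibrated exponential model", {
  # median of Exp(rate) is log(2)/rate: inversion identity
  g <- 320; r <- 0.0118; C <- 2
  target_bp <- C / (2 * g * r) * 1e6
  x <- sample_ibd_lengths(g, r, C, n = 1e5, seed = 33)
  expect_equal(stats::median(x), target_bp, tolerance = 0.01)

  # inverting the sample median through the clock recovers g
  g_hat <- lca_time(stats::median(x) / 1000)$generations
  expect_equal(g_hat, g, tolerance = 0.02)
  expect_error(sample_ibd_lengths(-1, n = 10), "positive")
})

test_that("planted ancient genomes share runs with donors and keep private alleles private", {
  cfg <- small_cohort_config(seed = 15)
  co <- generate_cohort(cfg)
  anc <- plant_ancient(co, "Anc_XXX_A1", donors = "Ccc_EAS",
                       n_alleles = 400, shared_fraction = 0.15,
                       run_len = 6, seed = 5)
  expect_equal(nrow(anc$genotypes$calls), 400L)
  expect_true(all(anc$truth$n_markers == 6L))

  db <- build_core_rare_db(co$genotypes, cfg$rare_threshold)
  prof <- match_ancient_alleles(anc$genotypes, db, "Anc_XXX_A1", "Anc_XXX")
  # matched alleles are exactly the copied runs: ancient-private never match
  expect_equal(n_markers(prof), sum(anc$truth$n_markers))

  # each planted run is recovered as an ancient-modern segment
  profs <- build_individual_profiles(db, co$roster)
  for (k in seq_len(nrow(anc$truth))) {
    donor_prof <- profs[[anc$truth$donor[k]]]
    segs <- detect_shared_segments(prof, donor_prof, 5)
    expect_true(any(segs$start <= anc$truth$start[k] &
                      segs$end >= anc$truth$end[k]))
  }

  # zero shared fraction: nothing matches, nothing detected
  anc0 <- plant_ancient(co, "Anc_XXX_A0", donors = "Ccc_EAS",
                        n_alleles = 100, shared_fraction = 0, seed = 6)
  expect_equal(n_markers(match_ancient_alleles(anc0$genotypes, db,
                                               "Anc_XXX_A0", "Anc_XXX")), 0L)
  expect_error(plant_ancient(co, "x", "Ccc_EAS", 10, shared_fraction = 1.2),
               "0, 1")
})

test_that("a cohort without planted segments shares only at chance level", {
  hits <- vapply(1:5, function(s) {
    cfg <- small_cohort_config(seed = 300 + s)
    co <- generate_cohort(cfg)
    db <- build_core_rare_db(co$genotypes, cfg$rare_threshold)
    profs <- build_individual_profiles(db, co$roster)
    nrow(all_pairs_scan(profs, 5)$segments)
  }, numeric(1))
  expect_lte(mean(hits), 0.2)
})
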