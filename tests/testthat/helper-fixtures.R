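# fixtures built in code: quick profiles, genotype tables and small cohorts

mk_profile <- function(id, pos, alt = "A", chrom = "chr1",
                       pop = "Aaa_EUR", region = "EUR", token = NULL) {
  individual_profile(id, pop, region,
                     data.frame(chrom = chrom, pos = pos,
                                alt = rep_len(alt, length(pos))),
                     db_token = token)
}

# random profile pair sharing a common marker subset, for fuzzing
random_pair <- function(span = 2000, n_shared_max = 40) {
  mk <- function() {
    n <- sample(5:n_shared_max, 1)
    data.frame(chrom = "c1", pos = sort(sample.int(span, n)),
               alt = sample(c("A", "C", "G", "T"), n, replace = TRUE))
  }
  shared <- mk()
  a <- individual_profile("A", "Aaa_EUR", "EUR",
                          unique(rbind(shared[sample(nrow(shared),
                                                     sample(nrow(shared), 1)), ],
                                       mk())))
  b <- individual_profile("B", "Bbb_EUR", "EUR", unique(rbind(shared, mk())))
  list(a = a, b = b)
}

# genotype table from a compact spec: list of (individual -> list of sites)
mk_genotypes <- function(carriers, individuals, cohort = "test",
                         n_sites_pos = NULL) {
  calls <- data.table::rbindlist(lapply(names(carriers), function(id) {
    x <- carriers[[id]]
    data.table::data.table(chrom = x$chrom %||% "chr1", pos = x$pos,
                           ref = x$ref %||% "A", alt = x$alt %||% "C",
                           individual_id = id, dosage = x$dosage %||% 1L)
  }))
  genotype_table(calls, individuals, cohort)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small fast synthetic cohort shared across tests
small_cohort_config <- function(seed = 1, planted = NULL) {
  synthetic_config(
    genome = c(chr1 = 5e6, chr2 = 5e6),
    populations = data.frame(
      population_id = c("Aaa_AFE", "Bbb_EUR", "Ccc_EAS"),
      region_code = c("AFE", "EUR", "EAS"), n = 4L),
    rare_threshold = 0.25,
    planted_segments = planted,
    seed = seed)
}
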