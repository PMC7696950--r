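test_that("alternate alleles partition into rare and non-rare at the frequency boundary", {
  # 2504 diploids: 16/5008 = 0.3195% is above 0.3%, 15/5008 = 0.2995% is below
  inds <- sprintf("Xxx_EUR_I%04d", 1:2504)
  carriers <- c(
    lapply(seq_len(16), function(i) list(pos = 100L)),   # 16 copies
    lapply(seq_len(15), function(i) list(pos = 200L)),
    list(list(pos = 300L))                               # singleton
  )
  names(carriers) <- c(inds[1:16], inds[101:115], inds[200])
  gt <- mk_genotypes(carriers, inds)
  db <- build_core_rare_db(gt, rare_threshold = 0.003)

  expect_equal(db$non_rare$pos, 100L)
  expect_setequal(db$entries$pos, c(200L, 300L))
  expect_equal(db$entries[pos == 200L, frequency], 15 / 5008)
  expect_equal(db$entries[pos == 300L, frequency], 1 / 5008)
  # partition: every observed allele in exactly one database
  expect_equal(nrow(db$entries) + nrow(db$non_rare), 3L)
  expect_length(intersect(db$entries[, paste(chrom, pos, alt)],
                          db$non_rare[, paste(chrom, pos, alt)]), 0)
})

test_that("lowering the threshold never adds rare alleles", {
  set.seed(11)
  inds <- sprintf("Yyy_EAS_I%03d", 1:50)
  carriers <- lapply(seq_along(inds), function(i) {
    list(pos = sample.int(1000, sample(1:5, 1)))
  })
  names(carriers) <- inds
  gt <- mk_genotypes(carriers, inds)
  keys <- function(db) db$entries[, paste(chrom, pos, alt)]
  prev <- NULL
  for (thr in c(0.20, 0.10, 0.05, 0.02)) {
    cur <- keys(build_core_rare_db(gt, thr))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("non-SNV records are rejected with a warning", {
  inds <- c("Aaa_EUR_I1", "Aaa_EUR_I2")
  calls <- data.frame(chrom = "chr1", pos = c(10L, 20L),
                      ref = c("A", "AT"), alt = c("C", "A"),
                      individual_id = inds, dosage = 1L)
  expect_warning(gt <- genotype_table(calls, inds), "non-SNV")
  expect_equal(nrow(gt$calls), 1L)
})

test_that("secondary cohort filter applies non-rare rejection then the copy cap", {
  prim_inds <- sprintf("Ppp_EUR_I%03d", 1:100)
  prim <- mk_genotypes(
    stats::setNames(c(lapply(1:60, function(i) list(pos = 1L)),   # frequent
                      list(list(pos = 2L))),
                    c(prim_inds[1:60], prim_inds[70])),
    prim_inds)
  db <- build_core_rare_db(prim, 0.01)
  expect_equal(db$non_rare$pos, 1L)

  sec_inds <- sprintf("Sss_SAS_I%02d", 1:30)
  sec <- mk_genotypes(
    stats::setNames(c(lapply(1:3, function(i) list(pos = 1L)),  # in non-rare
                      lapply(1:4, function(i) list(pos = 5L)),  # 4 copies: ok
                      lapply(1:5, function(i) list(pos = 6L))), # 5 copies: out
                    c(sec_inds[1:3], sec_inds[4:7], sec_inds[8:12])),
    sec_inds, cohort = "sgdp_like")
  spec <- cohort_spec("sgdp_like", "secondary", max_minor_count = 4)
  db2 <- filter_secondary_cohort(db, sec, spec)

  expect_equal(attr(db2, "n_added"), 1L)
  expect_true(5L %in% db2$entries$pos)        # accepted at the cap
  expect_false(6L %in% db2$entries$pos)       # above the cap
  expect_false(1L %in% db2$entries$pos)       # rejected by non-rare match
  expect_equal(db2$entries[pos == 5L, cohort], "sgdp_like")
})

test_that("secondary cohorts can be processed in either order", {
  prim_inds <- sprintf("Ppp_EUR_I%03d", 1:100)
  prim <- mk_genotypes(stats::setNames(list(list(pos = 2L)), prim_inds[1]),
                       prim_inds)
  db <- build_core_rare_db(prim, 0.01)

  mk_sec <- function(name, inds, sites) {
    mk_genotypes(sites, inds, cohort = name)
  }
  a_inds <- sprintf("Qaa_EAS_I%02d", 1:20)
  b_inds <- sprintf("Qbb_SAS_I%02d", 1:20)
  sec_a <- mk_sec("A", a_inds,
                  stats::setNames(list(list(pos = 10L), list(pos = 11L)),
                                  a_inds[1:2]))
  sec_b <- mk_sec("B", b_inds,
                  stats::setNames(list(list(pos = 10L), list(pos = 12L)),
                                  b_inds[1:2]))
  spec_a <- cohort_spec("A", "secondary", 4)
  spec_b <- cohort_spec("B", "secondary", 2)

  ab <- filter_secondary_cohort(filter_secondary_cohort(db, sec_a, spec_a),
                                sec_b, spec_b)
  ba <- filter_secondary_cohort(filter_secondary_cohort(db, sec_b, spec_b),
                                sec_a, spec_a)
  key <- function(d) d$entries[, paste(chrom, pos, alt)]
  expect_setequal(key(ab), key(ba))
  # carriers for the key both cohorts accepted are merged either way
  carr <- function(d) sort(unlist(d$entries[pos == 10L, carriers]))
  expect_equal(carr(ab), carr(ba))
  expect_length(carr(ab), 2L)
})

test_that("empty secondary cohort errors and adds nothing", {
  prim_inds <- sprintf("Ppp_EUR_I%02d", 1:10)
  prim <- mk_genotypes(stats::setNames(list(list(pos = 2L)), prim_inds[1]),
                       prim_inds)
  db <- build_core_rare_db(prim, 0.1)
  empty <- genotype_table(
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), individual_id = character()),
    individuals = "Zzz_SIB_I1", cohort = "empty")
  expect_error(
    filter_secondary_cohort(db, empty, cohort_spec("empty", "secondary", 2)),
    "no genotype calls")
})

test_that("ancient matching is exact set intersection against the database", {
  inds <- sprintf("Mmm_EUR_I%02d", 1:20)
  carriers <- stats::setNames(
    lapply(1:10, function(i) list(pos = i * 10L)), inds[1:10])
  db <- build_core_rare_db(mk_genotypes(carriers, inds), 0.1)
  expect_equal(nrow(db$entries), 10L)

  # ancient alleles are a superset of the db keys: profile is exactly the db
  anc_calls <- data.frame(chrom = "chr1",
                          pos = c(seq(10L, 100L, 10L), 501L, 502L),
                          ref = "A", alt = "C",
                          individual_id = "Anc_XXX_A1", dosage = 1L)
  anc <- genotype_table(anc_calls, "Anc_XXX_A1", cohort = "ancient")
  prof <- match_ancient_alleles(anc, db)
  expect_equal(n_markers(prof), 10L)
  expect_equal(prof$region_code, "XXX")
  expect_setequal(prof$markers$pos, seq(10L, 100L, 10L))

  # no overlap: empty profile
  anc2 <- genotype_table(
    data.frame(chrom = "chr1", pos = c(900L, 901L), ref = "A", alt = "C",
               individual_id = "Anc_XXX_A2", dosage = 1L),
    "Anc_XXX_A2", cohort = "ancient")
  expect_equal(n_markers(match_ancient_alleles(anc2, db)), 0L)
})

test_that("profiles conserve the database carrier assignments", {
  set.seed(3)
  inds <- sprintf("Ccc_SAS_I%02d", 1:30)
  carriers <- lapply(seq_along(inds), function(i) {
    list(pos = sort(sample.int(5000, sample(0:8, 1))))
  })
  names(carriers) <- inds
  carriers <- carriers[vapply(carriers, function(x) length(x$pos) > 0, TRUE)]
  gt <- mk_genotypes(carriers, inds)
  db <- build_core_rare_db(gt, 0.2)
  roster <- roster_from_ids(inds)
  profs <- build_individual_profiles(db, roster)

  expect_length(profs, 30L)
  total_markers <- sum(vapply(profs, n_markers, numeric(1)))
  expect_equal(total_markers, sum(lengths(db$entries$carriers)))
  # individuals with no rare alleles get empty profiles
  empty_ids <- setdiff(inds, names(carriers))
  if (length(empty_ids)) {
    expect_equal(n_markers(profs[[empty_ids[1]]]), 0L)
  }
  # a carrier missing from the roster is an error naming it
  expect_error(build_individual_profiles(db, roster[-1, ]),
               roster$individual_id[1])
})
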