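#' Pipeline configuration
#'
#' Bundles every threshold and parameter of a full run: the cohort source
#' (a [synthetic_config()], or a pre-built [genotype_table()] with roster),
#' the rare-allele frequency threshold, the cluster rule, the apportionment
#' cap and reference map, the median minimum, dating parameters, the OCE
#' restriction, and the output directory. All randomness is seeded from the
#' configuration, so a manifest plus the same inputs reproduces a run
#' bit-identically.
#'
#' @param cohort a [synthetic_config()], or a list with elements
#'   `genotypes` (a [genotype_table()]) and `roster`.
#' @param rare_threshold very-rare frequency cutoff; defaults to the
#'   synthetic config's own threshold, or 0.003 for real cohorts.
#' @param min_markers minimum shared markers per IBD cluster (default 5).
#' @param interruption_policy `"strict"` or `"lenient"`.
#' @param cap apportionment per-pair cap (default 100).
#' @param min_for_median minimum pooled segments for a median (default 5).
#' @param dating a [dating_params()].
#' @param dhgr_refs optional [dhgr_reference_map()]; apportionment and
#'   ranking are skipped without one.
#' @param oce_subset optional population identifiers representing OCE.
#' @param region_map optional named vector `population_id -> region/group`.
#' @param out_dir output directory (created if absent).
#' @param seed integer seed for the run.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort, rare_threshold = NULL, min_markers = 5L,
                            interruption_policy = "strict", cap = 100,
                            min_for_median = 5L, dating = dating_params(),
                            dhgr_refs = NULL, oce_subset = NULL,
                            region_map = NULL, out_dir = tempfile("rareibd_"),
                            seed = 1L) {
  if (inherits(cohort, "synthetic_config")) {
    rare_threshold <- rare_threshold %||% cohort$rare_threshold
  }
  rare_threshold <- rare_threshold %||% 0.003
  stopifnot(rare_threshold > 0, min_markers >= 2, cap > 0, min_for_median >= 1)
  structure(list(cohort = cohort, rare_threshold = rare_threshold,
                 min_markers = as.integer(min_markers),
                 interruption_policy = interruption_policy, cap = cap,
                 min_for_median = as.integer(min_for_median), dating = dating,
                 dhgr_refs = dhgr_refs, oce_subset = oce_subset,
                 region_map = region_map, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes every stage in order — cohort acquisition, very-rare-allele
#' database, individual profiles, all-pairs IBD scan, population matrices,
#' optional apportionment and per-population ranking, region medians,
#' dating table, individual-level MDS — and writes each product as
#' tab-delimited text under `config$out_dir`, together with a JSON manifest
#' of parameters, seeds and stage counts. A stage failure aborts with the
#' stage name and cause.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory objects (`db`, `profiles`,
#'   `catalog`, `matrices`, `dhgr`, `region_medians`, `dating`, `mds`) and
#'   `files` (named vector of emitted paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  emit <- function(name) {
    p <- file.path(config$out_dir, name)
    files[[name]] <<- p
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  cohort <- stage("cohort", {
    if (inherits(config$cohort, "synthetic_config")) {
      generate_cohort(config$cohort)
    } else {
      config$cohort
    }
  })
  genotypes <- cohort$genotypes
  roster <- as_roster(cohort$roster)

  db <- stage("rare_db", build_core_rare_db(genotypes, config$rare_threshold))
  write_rare_db(db, emit("rare_db.tsv"), emit("non_rare_db.tsv"))

  profiles <- stage("profiles", build_individual_profiles(db, roster))
  catalog <- stage("ibd_scan",
                   all_pairs_scan(profiles, config$min_markers,
                                  config$interruption_policy))
  write_catalog(catalog, emit("segments.tsv"))

  mats <- stage("popstats",
                population_matrices(catalog, profiles, config$min_for_median))
  sizes <- table(roster$population_id)
  size_lab <- stats::setNames(as.character(sizes), names(sizes))
  write_population_matrix(mats$I, emit("ibd_numbers.tsv"), N = mats$N,
                          sizes = size_lab)
  write_population_matrix(mats$J, emit("ibd_normalized.tsv"), N = mats$N,
                          sizes = size_lab)
  write_population_matrix(mats$mean_len, emit("ibd_mean_length.tsv"))
  write_population_matrix(mats$median_len, emit("ibd_median_length.tsv"))

  dhgr <- NULL
  if (!is.null(config$dhgr_refs)) {
    dhgr <- stage("dhgr", {
      missing_refs <- setdiff(unlist(config$dhgr_refs), rownames(mats$J))
      if (length(missing_refs)) {
        stop_("reference population(s) absent from cohort: ",
              paste(missing_refs, collapse = ", "))
      }
      apportion_all(mats$J, config$dhgr_refs, config$cap)
    })
    rounded <- copy(dhgr)
    for (j in setdiff(names(rounded), "population_id")) {
      set(rounded, j = j, value = round(rounded[[j]], 1))
    }
    fwrite(rounded, emit("dhgr_percentages.tsv"), sep = "\t")
    stage("ranking", {
      for (p in rownames(mats$J)) {
        write_rank_table(rank_populations(mats$J[p, ]),
                         emit(sprintf("rank_%s.tsv", p)))
      }
    })
  }

  region_medians <- stage("regions",
                          aggregate_regions(catalog, roster,
                                            region_map = config$region_map,
                                            oce_subset = config$oce_subset,
                                            min_for_median = config$min_for_median))
  write_population_matrix(region_medians, emit("region_medians_kb.tsv"))

  dating <- stage("dating",
                  dating_table(region_medians, params = config$dating))
  write_population_matrix(dating, emit("dating_ky.tsv"))

  mds <- stage("mds", {
    raw <- individual_count_matrix(catalog,
                                   ids = roster$individual_id)
    if (max(raw) > 0) {
      emb <- classical_mds(to_dissimilarity(build_similarity(raw)), dims = 2L)
      coords <- data.table(individual_id = rownames(emb$points),
                           emb$points)
      fwrite(coords, emit("mds_coordinates.tsv"), sep = "\t")
      emb
    }
  })

  manifest <- list(
    package = "rareIBD",
    version = as.character(utils::packageVersion("rareIBD")),
    seed = config$seed,
    parameters = list(rare_threshold = config$rare_threshold,
                      min_markers = config$min_markers,
                      interruption_policy = config$interruption_policy,
                      cap = config$cap,
                      min_for_median = config$min_for_median,
                      dating = unclass(config$dating),
                      oce_subset = config$oce_subset),
    synthetic_seed = if (inherits(config$cohort, "synthetic_config"))
      config$cohort$seed,
    counts = list(individuals = nrow(roster),
                  rare_alleles = nrow(db$entries),
                  non_rare_alleles = nrow(db$non_rare),
                  pairs_scanned = catalog$n_pairs_scanned,
                  segments = nrow(catalog$segments))
  )
  jsonlite::write_json(manifest, emit("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")

  invisible(list(db = db, profiles = profiles, catalog = catalog,
                 matrices = mats, dhgr = dhgr,
                 region_medians = region_medians, dating = dating,
                 mds = mds, files = unlist(files)))
}
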