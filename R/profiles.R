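#' Individual marker profiles
#'
#' An individual profile is the sorted per-chromosome track of very rare
#' alleles `(pos, alt)` an individual carries. Profiles are the unit of IBD
#' detection: a shared segment between two individuals is a run of
#' neighbouring markers present in both tracks.
#'
#' @param individual_id individual identifier.
#' @param population_id population identifier.
#' @param region_code three-letter region code (`XXX` for prehistoric or
#'   simulated samples).
#' @param markers data.frame with columns `chrom`, `pos`, `alt`; sorted on
#'   construction, duplicate `(chrom, pos, alt)` rows dropped.
#' @param db_token opaque fingerprint of the database the markers came from;
#'   detection refuses to compare profiles with differing tokens.
#' @return an object of class `individual_profile`.
#' @export
individual_profile <- function(individual_id, population_id,
                               region_code = "XXX", markers, db_token = NULL) {
  markers <- as.data.table(markers)[, .(chrom, pos, alt)]
  markers <- unique(markers)
  setkey(markers, chrom, pos, alt)
  if (nrow(markers) && any(markers$pos < 1)) {
    stop_("marker positions must be >= 1")
  }
  structure(
    list(individual_id = individual_id, population_id = population_id,
         region_code = region_code, markers = markers, db_token = db_token),
    class = "individual_profile"
  )
}

#' @export
print.individual_profile <- function(x, ...) {
  cat(sprintf("<individual_profile> %s (%s/%s): %d markers on %d chromosome(s)\n",
              x$individual_id, x$population_id, x$region_code,
              nrow(x$markers), length(unique(x$markers$chrom))))
  invisible(x)
}

#' Marker count of a profile
#' @param profile an [individual_profile()].
#' @return integer number of markers.
#' @export
n_markers <- function(profile) nrow(profile$markers)

#' Roster of a profile list
#' @param profiles list of [individual_profile()] objects.
#' @return data.table `individual_id, population_id, region_code`.
#' @export
profiles_roster <- function(profiles) {
  rbindlist(lapply(profiles, function(p) {
    data.table(individual_id = p$individual_id,
               population_id = p$population_id,
               region_code = p$region_code)
  }))
}
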