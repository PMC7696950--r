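#' Genotype tables
#'
#' The package's in-memory genotype container: a long table of carried
#' alternate alleles over biallelic SNVs. Only carriers are stored — the vast
#' majority of genotypes at a very rare site are homozygous reference, so the
#' long format is compact at any scale. Per-site called-genotype counts are
#' kept separately so allele frequencies use only genotyped individuals in
#' the denominator.
#'
#' @param calls data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `individual_id`, `dosage` (1 = heterozygous carrier, 2 = homozygous for
#'   the alternate allele). One row per carried alternate allele.
#' @param individuals character vector of all individual identifiers in the
#'   cohort, including non-carriers.
#' @param cohort cohort label.
#' @param sites optional data.frame with columns `chrom`, `pos`, `ref`,
#'   `alt`, `n_called` giving the number of individuals with a called
#'   genotype at each site; defaults to all individuals called everywhere.
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(calls, individuals, cohort = "cohort", sites = NULL) {
  if (!length(individuals)) stop_("cohort '", cohort, "' has zero individuals")
  calls <- as.data.table(calls)
  need <- c("chrom", "pos", "ref", "alt", "individual_id")
  if (!all(need %in% names(calls))) {
    stop_("calls must have columns ", paste(need, collapse = ", "))
  }
  if (!"dosage" %in% names(calls)) calls[, dosage := 1L]
  if (nrow(calls)) {
    if (any(is.na(calls$pos)) || any(calls$pos < 1)) {
      stop_("malformed genotype: positions must be >= 1")
    }
    if (!all(calls$dosage %in% 1:2)) {
      bad <- calls[!dosage %in% 1:2][1]
      stop_("malformed genotype at ", bad$chrom, ":", bad$pos,
            " for ", bad$individual_id, ": dosage must be 1 or 2")
    }
    unknown <- setdiff(calls$individual_id, individuals)
    if (length(unknown)) {
      stop_("malformed genotype: carrier(s) not in cohort roster: ",
            paste(utils::head(unknown, 5), collapse = ", "))
    }
    calls <- drop_non_snv(calls)
  }
  setkey(calls, chrom, pos, alt, individual_id)
  if (is.null(sites)) {
    sites <- unique(calls[, .(chrom, pos, ref, alt)])
    sites[, n_called := length(individuals)]
  } else {
    sites <- as.data.table(sites)
    sites <- drop_non_snv(sites, warn = FALSE)
  }
  setkey(sites, chrom, pos, alt)
  structure(
    list(calls = calls, sites = sites,
         individuals = individuals, cohort = cohort),
    class = "genotype_table"
  )
}

.nucs <- c("A", "C", "G", "T")

## reject indels / non-SNV rows with a warning naming how many were dropped
drop_non_snv <- function(dt, warn = TRUE) {
  ok <- dt$ref %in% .nucs & dt$alt %in% .nucs & dt$ref != dt$alt
  if (!all(ok)) {
    if (warn) {
      warning(sum(!ok), " non-SNV record(s) rejected (indels or malformed alleles)",
              call. = FALSE)
    }
    dt <- dt[ok]
  }
  dt
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> cohort '%s': %d individuals, %d sites, %d carried alleles\n",
              x$cohort, length(x$individuals), nrow(x$sites), nrow(x$calls)))
  invisible(x)
}

## per-site alternate-allele copy counts and frequencies for one cohort
site_frequencies <- function(genotypes) {
  counts <- genotypes$calls[, .(copies = sum(dosage),
                                carriers = list(sort(individual_id))),
                            by = .(chrom, pos, ref, alt)]
  out <- merge(genotypes$sites, counts, by = c("chrom", "pos", "ref", "alt"),
               all.x = TRUE)
  out[is.na(copies), copies := 0L]
  out[, frequency := copies / (2 * n_called)]
  out[]
}
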