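#' Read genotypes from a VCF file
#'
#' Streams biallelic SNV records from a VCF 4.x file into a
#' [genotype_table()]. Multi-allelic sites are decomposed into one record
#' per alternate allele, each judged independently downstream; indel and
#' otherwise non-SNV alternates are skipped. Counts of decomposed and
#' skipped records are reported so per-stage dataset accounting stays
#' reproducible. Missing genotypes are excluded from the per-site
#' called-genotype denominator.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @param cohort cohort label attached to the table.
#' @return a [genotype_table()].
#' @export
read_genotypes <- function(path, cohort = basename(path)) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.table(vcfR::getFIX(vcf))
  if (!nrow(fix)) {
    warning("empty VCF: ", path, call. = FALSE)
    return(genotype_table(
      data.table(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), individual_id = character(), dosage = integer()),
      individuals = colnames(vcf@gt)[-1] %||% character(), cohort = cohort))
  }
  if (is.null(vcf@gt) || !all(grepl("(^|:)GT(:|$)", vcf@gt[, "FORMAT"]))) {
    stop_("VCF lacks a GT field: ", path)
  }
  fix[, pos := as.integer(POS)]
  if (any(fix[, diff(pos) < 0, by = CHROM]$V1)) {
    stop_("unsorted VCF: ", path)
  }
  samples <- colnames(vcf@gt)[-1]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  allele_lists <- strsplit(gsub("\\|", "/", gt), "/", fixed = TRUE)
  dim(allele_lists) <- dim(gt)

  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_multi <- sum(lengths(alts) > 1)
  calls <- list(); sites <- list(); n_skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    row_alleles <- allele_lists[i, ]
    called <- !vapply(row_alleles, function(a) any(is.na(a) | a == "."),
                      logical(1))
    for (k in seq_along(alts[[i]])) {
      ref <- fix$REF[i]; alt <- alts[[i]][k]
      if (!(ref %in% .nucs && alt %in% .nucs && ref != alt)) {
        n_skipped <- n_skipped + 1L
        next
      }
      dos <- vapply(row_alleles, function(a) sum(a == as.character(k)),
                    integer(1))
      dos[!called] <- 0L
      carrier <- called & dos > 0L
      sites[[length(sites) + 1L]] <- data.table(
        chrom = fix$CHROM[i], pos = fix$pos[i], ref = ref, alt = alt,
        n_called = sum(called))
      if (any(carrier)) {
        calls[[length(calls) + 1L]] <- data.table(
          chrom = fix$CHROM[i], pos = fix$pos[i], ref = ref, alt = alt,
          individual_id = samples[carrier], dosage = dos[carrier])
      }
    }
  }
  if (n_skipped || n_multi) {
    message(sprintf("%s: %d record(s) ingested, %d multi-allelic site(s) decomposed, %d non-SNV alternate(s) skipped",
                    basename(path), length(sites), n_multi, n_skipped))
  }
  calls <- if (length(calls)) rbindlist(calls) else
    data.table(chrom = character(), pos = integer(), ref = character(),
               alt = character(), individual_id = character(),
               dosage = integer())
  genotype_table(calls, individuals = samples, cohort = cohort,
                 sites = rbindlist(sites))
}

#' Write a genotype table as VCF
#'
#' Emits a minimal sorted VCF 4.2 with a GT field, fixed sample ordering,
#' and one biallelic record per `(chrom, pos, alt)` — byte-reproducible for
#' a fixed input.
#'
#' @param genotypes a [genotype_table()] or [generate_cohort()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  if (inherits(genotypes, "synthetic_cohort")) genotypes <- genotypes$genotypes
  stopifnot(inherits(genotypes, "genotype_table"))
  samples <- genotypes$individuals
  sites <- copy(genotypes$sites)
  setorder(sites, chrom, pos, alt)
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gt_of <- c("0/0", "0/1", "1/1")
  by_site <- split(genotypes$calls[, .(individual_id, dosage)],
                   genotypes$calls[, paste(chrom, pos, alt)])
  lines <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i]
    dos <- integer(length(samples)); names(dos) <- samples
    hit <- by_site[[paste(s$chrom, s$pos, s$alt)]]
    if (!is.null(hit)) dos[hit$individual_id] <- hit$dosage
    paste(c(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", ".", "GT",
            gt_of[dos + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}
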