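#' Tabular output formats
#'
#' Every emitted table is plain tab-delimited text and re-parses into an
#' object equal to the in-memory one. `N/A` is written literally for
#' undefined cells, matching the convention of the printed matrices.
#'
#' @name tables_io
NULL

#' @describeIn tables_io Write the very-rare-allele database (one row per
#'   allele: `chrom, pos, ref, alt, cohort, frequency`, comma-joined
#'   carriers) and, optionally, the non-rare database in the same schema
#'   minus carriers.
#' @param db a `rare_allele_db`.
#' @param path output path for the rare-allele table.
#' @param non_rare_path optional output path for the non-rare table.
#' @export
write_rare_db <- function(db, path, non_rare_path = NULL) {
  out <- copy(db$entries)
  out[, carriers := vapply(carriers, paste, character(1), collapse = ",")]
  fwrite(out, path, sep = "\t")
  if (!is.null(non_rare_path)) {
    fwrite(db$non_rare, non_rare_path, sep = "\t")
  }
  invisible(path)
}

#' @describeIn tables_io Read a database written by [write_rare_db()].
#' @param threshold frequency threshold to record on the object.
#' @export
read_rare_db <- function(path, non_rare_path = NULL, threshold = 0.003) {
  entries <- fread(path, sep = "\t",
                   colClasses = list(character = c("chrom", "ref", "alt",
                                                   "cohort", "carriers")))
  entries[, carriers := strsplit(carriers, ",", fixed = TRUE)]
  setkey(entries, chrom, pos, alt)
  non_rare <- if (!is.null(non_rare_path)) {
    nr <- fread(non_rare_path, sep = "\t")
    # header-only files type columns as logical; coerce to the schema
    nr <- nr[, .(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt))]
    setkey(nr, chrom, pos, alt)
  } else {
    data.table(chrom = character(), pos = integer(), ref = character(),
               alt = character(), key = c("chrom", "pos", "alt"))
  }
  structure(list(entries = entries, non_rare = non_rare,
                 threshold = threshold),
            class = "rare_allele_db")
}

#' @describeIn tables_io Write a segment catalog
#'   (`id_a, id_b, chrom, start, end, n_markers, length_bp`); catalog
#'   bookkeeping goes into `#`-prefixed header lines.
#' @param catalog a [segment_catalog()].
#' @export
write_catalog <- function(catalog, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_individuals=%d", catalog$n_individuals),
               sprintf("# n_pairs_scanned=%.0f", catalog$n_pairs_scanned)),
             con)
  close(con); on.exit()
  fwrite(catalog$segments, path, sep = "\t", append = TRUE,
         col.names = TRUE)
  invisible(path)
}

#' @describeIn tables_io Read a catalog written by [write_catalog()].
#' @export
read_catalog <- function(path) {
  hdr <- readLines(path, n = 2L)
  meta <- as.numeric(sub(".*=", "", hdr))
  segs <- fread(path, sep = "\t", skip = 2L,
                colClasses = list(character = c("id_a", "id_b", "chrom")))
  segment_catalog(segs, n_individuals = meta[1], n_pairs_scanned = meta[2])
}

#' @describeIn tables_io Write a population matrix with leading identifier /
#'   name / cohort-sized columns and, when coefficients are supplied, a
#'   final `Norm_Coeff` column and row mirroring the printed layout.
#' @param m numeric matrix with population identifiers as dimnames.
#' @param N optional [normalization_coefficients()] table.
#' @param sizes optional named vector of population size labels, cohort
#'   letter suffixes included (e.g. `"10"`, `"2s"`, `"1v"`).
#' @param names optional named vector of display names.
#' @export
write_population_matrix <- function(m, path, N = NULL, sizes = NULL,
                                    names = NULL) {
  pops <- rownames(m)
  body <- as.data.table(m)
  for (j in seq_along(body)) set(body, j = j, value = na_str(body[[j]]))
  out <- data.table(id = pops,
                    name = if (is.null(names)) pops else unname(names[pops]),
                    size = if (is.null(sizes)) "" else unname(sizes[pops]))
  out <- cbind(out, body)
  if (!is.null(N)) {
    out[, Norm_Coeff := na_str(unclass(N)[pops])]
    last <- as.list(c("Norm_Coeff", "", "", na_str(unclass(N)[pops]), ""))
    names(last) <- names(out)
    out <- rbind(out, last)
  }
  fwrite(out, path, sep = "\t")
  invisible(path)
}

na_str <- function(x) ifelse(is.na(x), "N/A", format(x, digits = 10,
                                                     trim = TRUE,
                                                     scientific = FALSE))

#' @describeIn tables_io Read a matrix written by
#'   [write_population_matrix()]; returns list `m`, `N` (NULL when absent).
#' @export
read_population_matrix <- function(path) {
  raw <- fread(path, sep = "\t", colClasses = "character")
  has_N <- "Norm_Coeff" %in% names(raw)
  if (has_N && raw$id[nrow(raw)] == "Norm_Coeff") raw <- raw[-nrow(raw)]
  pops <- raw$id
  cols <- setdiff(names(raw), c("id", "name", "size", "Norm_Coeff"))
  m <- as.matrix(raw[, lapply(.SD, function(x) {
    suppressWarnings(as.numeric(ifelse(x == "N/A", NA, x)))
  }), .SDcols = cols])
  rownames(m) <- pops
  N <- NULL
  if (has_N) {
    N <- suppressWarnings(as.numeric(ifelse(raw$Norm_Coeff == "N/A", NA,
                                            raw$Norm_Coeff)))
    names(N) <- pops
    class(N) <- "normalization_table"
  }
  list(m = m, N = N)
}

#' @describeIn tables_io Write one population's ranking table
#'   (`ibd, population_id, population_name`).
#' @param rank_table a [rank_populations()] result.
#' @export
write_rank_table <- function(rank_table, path) {
  fwrite(rank_table, path, sep = "\t")
  invisible(path)
}
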