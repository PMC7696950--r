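#' Detect shared IBD segments between two individuals
#'
#' A shared IBD segment is a maximal run of at least `min_markers`
#' neighbouring very rare alleles common to both individuals (default 5,
#' which keeps the chance of a coincidental identical-by-state run
#' negligible). "Neighbouring" means consecutive in the merged sorted marker
#' track of the pair. Under the default `"strict"` interruption policy a
#' rare allele carried by exactly one of the two individuals that lies
#' strictly between two shared markers terminates the run — a non-shared
#' very rare allele inside a truly identical-by-descent span is unexpected.
#' The `"lenient"` policy ignores private markers. Segment coordinates are
#' 1-based inclusive; `length_bp = end - start + 1`.
#'
#' @param a,b [individual_profile()] objects drawn from the same database.
#' @param min_markers minimum shared markers per cluster (>= 2; default 5).
#' @param interruption_policy `"strict"` or `"lenient"`.
#' @param max_gap optional maximum base-pair gap between consecutive shared
#'   markers within a run (default `Inf`: no gap limit).
#' @return data.table with columns `id_a, id_b, chrom, start, end,
#'   n_markers, length_bp`, one row per segment; zero rows when none found.
#' @seealso [enumerate_shared_clusters_naive()] for the exhaustive reference
#'   implementation used in tests, [all_pairs_scan()] for whole cohorts.
#' @export
detect_shared_segments <- function(a, b, min_markers = 5L,
                                   interruption_policy = c("strict", "lenient"),
                                   max_gap = Inf) {
  interruption_policy <- match.arg(interruption_policy)
  check_pair(a, b, min_markers)
  segs <- lapply(intersect(unique(a$markers$chrom), unique(b$markers$chrom)),
                 function(ch) {
    runs <- shared_runs(a$markers[chrom == ch], b$markers[chrom == ch],
                        interruption_policy, max_gap)
    runs <- runs[lengths(runs) >= min_markers]
    if (!length(runs)) return(NULL)
    data.table(
      chrom = ch,
      start = vapply(runs, min, numeric(1)),
      end   = vapply(runs, max, numeric(1)),
      n_markers = lengths(runs)
    )
  })
  segs <- rbindlist(segs)
  finish_segments(segs, a$individual_id, b$individual_id)
}

check_pair <- function(a, b, min_markers) {
  stopifnot(inherits(a, "individual_profile"), inherits(b, "individual_profile"))
  if (min_markers < 1) stop_("min_markers must be >= 1")
  if (!is.null(a$db_token) && !is.null(b$db_token) && a$db_token != b$db_token) {
    stop_("profiles '", a$individual_id, "' and '", b$individual_id,
          "' come from different rare-allele databases")
  }
}

## positions of maximal uninterrupted runs of shared markers on one chromosome
shared_runs <- function(ma, mb, policy, max_gap) {
  ka <- paste(ma$pos, ma$alt)
  kb <- paste(mb$pos, mb$alt)
  shared_pos <- sort(ma$pos[ka %in% kb])
  k <- length(shared_pos)
  if (!k) return(list())
  brk <- logical(max(k - 1L, 0L))             # break after marker i?
  if (k > 1L) {
    if (is.finite(max_gap)) {
      brk <- brk | diff(shared_pos) > max_gap
    }
    if (policy == "strict") {
      priv <- sort(c(ma$pos[!ka %in% kb], mb$pos[!kb %in% ka]))
      if (length(priv)) {
        fi <- findInterval(priv, shared_pos)
        inside <- fi >= 1L & fi < k & priv > shared_pos[pmax(fi, 1L)]
        brk[unique(fi[inside])] <- TRUE
      }
    }
  }
  split(shared_pos, cumsum(c(0L, brk)))
}

finish_segments <- function(segs, id_a, id_b) {
  empty <- data.table(id_a = character(), id_b = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), n_markers = integer(),
                      length_bp = numeric())
  if (is.null(segs) || !nrow(segs)) return(empty)
  ids <- sort(c(id_a, id_b))                  # unordered pair, canonical order
  segs[, `:=`(id_a = ids[1], id_b = ids[2], length_bp = end - start + 1)]
  setcolorder(segs, names(empty))
  setorder(segs, chrom, start)
  segs[]
}

#' Exhaustively enumerate shared marker clusters (reference oracle)
#'
#' Same contract as [detect_shared_segments()], implemented by brute-force
#' scan over every window of shared markers: a window is reported iff it has
#' at least `min_markers` markers, is uninterrupted under the chosen policy,
#' and cannot be extended by an adjacent shared marker. Quadratic in the
#' number of shared markers; intended for verification on small profiles.
#'
#' @inheritParams detect_shared_segments
#' @return as [detect_shared_segments()].
#' @export
enumerate_shared_clusters_naive <- function(a, b, min_markers = 5L,
                                            interruption_policy = c("strict", "lenient"),
                                            max_gap = Inf) {
  interruption_policy <- match.arg(interruption_policy)
  check_pair(a, b, min_markers)
  out <- list()
  for (ch in intersect(unique(a$markers$chrom), unique(b$markers$chrom))) {
    ma <- a$markers[chrom == ch]; mb <- b$markers[chrom == ch]
    ka <- paste(ma$pos, ma$alt); kb <- paste(mb$pos, mb$alt)
    s <- sort(ma$pos[ka %in% kb])
    priv <- sort(c(ma$pos[!ka %in% kb], mb$pos[!kb %in% ka]))
    k <- length(s)
    if (k < min_markers) next
    ## gap (i, i+1) is admissible if no private marker strictly inside and
    ## the gap is not longer than max_gap
    gap_ok <- function(i) {
      if (interruption_policy == "strict" &&
          any(priv > s[i] & priv < s[i + 1])) return(FALSE)
      (s[i + 1] - s[i]) <= max_gap
    }
    for (i in seq_len(k)) {
      for (j in i:k) {
        if (j - i + 1 < min_markers) next
        if (j > i && !all(vapply(i:(j - 1), gap_ok, logical(1)))) next
        ## maximal: no admissible extension left or right
        if (i > 1 && gap_ok(i - 1)) next
        if (j < k && gap_ok(j)) next
        out[[length(out) + 1L]] <- data.table(
          chrom = ch, start = s[i], end = s[j], n_markers = j - i + 1L)
      }
    }
  }
  finish_segments(rbindlist(out), a$individual_id, b$individual_id)
}

#' Number of unordered pairings among n individuals
#'
#' @param n number of individuals.
#' @return `choose(n, 2)` as a plain number; e.g. 3121 modern plus 7 ancient
#'   genomes give `n_pairings(3128) == 4890628`.
#' @export
n_pairings <- function(n) {
  n <- as.numeric(n)
  n * (n - 1) / 2
}

#' Scan every pair of profiles for shared IBD segments
#'
#' Runs [detect_shared_segments()] over all `choose(n, 2)` unordered pairs
#' and collects the results into a segment catalog.
#'
#' @param profiles list of [individual_profile()] objects (>= 2).
#' @inheritParams detect_shared_segments
#' @param interruption_policy passed through to the per-pair detector.
#' @return an object of class `segment_catalog`: list with `segments`
#'   (data.table as returned per pair), `n_individuals`, `n_pairs_scanned`.
#' @export
all_pairs_scan <- function(profiles, min_markers = 5L,
                           interruption_policy = c("strict", "lenient"),
                           max_gap = Inf) {
  interruption_policy <- match.arg(interruption_policy)
  if (length(profiles) < 2) stop_("need at least 2 profiles")
  ids <- vapply(profiles, `[[`, character(1), "individual_id")
  if (anyDuplicated(ids)) {
    stop_("duplicate individual identifiers: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  n <- length(profiles)
  segs <- vector("list", n_pairings(n))
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      k <- k + 1L
      segs[[k]] <- detect_shared_segments(profiles[[i]], profiles[[j]],
                                          min_markers, interruption_policy,
                                          max_gap)
    }
  }
  segment_catalog(rbindlist(segs), n_individuals = n, n_pairs_scanned = k)
}

#' @rdname all_pairs_scan
#' @param segments data.table of segments (as emitted per pair).
#' @param n_individuals,n_pairs_scanned catalog bookkeeping counts.
#' @export
segment_catalog <- function(segments, n_individuals, n_pairs_scanned) {
  structure(list(segments = as.data.table(segments),
                 n_individuals = as.integer(n_individuals),
                 n_pairs_scanned = n_pairs_scanned),
            class = "segment_catalog")
}

#' @export
print.segment_catalog <- function(x, ...) {
  cat(sprintf("<segment_catalog> %d segments from %s pairings of %d individuals\n",
              nrow(x$segments), format(x$n_pairs_scanned, big.mark = ","),
              x$n_individuals))
  invisible(x)
}
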