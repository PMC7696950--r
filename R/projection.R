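#' Build a normalized similarity matrix from raw shared-IBD counts
#'
#' Forces symmetry by mirroring the lower triangle onto the upper (pairwise
#' scans can leave tiny asymmetries depending on orientation of the
#' bookkeeping), then divides every value by the global maximum so the
#' largest similarity is exactly 1. The diagonal (self-similarity) is
#' undefined at the individual level and is excluded from the maximum and
#' set to `NA`.
#'
#' @param raw square numeric matrix of shared-IBD counts between
#'   individuals, with identifiers as dimnames.
#' @return an object of class `similarity_matrix` (a matrix with entries in
#'   `[0, 1]`, `NA` diagonal).
#' @export
build_similarity <- function(raw) {
  if (!is.matrix(raw) || nrow(raw) != ncol(raw)) {
    stop_("raw must be a square matrix")
  }
  m <- raw
  m[upper.tri(m)] <- t(m)[upper.tri(m)]     # mirror lower triangle up
  diag(m) <- NA_real_
  mx <- max(m, na.rm = TRUE)
  if (mx <= 0) stop_("no positive similarity values")
  m <- m / mx
  structure(m, class = c("similarity_matrix", "matrix"))
}

#' Convert similarities to dissimilarities
#'
#' Applies `d = (1 - s)/s` elementwise: a pair sharing the maximum number of
#' segments (`s = 1`) is at distance 0, and distance grows without bound as
#' sharing vanishes. Pairs with `s = 0` would be infinitely distant; they
#' are assigned the distance of a similarity equal to half the smallest
#' positive entry — maximally distant but finite. The diagonal is 0 by
#' definition.
#'
#' @param s a [build_similarity()] matrix (entries in `[0, 1]`).
#' @return symmetric distance matrix with zero diagonal.
#' @export
to_dissimilarity <- function(s) {
  m <- unclass(s)
  if (any(m < 0, na.rm = TRUE)) stop_("negative similarity")
  if (any(m > 1, na.rm = TRUE)) stop_("similarity above 1; normalize first")
  pos <- m[!is.na(m) & m > 0]
  if (!length(pos)) stop_("no positive similarity values")
  s_floor <- min(pos) / 2
  m[!is.na(m) & m == 0] <- s_floor
  d <- (1 - m) / m
  diag(d) <- 0
  d
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Torgerson scaling: double-centre the squared distances, eigendecompose,
#' and return the top-`dims` coordinates scaled by the square root of their
#' eigenvalues (via [stats::cmdscale()]). Coordinates are centred and
#' deterministic up to sign and rotation; distances between embedded points
#' reproduce the input exactly when the input is Euclidean-embeddable in
#' `dims` dimensions. When fewer than `dims` positive eigenvalues exist the
#' missing coordinates are zero-padded with a warning.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param dims target dimensionality (default 2).
#' @return an object of class `mds_embedding`: list with `points`
#'   (n x dims coordinate matrix) and `eig` (all eigenvalues, decreasing).
#' @export
classical_mds <- function(d, dims = 2L) {
  if (!isTRUE(all.equal(unname(d), unname(t(d))))) stop_("d must be symmetric")
  k <- min(dims, nrow(d) - 1L)
  fit <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < dims) {
    warning("fewer than ", dims, " positive eigenvalues; padding with zeros",
            call. = FALSE)
    pts <- cbind(pts, matrix(0, nrow(pts), dims - ncol(pts)))
  }
  colnames(pts) <- paste0("MDS", seq_len(dims))
  structure(list(points = pts, eig = fit$eig), class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("<mds_embedding> %d points in %d dimensions; top eigenvalues: %s\n",
              nrow(x$points), ncol(x$points),
              paste(signif(utils::head(x$eig, 3), 4), collapse = ", ")))
  invisible(x)
}

#' Individual-by-individual shared-segment count matrix
#'
#' Counts shared segments per unordered pair of individuals from a segment
#' catalog — the raw input to [build_similarity()].
#'
#' @param catalog a [segment_catalog()].
#' @param ids individual identifiers fixing row order (default: all ids in
#'   the catalog, sorted).
#' @return square numeric count matrix.
#' @export
individual_count_matrix <- function(catalog, ids = NULL) {
  segs <- catalog$segments
  ids <- ids %||% sort(unique(c(segs$id_a, segs$id_b)))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(segs)) {
    counts <- segs[, .N, by = .(id_a, id_b)]
    counts <- counts[id_a %in% ids & id_b %in% ids]
    m[cbind(counts$id_a, counts$id_b)] <- counts$N
    m[cbind(counts$id_b, counts$id_a)] <- counts$N
  }
  m
}
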