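# Core data types: feature tables, group labels, distance matrices and 2D
# embeddings. All are thin S3 wrappers around base matrices/vectors with
# validated invariants; downstream code may also pass plain matrices, which
# are validated on entry.

#' Construct a sample-by-feature abundance table
#'
#' A feature table holds an `N x S` nonnegative matrix of abundances with
#' samples in rows. Row and column names act as sample and feature
#' identifiers and must be unique. When `relative = TRUE` every row must sum
#' to one (total-sum scaled composition).
#'
#' @param values numeric `N x S` matrix, samples in rows.
#' @param sample_ids optional character vector of N sample identifiers;
#'   defaults to existing rownames or `sample1..sampleN`.
#' @param feature_ids optional character vector of S feature identifiers.
#' @param relative logical; is the table row-normalized to relative
#'   abundances?
#' @return an object of class `feature_table` (a matrix with attributes).
#' @examples
#' x <- feature_table(matrix(c(2, 1, 2, 3, 0, 0), nrow = 2))
#' @export
feature_table <- function(values, sample_ids = NULL, feature_ids = NULL,
                          relative = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); s <- ncol(values)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(values)
    if (is.null(feature_ids)) feature_ids <- paste0("feature", seq_len(s))
  }
  if (length(sample_ids) != n) stop_fmds("sample_ids length != nrow(values)")
  if (length(feature_ids) != s) stop_fmds("feature_ids length != ncol(values)")
  if (anyDuplicated(sample_ids))
    stop_fmds("duplicate sample ids: ",
              paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(feature_ids))
    stop_fmds("duplicate feature ids: ",
              paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop_fmds("feature table contains non-finite values")
  if (any(values < 0)) stop_fmds("feature table contains negative values")
  if (isTRUE(relative)) {
    rs <- rowSums(values)
    bad <- which(abs(rs - 1) > 1e-9)
    if (length(bad))
      stop_fmds("relative-abundance rows do not sum to 1: ",
                paste(sample_ids[bad[seq_len(min(5, length(bad)))]],
                      collapse = ", "))
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(values, relative = isTRUE(relative),
            class = c("feature_table", "matrix", "array"))
}

#' Total-sum scale a feature table to relative abundances
#'
#' @param table a `feature_table` or nonnegative matrix, samples in rows.
#' @return a `feature_table` with `relative = TRUE`.
#' @export
relative_abundance <- function(table) {
  x <- as_table_matrix(table)
  rs <- rowSums(x)
  if (any(rs == 0))
    stop_fmds("all-zero sample row(s): ",
              paste(rownames(x)[rs == 0], collapse = ", "))
  feature_table(x / rs, relative = TRUE)
}

#' Construct a validated group label vector
#'
#' Labels are integers in `1..G`; each group must occur at least twice so
#' that within-group dispersion is defined.
#'
#' @param labels integer (or coercible) vector of group memberships.
#' @param G optional group count; defaults to `max(labels)`.
#' @return named integer vector of labels with attribute `G`.
#' @export
group_labels <- function(labels, G = NULL) {
  y <- as.integer(labels)
  if (anyNA(y)) stop_fmds("labels contain missing values")
  if (is.null(G)) G <- max(y)
  if (any(y < 1L) || any(y > G)) stop_fmds("labels must lie in 1..G")
  tab <- tabulate(y, nbins = G)
  if (any(tab == 0L))
    stop_fmds("empty group(s): ", paste(which(tab == 0L), collapse = ", "))
  if (any(tab < 2L))
    stop_fmds("group(s) with fewer than two samples: ",
              paste(which(tab < 2L), collapse = ", "))
  names(y) <- names(labels)
  attr(y, "G") <- as.integer(G)
  y
}

#' Construct a distance matrix object
#'
#' @param values square numeric matrix of pairwise dissimilarities.
#' @param metric name of the dissimilarity metric (free text).
#' @param sample_ids optional sample identifiers.
#' @return object of class `dist_matrix`.
#' @export
dist_matrix <- function(values, metric = "unknown", sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (ncol(values) != n) stop_fmds("distance matrix is not square")
  if (anyNA(values) || any(!is.finite(values)))
    stop_fmds("distance matrix contains non-finite values")
  asym <- abs(values - t(values))
  if (max(asym) > 1e-12) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop_fmds(sprintf("distance matrix asymmetric at (%d,%d)", ij[1], ij[2]))
  }
  if (any(abs(diag(values)) > 1e-12)) stop_fmds("distance matrix diagonal not zero")
  if (any(values < 0)) stop_fmds("distance matrix has negative entries")
  diag(values) <- 0
  values[] <- (values + t(values)) / 2   # symmetrize roundoff
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))
  }
  if (length(sample_ids) != n) stop_fmds("sample_ids length != nrow(values)")
  if (anyDuplicated(sample_ids)) stop_fmds("duplicate sample ids")
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(values, metric = metric,
            class = c("dist_matrix", "matrix", "array"))
}

#' Construct a 2D embedding
#'
#' Coordinates are stored as a `2 x N` matrix (points in columns), mirroring
#' the configuration `Z = (z_1, ..., z_N)`.
#'
#' @param coords numeric `2 x N` matrix of coordinates.
#' @param sample_ids optional sample identifiers for the N points.
#' @return object of class `embedding`.
#' @export
embedding <- function(coords, sample_ids = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != 2L) stop_fmds("embedding must be 2 x N (points in columns)")
  if (anyNA(coords) || any(!is.finite(coords)))
    stop_fmds("embedding contains non-finite coordinates")
  n <- ncol(coords)
  if (is.null(sample_ids)) {
    sample_ids <- colnames(coords)
    if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))
  }
  if (length(sample_ids) != n) stop_fmds("sample_ids length != ncol(coords)")
  if (anyDuplicated(sample_ids)) stop_fmds("duplicate sample ids")
  dimnames(coords) <- list(c("dim1", "dim2"), sample_ids)
  structure(coords, class = c("embedding", "matrix", "array"))
}

# ---- internal coercers ------------------------------------------------------

as_table_matrix <- function(table) {
  x <- as.matrix(unclass(table))
  storage.mode(x) <- "double"
  if (any(x < 0)) stop_fmds("feature table contains negative values")
  x
}

as_dist_matrix <- function(D) {
  if (inherits(D, "dist_matrix")) return(D)
  if (inherits(D, "dist")) return(dist_matrix(as.matrix(D)))
  dist_matrix(as.matrix(D))
}

as_embedding <- function(Z) {
  if (inherits(Z, "embedding")) return(Z)
  Z <- as.matrix(Z)
  if (nrow(Z) != 2L && ncol(Z) == 2L) Z <- t(Z)
  embedding(Z)
}

# Coordinates of points from an embedding or a feature-like matrix, points
# in rows, for pairwise-distance computations.
points_matrix <- function(points) {
  if (inherits(points, "embedding")) return(t(unclass(points)))
  x <- as.matrix(unclass(points))
  storage.mode(x) <- "double"
  x
}

# ---- distances --------------------------------------------------------------

#' Bray-Curtis dissimilarity between samples
#'
#' `d_ij = sum_s |x_is - x_js| / sum_s (x_is + x_js)`, computed on the rows
#' of an abundance table. Values lie in `[0, 1]`; identical rows give 0 and
#' rows with disjoint support give 1. All-zero rows are rejected (the
#' denominator would vanish for some pair).
#'
#' @param table `feature_table` or nonnegative matrix, samples in rows.
#' @return a `dist_matrix` with metric `"bray-curtis"`.
#' @examples
#' bray_curtis(rbind(c(2, 2, 0), c(1, 3, 0)))  # 0.25
#' @export
bray_curtis <- function(table) {
  x <- as_table_matrix(table)
  if (nrow(x) < 2L) stop_fmds("need at least 2 samples")
  rs <- rowSums(x)
  if (any(rs == 0))
    stop_fmds("all-zero sample row(s): ",
              paste(which(rs == 0), collapse = ", "))
  # |x_i - x_j| summed = (x_i + x_j) - 2 * min(x_i, x_j); use the min trick
  # via matrix algebra: sum min is not bilinear, fall back to a blocked loop.
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    xi <- x[i, ]
    rest <- (i + 1L):n
    num <- rowSums(abs(x[rest, , drop = FALSE] -
                         matrix(xi, length(rest), ncol(x), byrow = TRUE)))
    den <- rs[rest] + rs[i]
    d[i, rest] <- num / den
    d[rest, i] <- d[i, rest]
  }
  dist_matrix(d, metric = "bray-curtis", sample_ids = rownames(x))
}

#' Euclidean pairwise distances
#'
#' @param points an `embedding` (2 x N) or a matrix of points in rows.
#' @return a `dist_matrix` with metric `"euclidean"`.
#' @export
euclidean_pairwise <- function(points) {
  p <- points_matrix(points)
  if (nrow(p) < 2L) stop_fmds("need at least 2 points")
  d <- as.matrix(stats::dist(p, method = "euclidean"))
  dist_matrix(d, metric = "euclidean", sample_ids = rownames(p))
}

# Squared Euclidean distances of an embedding, plain matrix (hot path).
embed_dist <- function(Z) {
  zc <- unclass(as_embedding(Z))
  s <- colSums(zc^2)
  d2 <- outer(s, s, "+") - 2 * crossprod(zc)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  sqrt(d2)
}
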