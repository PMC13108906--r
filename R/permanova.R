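# Pseudo-F statistic and permutation-based multivariate analysis of
# variance (PERMANOVA) on a distance matrix, specialized to balanced
# designs:
#
#   F = ( sum_{i,j} d_ij^2 / (G * sum_{i,j} eps_ij d_ij^2) - 1 ) * (N-G)/(G-1)
#
# with eps_ij = 1{y_i = y_j} (sums over ordered pairs; the factor 2
# cancels). For one-dimensional Euclidean data this equals the classical
# one-way ANOVA F. The permutation p-value is
#
#   p = (1/K) * #{k : F^Pi_k >= F}
#
# with ties counting toward the numerator; no continuity correction is
# applied, so p may be exactly 0.

check_balanced <- function(y) {
  y <- group_labels(y)
  G <- attr(y, "G")
  tab <- tabulate(y, nbins = G)
  if (length(unique(tab)) != 1L)
    stop_fmds("unbalanced design: group sizes ", paste(tab, collapse = ", "),
              " (the pseudo-F used here assumes a balanced design)")
  if (G < 2L) stop_fmds("need at least two groups")
  y
}

# Within-group ordered-pair sum of squared distances for one labeling.
within_ss <- function(D2, y, G) {
  s <- 0
  for (g in seq_len(G)) {
    idx <- which(y == g)
    s <- s + sum(D2[idx, idx])
  }
  s
}

#' Pseudo-F statistic for grouped distances (balanced design)
#'
#' @param D a `dist_matrix` (or square symmetric matrix).
#' @param y group labels (integer vector, validated as balanced).
#' @return the pseudo-F statistic (scalar).
#' @examples
#' D <- matrix(2, 4, 4) - diag(2, 4)
#' D[1, 2] <- D[2, 1] <- D[3, 4] <- D[4, 3] <- 1
#' pseudo_f(D, c(1, 1, 2, 2))  # 7
#' @export
pseudo_f <- function(D, y) {
  D <- as_dist_matrix(D)
  y <- check_balanced(y)
  G <- attr(y, "G")
  n <- nrow(D)
  if (length(y) != n) stop_fmds("labels length != distance matrix size")
  if (n - G < 1L) stop_fmds("need N - G >= 1")
  D2 <- unclass(D)^2
  tot <- sum(D2)
  w <- within_ss(D2, y, G)
  if (w <= 0) stop_fmds("degenerate within-group dispersion")
  (tot / (G * w) - 1) * (n - G) / (G - 1)
}

# Pseudo-F for many labelings at once. perms: n x K matrix of permuted
# indices (labelings y[perms[,k]]). Vectorized through group-indicator
# matrix products.
pseudo_f_many <- function(D2, y, perms, G, tot = sum(D2)) {
  n <- nrow(D2)
  K <- ncol(perms)
  Y <- matrix(y[perms], n, K)
  w <- numeric(K)
  for (g in seq_len(G)) {
    M <- (Y == g) * 1
    w <- w + colSums(M * (D2 %*% M))
  }
  (tot / (G * w) - 1) * (n - G) / (G - 1)
}

#' PERMANOVA permutation test
#'
#' Draws `K` uniformly random label permutations (or, with
#' `exhaustive = TRUE` and `N <= 8`, enumerates all distinct labelings) and
#' compares the observed pseudo-F against the permutation distribution.
#'
#' @param D a `dist_matrix`.
#' @param y balanced group labels.
#' @param K number of permutations (default 999).
#' @param seed integer seed; the test is deterministic given the seed.
#' @param exhaustive enumerate all distinct label arrangements instead of
#'   sampling (small N only).
#' @param perms optional precomputed `N x K` permutation-index matrix
#'   (columns are permutations); overrides `K` and `seed`.
#' @return object of class `permanova_result` with fields `f_observed`,
#'   `f_permuted`, `p_value`, `K`, `seed`.
#' @export
permutation_test <- function(D, y, K = 999, seed = 1, exhaustive = FALSE,
                             perms = NULL) {
  D <- as_dist_matrix(D)
  y <- check_balanced(y)
  G <- attr(y, "G")
  n <- nrow(D)
  if (length(y) != n) stop_fmds("labels length != distance matrix size")
  D2 <- unclass(D)^2
  f_obs <- pseudo_f(D, y)
  if (exhaustive) {
    if (n > 8L) stop_fmds("exhaustive mode supported only for N <= 8")
    lab <- multiset_permutations(as.integer(y))
    fp <- vapply(seq_len(ncol(lab)), function(k) {
      w <- within_ss(D2, lab[, k], G)
      (sum(D2) / (G * w) - 1) * (n - G) / (G - 1)
    }, numeric(1))
    K <- ncol(lab)
  } else {
    if (K < 1L) stop_fmds("K must be >= 1")
    if (is.null(perms)) perms <- make_permutations(n, K, seed)
    K <- ncol(perms)
    fp <- pseudo_f_many(D2, as.integer(y), perms, G)
  }
  structure(list(f_observed = f_obs, f_permuted = fp,
                 p_value = mean(fp >= f_obs), K = K, seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA (balanced pseudo-F permutation test)\n")
  cat(sprintf("  F = %.6g, p = %.4g (K = %d permutations)\n",
              x$f_observed, x$p_value, x$K))
  invisible(x)
}

#' Paired permuted pseudo-F values in two spaces
#'
#' Applies the *same* label permutation to both the original distance
#' structure `D` and the Euclidean distances of the 2D embedding `Z`,
#' returning the two lists of permuted pseudo-F values in permutation
#' order (unsorted). This pairing underlies the F-scale mapping and the
#' F-correlation metric.
#'
#' @param D a `dist_matrix` (original space).
#' @param Z an `embedding`.
#' @param y balanced group labels.
#' @param K number of permutations.
#' @param seed integer seed.
#' @param perms optional precomputed permutation-index matrix.
#' @return list with components `f_x`, `f_z` (each length K) and
#'   `f_x_obs`, `f_z_obs` (observed statistics).
#' @export
paired_permuted_f <- function(D, Z, y, K = 999, seed = 1, perms = NULL) {
  D <- as_dist_matrix(D)
  Z <- as_embedding(Z)
  y <- check_balanced(y)
  G <- attr(y, "G")
  n <- nrow(D)
  if (ncol(Z) != n) stop_fmds("embedding size != distance matrix size")
  if (is.null(perms)) perms <- make_permutations(n, K, seed)
  Dz <- embed_dist(Z)
  D2x <- unclass(D)^2
  D2z <- Dz^2
  yi <- as.integer(y)
  list(f_x = pseudo_f_many(D2x, yi, perms, G),
       f_z = pseudo_f_many(D2z, yi, perms, G),
       f_x_obs = pseudo_f(D, y),
       f_z_obs = pseudo_f(dist_matrix(Dz, "euclidean"), y))
}
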