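# Embedding quality metrics: trustworthiness, continuity, Stress-1,
# Shepard correlation, F-correlation and F-rank-ratio.

# Rank matrix: rank[i, j] = position of j in the ascending distance
# ordering from i (excluding i, starting at 1, ties broken by index).
rank_matrix <- function(Dm) {
  n <- nrow(Dm)
  R <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    ord <- order(Dm[i, -i], seq_len(n - 1L))   # ties by index
    others <- seq_len(n)[-i]
    R[i, others[ord]] <- seq_len(n - 1L)
  }
  R
}

# Exact maximum achievable penalty sum_i sum_{j in worst U_k(i)} (r_ij - k):
# per point, the k embedded-neighbors can at worst be the k points with the
# largest original ranks (N-1, ..., N-k), of which only ranks > k
# contribute. Coincides with N * k(2N - 3k - 1)/2 (the printed normalizer)
# for k <= N/2.
max_penalty <- function(n, k) {
  m <- 0:(k - 1)
  n * sum(pmax(n - 1 - k - m, 0))
}

#' Trustworthiness and continuity of an embedding
#'
#' Rank-based preservation of k-nearest neighborhoods. Trustworthiness
#' penalizes points that enter the embedded neighborhood without being
#' original neighbors (penalty by original-space rank); continuity
#' penalizes original neighbors expelled from the embedded neighborhood
#' (penalty by embedded-space rank). The textbook normalizer
#' `2 / (N k (2N - 3k - 1))` is non-positive for `k >= (2N - 1)/3`; for
#' such k (used when evaluating global structure at k ~ 0.75 N) it is
#' replaced by the exact combinatorial maximum of the penalty so values
#' stay in `[0, 1]`. The raw textbook-normalized values are also returned.
#'
#' @param D_orig `dist_matrix` in the original space.
#' @param Z `embedding` (or `dist_matrix` of the embedded space).
#' @param k neighborhood size, `1 <= k < N`.
#' @return list with `trustworthiness`, `continuity` (bounded versions) and
#'   `trustworthiness_raw`, `continuity_raw` (textbook normalizer, `NA`
#'   when the normalizer is non-positive).
#' @export
trust_continuity <- function(D_orig, Z, k) {
  D_orig <- as_dist_matrix(D_orig)
  n <- nrow(D_orig)
  if (!(k >= 1 && k < n)) stop_fmds("k must satisfy 1 <= k < N")
  Dz <- if (inherits(Z, "dist_matrix")) unclass(Z) else embed_dist(as_embedding(Z))
  Dx <- unclass(D_orig)
  Rx <- rank_matrix(Dx)
  Rz <- rank_matrix(Dz)
  pen_t <- 0; pen_c <- 0
  for (i in seq_len(n)) {
    in_x <- Rx[i, ] >= 1 & Rx[i, ] <= k
    in_z <- Rz[i, ] >= 1 & Rz[i, ] <= k
    U <- which(in_z & !in_x)            # intruders in the embedding
    V <- which(in_x & !in_z)            # originals pushed out
    if (length(U)) pen_t <- pen_t + sum(Rx[i, U] - k)
    if (length(V)) pen_c <- pen_c + sum(Rz[i, V] - k)
  }
  norm_raw <- n * k * (2 * n - 3 * k - 1) / 2
  mp <- max_penalty(n, k)   # == norm_raw for k <= N/2; the exact bound beyond
  bounded <- function(pen) if (mp == 0) 1 else 1 - pen / mp
  list(trustworthiness = bounded(pen_t),
       continuity = bounded(pen_c),
       trustworthiness_raw = if (norm_raw > 0) 1 - pen_t / norm_raw else NA_real_,
       continuity_raw = if (norm_raw > 0) 1 - pen_c / norm_raw else NA_real_)
}

#' Stress-1 (normalized stress) of an embedding
#'
#' `sqrt( sum (d_ij - ||z_i - z_j||)^2 / sum ||z_i - z_j||^2 )` (Kruskal's
#' convention, with the square root). The raw squared ratio is available
#' via `stress1_sq()`.
#'
#' @param D a `dist_matrix`.
#' @param Z an `embedding`.
#' @return nonnegative scalar.
#' @export
stress1 <- function(D, Z) sqrt(stress1_sq(D, Z))

#' @rdname stress1
#' @export
stress1_sq <- function(D, Z) {
  D <- as_dist_matrix(D)
  Z <- as_embedding(Z)
  Dz <- embed_dist(Z)
  denom <- sum(Dz^2)
  if (denom <= 0) stop_fmds("degenerate configuration (all points coincident)")
  sum((unclass(D) - Dz)^2) / denom
}

#' Shepard diagram pairs and correlation
#'
#' One row per unordered pair `(d_ij, ||z_i - z_j||)`, plus the Pearson
#' correlation over all `N (N - 1) / 2` pairs.
#'
#' @param D a `dist_matrix`.
#' @param Z an `embedding`.
#' @return list with `pairs` (data frame: i, j, d_orig, d_embedded) and
#'   `pearson_r`.
#' @export
shepard <- function(D, Z) {
  D <- as_dist_matrix(D)
  Z <- as_embedding(Z)
  Dm <- unclass(D)
  Dz <- embed_dist(Z)
  n <- nrow(Dm)
  ut <- upper.tri(Dm)
  idx <- which(ut, arr.ind = TRUE)
  d0 <- Dm[ut]; d1 <- Dz[ut]
  if (stats::sd(d0) == 0 || stats::sd(d1) == 0)
    stop_fmds("correlation undefined (zero variance in pairwise distances)")
  list(pairs = data.frame(i = idx[, 1], j = idx[, 2],
                          d_orig = d0, d_embedded = d1),
       pearson_r = stats::cor(d0, d1))
}

#' F-correlation between original and embedded permutation F-values
#'
#' Pearson correlation of the K paired permuted pseudo-F values (same
#' permutation applied in both spaces).
#'
#' @param D a `dist_matrix`.
#' @param Z an `embedding`.
#' @param y balanced group labels.
#' @param K permutations (default 500).
#' @param seed integer seed.
#' @param perms optional precomputed permutation matrix.
#' @return correlation in `[-1, 1]`.
#' @export
f_correlation <- function(D, Z, y, K = 500, seed = 1, perms = NULL) {
  if (K < 3) stop_fmds("K must be >= 3")
  pf <- paired_permuted_f(D, Z, y, K = K, seed = seed, perms = perms)
  if (stats::sd(pf$f_x) == 0 || stats::sd(pf$f_z) == 0)
    stop_fmds("degenerate F distribution (zero variance)")
  stats::cor(pf$f_x, pf$f_z)
}

#' F-rank-ratio between embedded and original spaces
#'
#' `sum_k 1{F_z^Pi < F_z} / sum_k 1{F_x^Pi < F_x}` over a shared
#' permutation set; equals `(1 - p_z) / (1 - p_x)` up to the
#' strict-inequality convention. A value of 1 means the embedding
#' preserves the statistical significance of the group separation.
#'
#' @inheritParams f_correlation
#' @param K permutations (default 500).
#' @return positive scalar.
#' @export
f_rank_ratio <- function(D, Z, y, K = 500, seed = 1, perms = NULL) {
  pf <- paired_permuted_f(D, Z, y, K = K, seed = seed, perms = perms)
  den <- sum(pf$f_x < pf$f_x_obs)
  if (den == 0)
    stop_fmds("original-structure F at the bottom of its null (p_x = 1)")
  sum(pf$f_z < pf$f_z_obs) / den
}

#' Full quality report for an embedding
#'
#' Evaluates all six metrics. Neighborhood sizes default to ~8% and 75% of
#' the data size (local and global neighborhoods).
#'
#' @param D a `dist_matrix` of the original space.
#' @param Z an `embedding`.
#' @param y balanced group labels (needed for the F-based metrics; omit to
#'   skip them).
#' @param k_local,k_global neighborhood sizes; defaults `round(0.08 N)` and
#'   `round(0.75 N)` (clamped to `[1, N - 1]`).
#' @param K_f permutations for the F-based metrics (default 500).
#' @param seed integer seed (one shared permutation set for both F
#'   metrics).
#' @return list of class `quality_report`.
#' @export
evaluate_embedding <- function(D, Z, y = NULL,
                               k_local = NULL, k_global = NULL,
                               K_f = 500, seed = 1) {
  D <- as_dist_matrix(D)
  n <- nrow(D)
  clamp <- function(k) max(1L, min(n - 1L, as.integer(round(k))))
  if (is.null(k_local)) k_local <- clamp(0.08 * n) else k_local <- clamp(k_local)
  if (is.null(k_global)) k_global <- clamp(0.75 * n) else k_global <- clamp(k_global)
  tc_l <- trust_continuity(D, Z, k_local)
  tc_g <- trust_continuity(D, Z, k_global)
  out <- list(
    k_local = k_local, k_global = k_global,
    trustworthiness_local = tc_l$trustworthiness,
    continuity_local = tc_l$continuity,
    trustworthiness_global = tc_g$trustworthiness,
    continuity_global = tc_g$continuity,
    stress1 = stress1(D, Z),
    stress1_sq = stress1_sq(D, Z),
    shepard_r = shepard(D, Z)$pearson_r)
  if (!is.null(y)) {
    perms <- make_permutations(n, K_f, derive_seed(seed, "quality-f"))
    out$f_correlation <- f_correlation(D, Z, y, perms = perms)
    out$f_rank_ratio <- f_rank_ratio(D, Z, y, perms = perms)
  }
  structure(out, class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("Embedding quality report\n")
  cat(sprintf("  trustworthiness: %.4f (k=%d) / %.4f (k=%d)\n",
              x$trustworthiness_local, x$k_local,
              x$trustworthiness_global, x$k_global))
  cat(sprintf("  continuity:      %.4f (k=%d) / %.4f (k=%d)\n",
              x$continuity_local, x$k_local, x$continuity_global, x$k_global))
  cat(sprintf("  stress1 = %.4g, shepard_r = %.4f\n", x$stress1, x$shepard_r))
  if (!is.null(x$f_correlation))
    cat(sprintf("  f_correlation = %.4f, f_rank_ratio = %.4f\n",
                x$f_correlation, x$f_rank_ratio))
  invisible(x)
}
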