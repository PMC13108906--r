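# Classical scaling (PCoA), raw stress, SMACOF-style metric MDS with
# per-point (Gauss-Seidel) majorization sweeps, and the supervised-MDS
# baseline with a label-weighted confirmatory term.

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers `-0.5 * J D^2 J`, eigendecomposes, and returns the top
#' `dims` coordinates scaled by the square root of their (nonnegative)
#' eigenvalues. Axes are ordered by decreasing eigenvalue; the sign of each
#' axis is fixed so its first nonzero loading is positive. If fewer than
#' `dims` positive eigenvalues exist the remaining axes are zero-filled with
#' a warning.
#'
#' @param D a `dist_matrix`.
#' @param dims number of output dimensions (default 2).
#' @return an `embedding` (for `dims = 2`) carrying attribute
#'   `eigenvalues`; for other `dims`, a `dims x N` matrix.
#' @export
pcoa <- function(D, dims = 2) {
  D <- as_dist_matrix(D)
  n <- nrow(D)
  if (n < dims + 1L) stop_fmds("need N >= dims + 1")
  B <- unclass(D)^2
  B <- -0.5 * B
  rm_ <- rowMeans(B); gm <- mean(B)
  B <- B - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > max(1e-12, 1e-9 * abs(e$values[1]))
  npos <- sum(pos)
  take <- min(dims, npos)
  coords <- matrix(0, dims, n)
  for (a in seq_len(take)) {
    v <- e$vectors[, a] * sqrt(e$values[a])
    nz <- which(abs(v) > 1e-12)
    if (length(nz) && v[nz[1]] < 0) v <- -v
    coords[a, ] <- v
  }
  if (take < dims)
    warning(sprintf("only %d positive eigenvalue(s); axes %s zero-filled",
                    npos, paste((take + 1):dims, collapse = ",")))
  out <- if (dims == 2L) embedding(coords, sample_ids = rownames(D)) else coords
  attr(out, "eigenvalues") <- e$values
  out
}

#' Raw stress of an embedding
#'
#' `0.5 * sum_{i,j} (d_ij - ||z_i - z_j||)^2` over ordered pairs (i.e. the
#' plain sum over unordered pairs).
#'
#' @param D a `dist_matrix`.
#' @param Z an `embedding` with matching N.
#' @return nonnegative scalar.
#' @export
raw_stress <- function(D, Z) {
  D <- as_dist_matrix(D)
  Z <- as_embedding(Z)
  if (ncol(Z) != nrow(D)) stop_fmds("embedding size != distance matrix size")
  0.5 * sum((unclass(D) - embed_dist(Z))^2)
}

#' Embedding configuration for the iterative MDS solvers
#'
#' @param max_iter maximum sweeps (default 300).
#' @param tol relative objective decrease below which iteration stops
#'   (default 1e-6).
#' @param seed integer seed (used by callers that randomize).
#' @param alpha supervised-MDS balance hyperparameter in `[0, 1]`.
#' @return a list of class `embed_config`.
#' @export
embed_config <- function(max_iter = 300, tol = 1e-6, seed = 1, alpha = 0.5) {
  if (!(alpha >= 0 && alpha <= 1)) stop_fmds("alpha must lie in [0, 1]")
  if (!(tol > 0)) stop_fmds("tol must be positive")
  if (max_iter < 1) stop_fmds("max_iter must be >= 1")
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), alpha = alpha),
            class = "embed_config")
}

# One per-point Guttman sweep minimizing raw stress: for each k in turn,
# majorize the -d*||z_k - z_j|| cross terms at the current configuration
# (Cauchy-Schwarz) and solve the resulting quadratic exactly. Coincident
# pairs contribute nothing to the transform term (u_j = 0 convention).
# Updates are in place (Gauss-Seidel), which keeps the monotone-descent
# guarantee of majorization per point.
guttman_sweep <- function(Dm, zc) {
  n <- ncol(zc)
  for (k in seq_len(n)) {
    diff <- zc - zc[, k]              # 2 x n, z_j - z_k
    r <- sqrt(colSums(diff^2))
    u <- -diff                        # direction z_k - z_j
    ok <- r > 0
    u[, ok] <- u[, ok] / rep(r[ok], each = 2)
    u[, !ok] <- 0
    u[, k] <- 0
    zk <- (rowSums(zc[, -k, drop = FALSE]) +
             as.vector(u %*% Dm[, k])) / (n - 1)
    zc[, k] <- zk
  }
  zc
}

#' SMACOF-style metric MDS
#'
#' Iteratively refines an initial configuration by per-point majorization
#' sweeps of the raw stress; stress is non-increasing across sweeps and
#' iteration stops when its relative decrease falls below `cfg$tol` or
#' `cfg$max_iter` sweeps are reached.
#'
#' @param D a `dist_matrix`.
#' @param init initial `embedding` (e.g. from [pcoa()]).
#' @param cfg an [embed_config()].
#' @return an `embedding`, centered at the origin, with attribute
#'   `stress_trace` (per-sweep raw stress, starting at the initial value).
#' @export
smacof_metric_mds <- function(D, init, cfg = embed_config()) {
  D <- as_dist_matrix(D)
  Z <- as_embedding(init)
  Dm <- unclass(D)
  zc <- unclass(Z)
  if (max(apply(zc, 1, stats::sd)) == 0 && ncol(zc) > 1)
    stop_fmds("degenerate initialization: all points coincident")
  trace <- raw_stress(D, Z)
  for (it in seq_len(cfg$max_iter)) {
    zc <- guttman_sweep(Dm, zc)
    s <- 0.5 * sum((Dm - embed_dist(embedding(zc)))^2)
    trace <- c(trace, s)
    prev <- trace[length(trace) - 1L]
    if (prev - s < cfg$tol * max(prev, .Machine$double.eps)) break
  }
  zc <- zc - rowMeans(zc)
  out <- embedding(zc, sample_ids = colnames(Z))
  attr(out, "stress_trace") <- trace
  out
}

#' Metric MDS pipeline: PCoA initialization plus SMACOF refinement
#'
#' @param D a `dist_matrix`.
#' @param cfg an [embed_config()].
#' @param refine set `FALSE` to return the pure PCoA configuration.
#' @return an `embedding`.
#' @export
metric_mds <- function(D, cfg = embed_config(), refine = TRUE) {
  Z0 <- pcoa(D, dims = 2)
  if (!refine) return(Z0)
  smacof_metric_mds(D, Z0, cfg)
}

# ---- supervised MDS baseline ------------------------------------------------

# Objective: (1 - alpha) * raw_stress
#          + alpha * sum_{i,j: y_j > y_i} (y_j - y_i) *
#                    sum_{s=1,2} (d_ij^2 - t_ijs)^2
# where t_ijs = (z_js - z_is) by default (the printed benchmark form) or
# (z_js - z_is)^2 with squared_diff = TRUE.
supermds_objective <- function(Dm, zc, y, alpha, squared_diff = FALSE) {
  raw <- 0.5 * sum((Dm - embed_dist(embedding(zc)))^2)
  conf <- 0
  n <- ncol(zc)
  for (i in seq_len(n)) {
    jj <- which(y > y[i])
    if (!length(jj)) next
    w <- y[jj] - y[i]
    for (s in 1:2) {
      t_ <- zc[s, jj] - zc[s, i]
      if (squared_diff) t_ <- t_^2
      conf <- conf + sum(w * (Dm[i, jj]^2 - t_)^2)
    }
  }
  (1 - alpha) * raw + alpha * conf
}

#' Supervised MDS baseline
#'
#' Minimizes a convex combination of the raw stress and a label-weighted
#' confirmatory term that pulls signed coordinate differences of
#' cross-group pairs toward the squared original distances. Optimized by
#' per-point majorization sweeps from a metric-MDS initialization; with
#' `alpha = 0` it reduces to metric MDS.
#'
#' @param D a `dist_matrix`.
#' @param y group labels (ordinal; weights are `y_j - y_i` over pairs with
#'   `y_j > y_i`).
#' @param cfg an [embed_config()]; `cfg$alpha` balances the two terms.
#' @param squared_diff use the squared coordinate difference
#'   `(z_js - z_is)^2` inside the confirmatory term instead of the signed
#'   difference (non-default variant; optimized numerically).
#' @return an `embedding` with attribute `objective_trace`.
#' @export
supermds <- function(D, y, cfg = embed_config(), squared_diff = FALSE) {
  D <- as_dist_matrix(D)
  y <- group_labels(y)
  Dm <- unclass(D)
  n <- nrow(Dm)
  if (length(y) != n) stop_fmds("labels length != distance matrix size")
  alpha <- cfg$alpha
  Z <- metric_mds(D, cfg)
  zc <- unclass(Z)
  if (squared_diff) {
    # quartic confirmatory term: generic quasi-Newton on the full objective
    obj <- function(par) supermds_objective(Dm, matrix(par, 2, n), y, alpha,
                                            squared_diff = TRUE)
    opt <- stats::optim(as.vector(zc), obj, method = "BFGS",
                        control = list(maxit = cfg$max_iter))
    out <- embedding(matrix(opt$par, 2, n), sample_ids = colnames(Z))
    attr(out, "objective_trace") <- c(obj(as.vector(zc)), opt$value)
    return(out)
  }
  yi <- as.integer(y)
  D2 <- Dm^2
  trace <- supermds_objective(Dm, zc, yi, alpha)
  for (it in seq_len(cfg$max_iter)) {
    for (k in seq_len(n)) {
      diff <- zc - zc[, k]
      r <- sqrt(colSums(diff^2))
      u <- -diff
      ok <- r > 0
      u[, ok] <- u[, ok] / rep(r[ok], each = 2)
      u[, !ok] <- 0; u[, k] <- 0
      above <- which(yi > yi[k])   # pairs (k, j): y_j > y_k, term (d^2 - (z_j - z_k))^2
      below <- which(yi < yi[k])   # pairs (j, k): y_k > y_j, term (d^2 - (z_k - z_j))^2
      w_ab <- yi[above] - yi[k]
      w_be <- yi[k] - yi[below]
      A <- (1 - alpha) * (n - 1) + alpha * (sum(w_ab) + sum(w_be))
      if (A <= 0) stop_fmds("degenerate supermds update (zero weight)")
      for (s in 1:2) {
        rhs <- (1 - alpha) * (sum(zc[s, -k]) + sum(Dm[, k] * u[s, ])) +
          alpha * (sum(w_ab * (zc[s, above] - D2[k, above])) +
                     sum(w_be * (zc[s, below] + D2[k, below])))
        zc[s, k] <- rhs / A
      }
    }
    o <- supermds_objective(Dm, zc, yi, alpha)
    trace <- c(trace, o)
    prev <- trace[length(trace) - 1L]
    if (prev - o < cfg$tol * max(abs(prev), .Machine$double.eps)) break
  }
  zc <- zc - rowMeans(zc)
  out <- embedding(zc, sample_ids = colnames(Z))
  attr(out, "objective_trace") <- trace
  out
}
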