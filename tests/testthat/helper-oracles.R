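# Shared fixtures and independent oracles. Oracles are deliberately naive
# (loops, enumeration, generic optimizers) and never call the code paths
# they check.

# ---- toy fixtures -----------------------------------------------------------

# 4-point distance matrix: within-group pairs at 1, between at 2.
toy_within1_between2 <- function() {
  D <- matrix(2, 4, 4) - diag(2, 4)
  D[1, 2] <- D[2, 1] <- 1
  D[3, 4] <- D[4, 3] <- 1
  dist_matrix(D)
}

unit_square <- function() rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))

# Small balanced binary semisynthetic dataset from the frozen fixture.
small_binary <- function(n_per_group = 20, seed = 1) {
  sim <- simulate_microbiome(
    simulation_spec(n_per_group, 2, seed = seed, scheme = "binary"))
  sim$D <- bray_curtis(sim$table)
  sim
}

# Random 2D point cloud and its exact Euclidean distance structure.
random_planar <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(rnorm(2 * n), n, 2)
  list(pts = pts, D = euclidean_pairwise(pts),
       Z = embedding(t(pts)))
}

# ---- oracles ----------------------------------------------------------------

# Classical one-way ANOVA F for univariate data.
anova_f_oracle <- function(x, y) {
  fit <- stats::lm(x ~ factor(y))
  stats::anova(fit)$`F value`[1]
}

# One sequential per-point Guttman sweep of metric MDS (raw stress
# majorization), written as plain loops.
guttman_sweep_oracle <- function(Dm, zc) {
  n <- ncol(zc)
  for (k in seq_len(n)) {
    acc <- c(0, 0)
    for (j in seq_len(n)) {
      if (j == k) next
      r <- sqrt(sum((zc[, k] - zc[, j])^2))
      u <- if (r > 0) (zc[, k] - zc[, j]) / r else c(0, 0)
      acc <- acc + zc[, j] + Dm[k, j] * u
    }
    zc[, k] <- acc / (n - 1)
  }
  zc
}

# Exhaustive pseudo-F permutation distribution over all distinct labelings.
exhaustive_f_oracle <- function(Dm, y) {
  G <- max(y)
  n <- length(y)
  perm_all <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      if (i > 1 && v[i] %in% v[seq_len(i - 1)]) next
      for (rest in perm_all(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  vapply(perm_all(sort(y)), function(lab) {
    D2 <- Dm^2
    w <- 0
    for (g in seq_len(G)) {
      idx <- which(lab == g)
      w <- w + sum(D2[idx, idx])
    }
    (sum(D2) / (G * w) - 1) * (n - G) / (G - 1)
  }, numeric(1))
}

# Naive trustworthiness/continuity straight from the definition, using the
# bounded normalizer (exact maximum penalty) when the textbook one is
# non-positive.
trust_cont_oracle <- function(Dx, Dz, k) {
  n <- nrow(Dx)
  ranks_from <- function(D, i) {
    ord <- order(D[i, -i], seq_len(n - 1))
    r <- integer(n)
    r[(seq_len(n)[-i])[ord]] <- seq_len(n - 1)
    r
  }
  pen_t <- 0; pen_c <- 0
  for (i in seq_len(n)) {
    rx <- ranks_from(Dx, i); rz <- ranks_from(Dz, i)
    Ck  <- which(rx >= 1 & rx <= k)
    Ckh <- which(rz >= 1 & rz <= k)
    for (j in setdiff(Ckh, Ck)) pen_t <- pen_t + rx[j] - k
    for (j in setdiff(Ck, Ckh)) pen_c <- pen_c + rz[j] - k
  }
  maxpen <- n * sum(pmax(n - 1 - k - 0:(k - 1), 0))
  if (maxpen == 0) return(c(trust = 1, cont = 1))
  c(trust = 1 - pen_t / maxpen, cont = 1 - pen_c / maxpen)
}

# Per-point F-MDS surrogate at point k, written out explicitly from its
# definition: quadratic pieces for positive pair weights, tangent
# linearization for negative ones, Cauchy-Schwarz linearization of the
# raw-stress cross term. Minimized numerically by optim.
surrogate_min_oracle <- function(Dm, zc0, y, lam, fx_target, delta, k) {
  n <- ncol(zc0)
  G <- max(y)
  cw <- function(i, j) {
    eps <- as.numeric(y[i] == y[j])
    1 - G * eps * (1 + (G - 1) / (n - G) * fx_target)
  }
  g <- function(zk) {
    val <- 0
    for (j in seq_len(n)) {
      if (j == k) next
      r0 <- sqrt(sum((zc0[, k] - zc0[, j])^2))
      u <- if (r0 > 0) (zc0[, k] - zc0[, j]) / r0 else c(0, 0)
      q <- sum((zk - zc0[, j])^2)
      Aj <- 1 / n + lam * delta * cw(k, j)
      if (Aj >= 0) {
        val <- val + Aj * q
      } else {
        q0 <- sum((zc0[, k] - zc0[, j])^2)
        val <- val + Aj * (q0 + 2 * sum((zc0[, k] - zc0[, j]) * (zk - zc0[, k])))
      }
      val <- val - (2 / n) * Dm[k, j] * sum((zk - zc0[, j]) * u)
    }
    val
  }
  stats::optim(zc0[, k], g, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))$par
}

# Procrustes residual after optimal translation/rotation/reflection.
procrustes_resid <- function(A, B) {
  A <- scale(A, scale = FALSE); B <- scale(B, scale = FALSE)
  s <- svd(t(B) %*% A)
  R <- s$u %*% t(s$v)
  sqrt(sum((B %*% R - A)^2))
}
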