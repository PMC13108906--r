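# F-informed MDS: perturb a metric-MDS embedding until the PERMANOVA
# p-value computed on the 2D Euclidean distances matches the p-value of the
# original distance structure.
#
# Objective (exact form used by the majorizer):
#
#   O(Z) = (1/N) sum_{i,j} (d_ij - ||z_i - z_j||)^2
#        + lambda * | sum_{i,j} c_ij ||z_i - z_j||^2 |
#
#   c_ij = 1 - G * eps_ij * (1 + (G-1)/(N-G) * f_target)
#
# where f_target = f_z(F_x) maps the observed original-space pseudo-F onto
# the embedding's F scale through a monotone local regression fitted on
# paired, sorted permuted pseudo-F values. Algebraically the bracketed sum
# equals G * W_z * (G-1)/(N-G) * (F_z - f_target) with W_z the within-group
# sum of squared embedded distances, so the confirmatory term vanishes
# exactly when the embedding's pseudo-F hits the target.

#' Configuration for F-informed MDS
#'
#' @param lam hyperparameter `lambda` in `(0, 1]` balancing raw stress and
#'   the confirmatory term; values above 1 can break the convexity of the
#'   per-point majorizer and are rejected.
#' @param K_map permutations used to fit the F-scale mapping (default 999).
#' @param K_p permutations used for p-value tracking (default 999).
#' @param stop_band half-width of the stopping band on `|p_z - p_x|`
#'   (default 0.05).
#' @param px_gate run the perturbation only when `p_x < px_gate`
#'   (default 0.1).
#' @param run_gate run only when `p_z - p_x > run_gate` (default 0.05).
#' @param max_epochs hard cap on majorization epochs (default 100).
#' @param seed integer seed for the shared permutation set.
#' @param refit_per_point refit the F-scale mapping before every per-point
#'   update instead of once per epoch (faithful but disproportionately
#'   expensive; default FALSE).
#' @param literal_stop use the literal disjunctive while-condition
#'   (continue while out of band OR still improving) instead of stopping at
#'   first entry into the band (default FALSE).
#' @return a list of class `fmds_config`.
#' @export
fmds_config <- function(lam = 0.5, K_map = 999, K_p = 999, stop_band = 0.05,
                        px_gate = 0.1, run_gate = 0.05, max_epochs = 100,
                        seed = 1, refit_per_point = FALSE,
                        literal_stop = FALSE) {
  if (!(lam > 0 && lam <= 1)) stop_fmds("lambda must lie in (0, 1]")
  if (!(stop_band > 0)) stop_fmds("stop_band must be positive")
  if (max_epochs < 1) stop_fmds("max_epochs must be >= 1")
  if (K_map < 10) stop_fmds("K_map must be >= 10")
  structure(list(lam = lam, K_map = as.integer(K_map), K_p = as.integer(K_p),
                 stop_band = stop_band, px_gate = px_gate,
                 run_gate = run_gate, max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed),
                 refit_per_point = isTRUE(refit_per_point),
                 literal_stop = isTRUE(literal_stop)),
            class = "fmds_config")
}

# ---- F-scale mapping --------------------------------------------------------

#' Fit the monotone F-scale mapping between original and embedded pseudo-F
#'
#' Computes paired permuted pseudo-F values in the original and embedded
#' spaces (same permutation per pair), sorts each list ascending
#' independently, and fits a local (loess, span 0.75, degree 1) regression
#' of the sorted embedded values on the sorted original values. Fitted
#' values are made monotone non-decreasing by isotonic post-adjustment;
#' outside the fitted range the mapping extrapolates linearly from the end
#' segments.
#'
#' @param D a `dist_matrix`.
#' @param Z an `embedding`.
#' @param y balanced group labels.
#' @param K permutations (>= 10).
#' @param seed integer seed.
#' @param perms optional precomputed permutation matrix.
#' @param f_x optional precomputed permuted pseudo-F values for `D`
#'   (avoids recomputation across epochs, `D` being fixed).
#' @return object of class `f_mapping` with fields `sorted_fx`,
#'   `sorted_fz`, and `fitted`; evaluate with [predict_f_mapping()].
#' @export
fit_fz_mapping <- function(D, Z, y, K = 999, seed = 1, perms = NULL,
                           f_x = NULL) {
  if (K < 10) stop_fmds("K must be >= 10")
  if (is.null(perms)) perms <- make_permutations(nrow(as_dist_matrix(D)), K, seed)
  if (is.null(f_x)) {
    pf <- paired_permuted_f(D, Z, y, perms = perms)
    f_x <- pf$f_x; f_z <- pf$f_z
  } else {
    y <- check_balanced(y)
    f_z <- pseudo_f_many(embed_dist(Z)^2, as.integer(y), perms, attr(y, "G"))
  }
  new_f_mapping(sort(f_x), sort(f_z))
}

new_f_mapping <- function(sx, sz) {
  if (diff(range(sx)) <= .Machine$double.eps * max(abs(sx), 1))
    stop_fmds("degenerate F distribution (all permuted F identical)")
  fit <- suppressWarnings(
    stats::loess(sz ~ sx, data = data.frame(sx = sx, sz = sz),
                 span = 0.75, degree = 1,
                 control = stats::loess.control(surface = "direct")))
  fitted <- stats::predict(fit, newdata = data.frame(sx = sx))
  fitted <- stats::isoreg(sx, fitted)$yf   # enforce monotone non-decreasing
  structure(list(sorted_fx = sx, sorted_fz = sz, fitted = fitted),
            class = "f_mapping")
}

#' Evaluate an F-scale mapping
#'
#' Piecewise-linear interpolation of the monotone fitted values; linear
#' extrapolation from the end segments outside the fitted range.
#'
#' @param mapping an `f_mapping` from [fit_fz_mapping()].
#' @param x numeric values on the original F scale.
#' @return mapped values on the embedding F scale.
#' @export
predict_f_mapping <- function(mapping, x) {
  sx <- mapping$sorted_fx; fy <- mapping$fitted
  keep <- !duplicated(sx)
  sx <- sx[keep]; fy <- fy[keep]
  if (length(sx) < 2L) return(rep(fy[1], length(x)))
  out <- stats::approx(sx, fy, xout = x, rule = 2, ties = "ordered")$y
  lo <- x < sx[1]; hi <- x > sx[length(sx)]
  if (any(lo)) {
    s <- (fy[2] - fy[1]) / (sx[2] - sx[1])
    out[lo] <- fy[1] + s * (x[lo] - sx[1])
  }
  if (any(hi)) {
    m <- length(sx)
    s <- (fy[m] - fy[m - 1]) / (sx[m] - sx[m - 1])
    out[hi] <- fy[m] + s * (x[hi] - sx[m])
  }
  out
}

# ---- objective --------------------------------------------------------------

# Pair weights c_ij for the confirmatory term.
conf_weights <- function(y, fx_target) {
  y <- check_balanced(y)
  G <- attr(y, "G")
  n <- length(y)
  eps <- outer(y, y, "==") * 1
  1 - G * eps * (1 + (G - 1) / (n - G) * fx_target)
}

#' F-informed MDS objective
#'
#' @param D a `dist_matrix`.
#' @param Z an `embedding`.
#' @param y balanced group labels.
#' @param lam hyperparameter lambda.
#' @param fx_target mapped target `f_z(F_x)` on the embedding F scale.
#' @return list with `raw_term` (`(1/N) sum (d - ||.||)^2`), `conf_term`
#'   (absolute value of the weighted sum of squared embedded distances),
#'   `conf_signed` (the argument before taking the absolute value),
#'   `total = raw_term + lam * conf_term`, and `delta` (sign of the
#'   confirmatory argument, `+1`, `-1` or `0`).
#' @export
fmds_objective <- function(D, Z, y, lam, fx_target) {
  D <- as_dist_matrix(D)
  Z <- as_embedding(Z)
  n <- nrow(D)
  if (ncol(Z) != n) stop_fmds("embedding size != distance matrix size")
  Dz <- embed_dist(Z)
  raw <- sum((unclass(D) - Dz)^2) / n
  C <- conf_weights(y, fx_target)
  arg <- sum(C * Dz^2)
  list(raw_term = raw, conf_term = abs(arg), conf_signed = arg,
       total = raw + lam * abs(arg), delta = sign(arg))
}

# ---- majorization -----------------------------------------------------------

# Per-point surrogate pieces for point k. The terms of the delta-fixed
# objective that involve z_k are
#
#   sum_j (2/n) (d_kj - ||z_k - z_j||)^2 + 2 lam delta sum_j c_kj ||z_k - z_j||^2
#
# The raw-stress cross term -2 d ||z_k - z_j|| is majorized by its
# Cauchy-Schwarz linearization at the current point; collecting quadratic
# weights gives A_j = 1/n + lam * delta * c_kj per pair. Pairs with
# negative A_j make their quadratic piece concave in z_k, so those pieces
# are majorized by their tangent at the current configuration (the standard
# treatment of negative weights in SMACOF); the surrogate then stays a
# convex quadratic whose minimizer is closed-form.
point_update <- function(Dm, zc, C, lam, delta, k, n) {
  diff <- zc - zc[, k]
  r <- sqrt(colSums(diff^2))
  u <- -diff
  ok <- r > 0
  u[, ok] <- u[, ok] / rep(r[ok], each = 2)
  u[, !ok] <- 0; u[, k] <- 0
  Aj <- 1 / n + lam * delta * C[k, ]
  Aj[k] <- 0
  S_pos <- sum(Aj[Aj > 0])
  if (S_pos <= 0) stop_fmds("majorizer not convex; reduce lambda")
  S_neg <- sum(Aj[Aj < 0])
  (as.vector(zc %*% Aj) - zc[, k] * S_neg +
     as.vector(u %*% Dm[, k]) / n) / S_pos
}

#' One majorization epoch of F-informed MDS
#'
#' Performs one full sweep `k = 1..N` of per-point updates. For each point
#' the raw-stress cross term is majorized by its Cauchy-Schwarz
#' linearization at the current configuration; the confirmatory term (with
#' the absolute value replaced by `delta` times its argument) is quadratic
#' in `z_k`, and any concave per-pair pieces (negative quadratic weight,
#' which arise when `delta` opposes a pair's confirmatory weight) are
#' tangent-majorized. The resulting convex quadratic surrogate is minimized
#' in closed form per coordinate; a positive quadratic coefficient is
#' asserted at every update.
#'
#' @param D a `dist_matrix`.
#' @param Z current `embedding`.
#' @param y balanced group labels.
#' @param lam hyperparameter lambda (`0 <= lam <= 1`; `lam = 0` reproduces
#'   one metric-MDS Guttman sweep).
#' @param fx_target mapped target `f_z(F_x)`.
#' @param delta sign of the confirmatory argument, held fixed during the
#'   sweep so the surrogate stays quadratic.
#' @return updated `embedding`.
#' @export
majorization_epoch <- function(D, Z, y, lam, fx_target, delta) {
  D <- as_dist_matrix(D)
  Z <- as_embedding(Z)
  n <- nrow(D)
  if (ncol(Z) != n) stop_fmds("embedding size != distance matrix size")
  if (lam < 0 || lam > 1) stop_fmds("lambda must lie in [0, 1] for the majorizer")
  Dm <- unclass(D)
  zc <- unclass(Z)
  C <- conf_weights(y, fx_target)
  for (k in seq_len(n)) {
    zc[, k] <- point_update(Dm, zc, C, lam, delta, k, n)
  }
  embedding(zc, sample_ids = colnames(Z))
}

# ---- full algorithm ---------------------------------------------------------

#' F-informed multidimensional scaling
#'
#' Initializes a 2D configuration by metric MDS (PCoA + SMACOF refinement),
#' then — only when the group difference is significant in the original
#' structure (`p_x < px_gate`) but lost in 2D (`p_z - p_x > run_gate`) —
#' iteratively perturbs the configuration by majorization epochs until the
#' 2D PERMANOVA p-value enters the stopping band `|p_z - p_x| < stop_band`.
#' One fixed, seeded permutation set is shared by all p-value evaluations
#' and mapping fits for the whole run, so changes in `p_z` reflect changes
#' in the configuration rather than permutation noise.
#'
#' @param D a `dist_matrix` of original-space dissimilarities.
#' @param y balanced group labels.
#' @param cfg an [fmds_config()].
#' @param init optional initial `embedding`; defaults to [metric_mds()].
#' @return object of class `fmds_result`: list with `embedding` (the
#'   best-so-far configuration at termination), `trace` (per-epoch data
#'   frame: raw term, confirmatory term, total objective, delta, p_z),
#'   `mapping` (last fitted `f_mapping`, or NULL if gated out), `p_x`,
#'   `p_z`, `converged`, `epochs_used`, and `config`.
#' @export
fmds <- function(D, y, cfg = fmds_config(), init = NULL) {
  D <- as_dist_matrix(D)
  y <- check_balanced(y)
  G <- attr(y, "G")
  n <- nrow(D)
  if (length(y) != n) stop_fmds("labels length != distance matrix size")
  yi <- as.integer(y)
  Kshare <- max(cfg$K_map, cfg$K_p)
  perms <- make_permutations(n, Kshare, derive_seed(cfg$seed, "fmds-perms"))
  perms_p <- perms[, seq_len(cfg$K_p), drop = FALSE]
  perms_map <- perms[, seq_len(cfg$K_map), drop = FALSE]
  D2x <- unclass(D)^2
  f_x_obs <- pseudo_f(D, y)
  f_x_perm_p <- pseudo_f_many(D2x, yi, perms_p, G)
  f_x_perm_map <- pseudo_f_many(D2x, yi, perms_map, G)
  p_x <- mean(f_x_perm_p >= f_x_obs)

  Z <- if (is.null(init)) metric_mds(D, embed_config(seed = cfg$seed))
       else as_embedding(init)
  p_z_of <- function(Z) {
    D2z <- embed_dist(Z)^2
    fz <- pseudo_f_many(D2z, yi, perms_p, G)
    fz_obs <- pseudo_f(dist_matrix(sqrt(D2z), "euclidean"), y)
    mean(fz >= fz_obs)
  }
  p_z <- p_z_of(Z)

  trace <- data.frame(epoch = integer(), raw_term = numeric(),
                      conf_term = numeric(), total = numeric(),
                      delta = numeric(), p_z = numeric())
  if (!(p_x < cfg$px_gate && p_z - p_x > cfg$run_gate)) {
    return(structure(list(embedding = Z, trace = trace, mapping = NULL,
                          p_x = p_x, p_z = p_z, converged = TRUE,
                          epochs_used = 0L, config = cfg),
                     class = "fmds_result"))
  }

  best_Z <- Z; best_gap <- abs(p_z - p_x)
  mapping <- NULL
  converged <- FALSE
  epochs <- 0L
  gap_old <- Inf
  for (epoch in seq_len(cfg$max_epochs)) {
    epochs <- epoch
    mapping <- fit_fz_mapping(D, Z, y, K = cfg$K_map, perms = perms_map,
                              f_x = f_x_perm_map)
    fx_target <- predict_f_mapping(mapping, f_x_obs)
    ob <- fmds_objective(D, Z, y, cfg$lam, fx_target)
    delta <- if (ob$delta == 0) 1 else ob$delta
    if (cfg$refit_per_point) {
      zc <- Z
      for (k in seq_len(n)) {
        mapping <- fit_fz_mapping(D, zc, y, K = cfg$K_map, perms = perms_map,
                                  f_x = f_x_perm_map)
        fx_target <- predict_f_mapping(mapping, f_x_obs)
        zc <- majorization_single(D, zc, y, cfg$lam, fx_target, delta, k)
      }
      Z <- zc
    } else {
      Z <- majorization_epoch(D, Z, y, cfg$lam, fx_target, delta)
    }
    p_z <- p_z_of(Z)
    ob_after <- fmds_objective(D, Z, y, cfg$lam, fx_target)
    trace <- rbind(trace, data.frame(epoch = epoch,
                                     raw_term = ob_after$raw_term,
                                     conf_term = ob_after$conf_term,
                                     total = ob_after$total,
                                     delta = delta, p_z = p_z))
    gap <- abs(p_z - p_x)
    if (gap < best_gap) { best_gap <- gap; best_Z <- Z }
    if (cfg$literal_stop) {
      if (!(gap > cfg$stop_band || gap < gap_old)) { converged <- gap <= cfg$stop_band; break }
    } else if (gap < cfg$stop_band) {
      converged <- TRUE
      break
    }
    gap_old <- gap
  }
  final_Z <- if (converged) Z else best_Z
  final_p_z <- if (converged) p_z else p_z_of(best_Z)
  structure(list(embedding = final_Z, trace = trace, mapping = mapping,
                 p_x = p_x, p_z = final_p_z, converged = converged,
                 epochs_used = epochs, config = cfg),
            class = "fmds_result")
}

# Per-point variant used by the refit-per-point cadence: update only point k.
majorization_single <- function(D, Z, y, lam, fx_target, delta, k) {
  D <- as_dist_matrix(D)
  Z <- as_embedding(Z)
  n <- nrow(D)
  Dm <- unclass(D)
  zc <- unclass(Z)
  C <- conf_weights(y, fx_target)
  zc[, k] <- point_update(Dm, zc, C, lam, delta, k, n)
  embedding(zc, sample_ids = colnames(Z))
}

#' @export
print.fmds_result <- function(x, ...) {
  cat("F-informed MDS result\n")
  cat(sprintf("  p_x = %.4g, p_z = %.4g, converged = %s, epochs = %d\n",
              x$p_x, x$p_z, x$converged, x$epochs_used))
  invisible(x)
}

# ---- lambda selection -------------------------------------------------------

#' Grid search for the hyperparameter lambda
#'
#' Runs [fmds()] at every lambda in `grid`, records epochs to termination,
#' Stress-1, and Shepard correlation, min-max normalizes each diagnostic to
#' `[0, 1]` across the grid (correlation inverted so that smaller is
#' better), and returns the lambda minimizing their sum. Ties are broken
#' toward larger lambda.
#'
#' @param D a `dist_matrix`.
#' @param y balanced group labels.
#' @param grid numeric vector of candidate lambdas within `[0.15, 1]`.
#' @param cfg an [fmds_config()] supplying all other settings.
#' @return list with `lambda_star` and `table` (per-lambda diagnostics,
#'   normalized components, and `f_obj`).
#' @export
tune_lambda <- function(D, y, grid, cfg = fmds_config()) {
  if (any(grid < 0.15 - 1e-12) || any(grid > 1 + 1e-12))
    stop_fmds("lambda grid must lie within [0.15, 1]")
  D <- as_dist_matrix(D)
  rows <- lapply(grid, function(l) {
    cfg_l <- cfg; cfg_l$lam <- l
    fit <- fmds(D, y, cfg_l)
    data.frame(lambda = l, epochs = fit$epochs_used,
               stress1 = stress1(D, fit$embedding),
               shepard_r = shepard(D, fit$embedding)$pearson_r,
               converged = fit$converged)
  })
  tab <- do.call(rbind, rows)
  mm <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) rep(0, length(v)) else (v - rng[1]) / diff(rng)
  }
  if (length(grid) == 1L) {
    warning("single-value grid: min-max normalization is degenerate")
    tab$n_epochs <- 0; tab$n_stress1 <- 0; tab$n_corr <- 0; tab$f_obj <- 0
    return(list(lambda_star = grid[1], table = tab))
  }
  tab$n_epochs <- mm(tab$epochs)
  tab$n_stress1 <- mm(tab$stress1)
  tab$n_corr <- mm(-tab$shepard_r)     # invert: larger correlation is better
  tab$f_obj <- tab$n_epochs + tab$n_stress1 + tab$n_corr
  best <- which(tab$f_obj == min(tab$f_obj))
  lambda_star <- max(tab$lambda[best])  # ties toward larger lambda
  list(lambda_star = lambda_star, table = tab)
}
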