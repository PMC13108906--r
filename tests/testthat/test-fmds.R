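test_that("fmds_config enforces the lambda cap and other invariants", {
  expect_error(fmds_config(lam = 1.2), "lambda")
  expect_error(fmds_config(lam = 0), "lambda")
  expect_error(fmds_config(stop_band = 0), "stop_band")
  expect_error(fmds_config(max_epochs = 0), "max_epochs")
  expect_error(fmds_config(K_map = 5), "K_map")
})

test_that("the F-scale mapping is the identity for (scaled) isometries", {
  pl <- random_planar(12, seed = 6)
  y <- rep(1:2, each = 6)
  map <- fit_fz_mapping(pl$D, pl$Z, y, K = 200, seed = 3)
  grid <- seq(min(map$sorted_fx), max(map$sorted_fx), length.out = 50)
  expect_equal(predict_f_mapping(map, grid), grid, tolerance = 1e-6)
  # pseudo-F is scale invariant, so a scaled isometry maps identically
  map2 <- fit_fz_mapping(pl$D, embedding(3.7 * unclass(pl$Z)), y,
                         K = 200, seed = 3)
  expect_equal(predict_f_mapping(map2, grid), grid, tolerance = 1e-6)
})

test_that("the fitted mapping is monotone non-decreasing on its range", {
  for (s in 1:3) {
    sim <- small_binary(8, seed = s)
    Z <- metric_mds(sim$D)
    map <- fit_fz_mapping(sim$D, Z, sim$labels, K = 150, seed = s)
    grid <- seq(min(map$sorted_fx), max(map$sorted_fx), length.out = 200)
    expect_true(all(diff(predict_f_mapping(map, grid)) >= -1e-12))
  }
})

test_that("a degenerate permuted-F distribution is rejected", {
  Deq <- dist_matrix(matrix(1, 6, 6) - diag(6))
  y <- rep(1:2, each = 3)
  Z <- embedding(matrix(rnorm(12), 2, 6))
  expect_error(fit_fz_mapping(Deq, Z, y, K = 50, seed = 1),
               "degenerate F distribution")
})

test_that("fmds_objective terms vanish and compose as specified", {
  pl <- random_planar(10, seed = 8)
  y <- rep(1:2, each = 5)
  fx <- pseudo_f(pl$D, y)
  # perfect isometry with the observed F as target: both terms zero
  ob <- fmds_objective(pl$D, pl$Z, y, lam = 0.7, fx_target = fx)
  expect_equal(ob$raw_term, 0, tolerance = 1e-9)
  expect_equal(ob$conf_term, 0, tolerance = 1e-6)
  # conf term vanishes exactly when F_z equals the target
  sim <- small_binary(6, seed = 2)
  Z <- metric_mds(sim$D)
  fz <- pseudo_f(euclidean_pairwise(Z), sim$labels)
  ob2 <- fmds_objective(sim$D, Z, sim$labels, lam = 0.5, fx_target = fz)
  expect_equal(ob2$conf_term, 0, tolerance = 1e-8 * sum(unclass(sim$D)^2))
  # and is nonzero for a different target, with delta = sign(F_z - target)
  ob3 <- fmds_objective(sim$D, Z, sim$labels, lam = 0.5, fx_target = fz + 1)
  expect_gt(ob3$conf_term, 0)
  expect_equal(ob3$delta, -1)
  ob4 <- fmds_objective(sim$D, Z, sim$labels, lam = 0.5, fx_target = fz - 0.5)
  expect_equal(ob4$delta, 1)
  # lam = 0 collapses the total onto the raw term
  ob5 <- fmds_objective(sim$D, Z, sim$labels, lam = 0, fx_target = fz + 1)
  expect_equal(ob5$total, ob5$raw_term)
})

test_that("majorization epoch at lambda 0 equals a metric-MDS Guttman sweep", {
  D <- small_binary(3, seed = 7)$D
  set.seed(2)
  zc <- matrix(rnorm(12), 2, 6)
  Z1 <- majorization_epoch(D, embedding(zc), rep(1:2, each = 3),
                           lam = 0, fx_target = 1, delta = 1)
  oracle <- guttman_sweep_oracle(unclass(D), zc)
  expect_equal(unclass(Z1), oracle, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("per-point update minimizes the explicit surrogate (numeric oracle)", {
  D <- toy_within1_between2()
  y <- c(1, 1, 2, 2)
  set.seed(5)
  for (case in list(list(lam = 0.3, fx = 0.5, delta = 1),
                    list(lam = 0.3, fx = 2.0, delta = -1),
                    list(lam = 1.0, fx = 3.0, delta = -1))) {
    zc0 <- matrix(rnorm(8), 2, 4)
    for (k in 1:4) {
      ours <- fimds:::majorization_single(D, embedding(zc0), y, case$lam,
                                          case$fx, case$delta, k)
      ref <- surrogate_min_oracle(unclass(D), zc0, y, case$lam, case$fx,
                                  case$delta, k)
      expect_equal(unclass(ours)[, k], ref, tolerance = 1e-6,
                   ignore_attr = TRUE)
    }
  }
})

test_that("an epoch never increases the delta-fixed objective", {
  sim <- small_binary(10, seed = 3)
  Z <- metric_mds(sim$D)
  fx <- pseudo_f(sim$D, sim$labels)
  map <- fit_fz_mapping(sim$D, Z, sim$labels, K = 150, seed = 4)
  tgt <- predict_f_mapping(map, fx)
  for (lam in c(0.2, 0.6, 1.0)) {
    ob0 <- fmds_objective(sim$D, Z, sim$labels, lam, tgt)
    delta <- if (ob0$delta == 0) 1 else ob0$delta
    Z1 <- majorization_epoch(sim$D, Z, sim$labels, lam, tgt, delta)
    ob1 <- fmds_objective(sim$D, Z1, sim$labels, lam, tgt)
    before <- ob0$raw_term + lam * delta * ob0$conf_signed
    after <- ob1$raw_term + lam * delta * ob1$conf_signed
    expect_lte(after, before + 1e-9 * max(1, abs(before)))
  }
})

test_that("gating returns the metric-MDS embedding bit-for-bit", {
  # well-separated planar blobs: p_z tracks p_x closely, no perturbation
  set.seed(12)
  pts <- rbind(matrix(rnorm(30, 0), 15, 2), matrix(rnorm(30, 8), 15, 2))
  D <- euclidean_pairwise(pts)
  y <- rep(1:2, each = 15)
  cfg <- fmds_config(lam = 0.5, K_map = 99, K_p = 99, seed = 9)
  fit <- fmds(D, y, cfg)
  expect_true(fit$converged)
  expect_identical(fit$epochs_used, 0L)
  Z0 <- metric_mds(D, embed_config(seed = cfg$seed))
  expect_identical(unclass(fit$embedding), unclass(Z0))
})

test_that("fmds is deterministic and converges on the binary fixture", {
  sim <- small_binary(30, seed = 1)
  cfg <- fmds_config(lam = 0.5, K_map = 199, K_p = 199, seed = 5,
                     max_epochs = 40)
  f1 <- fmds(sim$D, sim$labels, cfg)
  f2 <- fmds(sim$D, sim$labels, cfg)
  expect_identical(unclass(f1$embedding), unclass(f2$embedding))
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$p_z, f2$p_z)
  if (f1$p_x < cfg$px_gate && f1$epochs_used > 0 && f1$converged) {
    expect_lt(abs(f1$p_z - f1$p_x), cfg$stop_band)
  }
})

test_that("tune_lambda normalizes diagnostics and recomputes f_obj", {
  sim <- small_binary(15, seed = 2)
  cfg <- fmds_config(K_map = 99, K_p = 99, seed = 3, max_epochs = 20)
  res <- tune_lambda(sim$D, sim$labels, c(0.2, 0.5, 1.0), cfg)
  tab <- res$table
  for (col in c("n_epochs", "n_stress1", "n_corr")) {
    expect_true(all(tab[[col]] >= 0 & tab[[col]] <= 1))
    expect_equal(min(tab[[col]]), 0)
  }
  # each component attains 1 across the grid unless its diagnostic is flat
  if (diff(range(tab$stress1)) > 0) expect_equal(max(tab$n_stress1), 1)
  if (diff(range(tab$shepard_r)) > 0) expect_equal(max(tab$n_corr), 1)
  if (diff(range(tab$epochs)) > 0) expect_equal(max(tab$n_epochs), 1)
  # spreadsheet-style recomputation of the objective from the diagnostics
  mm <- function(v) if (diff(range(v)) == 0) rep(0, length(v)) else
    (v - min(v)) / diff(range(v))
  f_obj <- mm(tab$epochs) + mm(tab$stress1) + mm(-tab$shepard_r)
  expect_equal(tab$f_obj, f_obj, tolerance = 1e-12)
  best <- which(f_obj == min(f_obj))
  expect_equal(res$lambda_star, max(tab$lambda[best]))
  expect_error(tune_lambda(sim$D, sim$labels, c(0.05, 0.5), cfg), "grid")
  expect_warning(r1 <- tune_lambda(sim$D, sim$labels, 0.5, cfg), "degenerate")
  expect_equal(r1$lambda_star, 0.5)
})
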