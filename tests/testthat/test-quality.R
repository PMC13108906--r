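test_that("a perfect isometry scores perfectly on all six metrics", {
  pl <- random_planar(14, seed = 10)
  y <- rep(1:2, each = 7)
  for (k in c(1, 3, 7, 10, 12)) {
    tc <- trust_continuity(pl$D, pl$Z, k)
    expect_equal(tc$trustworthiness, 1)
    expect_equal(tc$continuity, 1)
  }
  expect_lt(stress1(pl$D, pl$Z), 1e-6)
  expect_gt(shepard(pl$D, pl$Z)$pearson_r, 0.999999)
  expect_equal(f_correlation(pl$D, pl$Z, y, K = 100, seed = 2), 1,
               tolerance = 1e-9)
  expect_equal(f_rank_ratio(pl$D, pl$Z, y, K = 100, seed = 2), 1)
})

test_that("trust/continuity match the brute-force oracle, all k regimes", {
  set.seed(33)
  for (rep in 1:6) {
    n <- sample(4:7, 1)
    Dx <- euclidean_pairwise(matrix(rnorm(n * 5), n, 5))
    Z <- embedding(matrix(rnorm(2 * n), 2, n))
    Dz <- euclidean_pairwise(Z)
    for (k in seq_len(n - 1)) {        # includes k >= (2n-1)/3
      tc <- trust_continuity(Dx, Z, k)
      ref <- trust_cont_oracle(unclass(Dx), unclass(Dz), k)
      expect_equal(tc$trustworthiness, unname(ref["trust"]), tolerance = 1e-12)
      expect_equal(tc$continuity, unname(ref["cont"]), tolerance = 1e-12)
      expect_true(tc$trustworthiness >= 0 && tc$trustworthiness <= 1)
      expect_true(tc$continuity >= 0 && tc$continuity <= 1)
    }
  }
})

test_that("trustworthiness and continuity swap under role reversal", {
  pl <- random_planar(9, seed = 3)
  Z <- embedding(matrix(rnorm(18), 2, 9))
  Dz <- euclidean_pairwise(Z)
  for (k in c(2, 4)) {
    a <- trust_continuity(pl$D, Z, k)
    b <- trust_continuity(Dz, fimds:::as_dist_matrix(pl$D), k)
    expect_equal(a$trustworthiness, b$continuity, tolerance = 1e-12)
    expect_equal(a$continuity, b$trustworthiness, tolerance = 1e-12)
  }
})

test_that("stress1 matches algebraic cases and flags degeneracy", {
  pl <- random_planar(8, seed = 4)
  expect_lt(stress1(pl$D, pl$Z), 1e-9)
  Z2 <- embedding(2 * unclass(pl$Z))
  expect_equal(stress1(pl$D, Z2), 0.5, tolerance = 1e-9)
  expect_equal(stress1_sq(pl$D, Z2), 0.25, tolerance = 1e-9)
  Zdeg <- embedding(matrix(0, 2, 8))
  expect_error(stress1(pl$D, Zdeg), "degenerate")
})

test_that("shepard reports pair tables and correlation signs", {
  pl <- random_planar(7, seed = 5)
  sp <- shepard(pl$D, pl$Z)
  expect_equal(nrow(sp$pairs), 7 * 6 / 2)
  # affine relation between the spaces gives r = 1
  Daff <- unclass(pl$D) * 0.5 + 0.1
  diag(Daff) <- 0
  expect_equal(shepard(dist_matrix(Daff), pl$Z)$pearson_r, 1,
               tolerance = 1e-12)
  # anti-monotone toy: reverse the original distances off the diagonal
  Drev <- max(unclass(pl$D)) * 1.5 - unclass(pl$D)
  diag(Drev) <- 0
  expect_lt(shepard(dist_matrix(Drev), pl$Z)$pearson_r, 0)
  Zflat <- embedding(matrix(1, 2, 7))
  expect_error(shepard(pl$D, Zflat), "correlation undefined")
})

test_that("f_rank_ratio matches exhaustive enumeration on the N=4 toy", {
  D <- toy_within1_between2()
  y <- c(1, 1, 2, 2)
  Z <- pcoa(D)   # the toy is exactly embeddable? use whatever pcoa returns
  # numerator/denominator counted from the exhaustive distribution
  fp <- permutation_test(D, y, exhaustive = TRUE)
  expect_equal(sum(fp$f_permuted < fp$f_observed), 4)
  # with a true isometric embedding the ratio is exactly 1
  pl <- random_planar(8, seed = 6)
  yy <- rep(1:2, each = 4)
  expect_equal(f_rank_ratio(pl$D, pl$Z, yy, K = 60, seed = 2), 1)
  # p_x = 1 (all permuted F equal the observed) is rejected
  Deq <- dist_matrix(matrix(1, 4, 4) - diag(4))
  expect_error(f_rank_ratio(Deq, pl$Z[, 1:4, drop = FALSE], y, K = 20, seed = 1),
               "bottom of its null")
})

test_that("f_correlation detects isometry and independence, deterministically", {
  pl <- random_planar(12, seed = 7)
  y <- rep(1:2, each = 6)
  expect_equal(f_correlation(pl$D, pl$Z, y, K = 100, seed = 4), 1,
               tolerance = 1e-9)
  expect_identical(f_correlation(pl$D, pl$Z, y, K = 100, seed = 4),
                   f_correlation(pl$D, pl$Z, y, K = 100, seed = 4))
  # an unrelated random configuration decorrelates the F lists
  sim <- small_binary(20, seed = 2)
  set.seed(99)
  Zrand <- embedding(matrix(rnorm(80), 2, 40))
  expect_lt(abs(f_correlation(sim$D, Zrand, sim$labels, K = 500, seed = 8)),
            0.3)
})

test_that("metrics are rigid-motion invariant; scale behavior as documented", {
  pl <- random_planar(10, seed = 11)
  y <- rep(1:2, each = 5)
  sim_D <- small_binary(5, seed = 6)$D   # non-trivial original distances
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Zrot <- embedding(R %*% (unclass(pl$Z) + c(3, -2)) * c(1, 1))
  Zrefl <- embedding(rbind(unclass(pl$Z)[1, ], -unclass(pl$Z)[2, ]))
  for (Zv in list(Zrot, Zrefl)) {
    expect_equal(stress1(sim_D, Zv), stress1(sim_D, pl$Z), tolerance = 1e-9)
    expect_equal(shepard(sim_D, Zv)$pearson_r, shepard(sim_D, pl$Z)$pearson_r,
                 tolerance = 1e-9)
    tc0 <- trust_continuity(sim_D, pl$Z, 3)
    tcv <- trust_continuity(sim_D, Zv, 3)
    expect_equal(tcv$trustworthiness, tc0$trustworthiness)
    expect_equal(f_correlation(sim_D, Zv, y, K = 50, seed = 3),
                 f_correlation(sim_D, pl$Z, y, K = 50, seed = 3),
                 tolerance = 1e-9)
  }
  # scaling: stress1 changes, rank- and F-based metrics do not
  Zs <- embedding(3 * unclass(pl$Z))
  expect_false(isTRUE(all.equal(stress1(sim_D, Zs), stress1(sim_D, pl$Z))))
  expect_equal(trust_continuity(sim_D, Zs, 3)$trustworthiness,
               trust_continuity(sim_D, pl$Z, 3)$trustworthiness)
  expect_equal(f_rank_ratio(sim_D, Zs, y, K = 50, seed = 3),
               f_rank_ratio(sim_D, pl$Z, y, K = 50, seed = 3))
  # Pearson correlation is affine-invariant, so shepard_r is scale-stable
  expect_equal(shepard(sim_D, Zs)$pearson_r, shepard(sim_D, pl$Z)$pearson_r,
               tolerance = 1e-9)
})

test_that("evaluate_embedding aggregates with the documented defaults", {
  sim <- small_binary(10, seed = 8)
  Z <- metric_mds(sim$D)
  rep_ <- evaluate_embedding(sim$D, Z, sim$labels, K_f = 100, seed = 2)
  expect_equal(rep_$k_local, round(0.08 * 20))
  expect_equal(rep_$k_global, round(0.75 * 20))
  expect_true(rep_$stress1 >= 0)
  expect_true(abs(rep_$shepard_r) <= 1)
  expect_true(abs(rep_$f_correlation) <= 1)
  expect_gt(rep_$f_rank_ratio, 0)
})
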