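grid_500 <- 50 * (1:10) - 25

test_that("basis construction and exact Gram matrix", {
  b <- bspline_basis(500, 8)
  expect_equal(b$n_basis, 8)
  expect_equal(length(b$interior_knots), 4)
  # Gram is symmetric positive definite and matches fine trapezoid quadrature
  expect_equal(b$G, t(b$G))
  expect_true(all(eigen(b$G, symmetric = TRUE, only.values = TRUE)$values > 0))
  xs <- seq(0, 500, length.out = 20001)
  B <- eval_basis(b, xs)
  w <- rep(500 / 20000, 20001)
  w[c(1, 20001)] <- w[c(1, 20001)] / 2
  G_quad <- t(B) %*% (B * w)
  expect_equal(b$G, G_quad, tolerance = 1e-7)
  expect_error(bspline_basis(500, 3), "at least the spline order")
})

test_that("least-squares smoothing reproduces curves in the basis span", {
  b <- bspline_basis(500, 8)
  set.seed(2)
  coefs <- rnorm(8)
  y <- as.numeric(eval_basis(b, grid_500) %*% coefs)
  fit <- smooth_profile(y, grid_500, b)
  expect_equal(fit, coefs, tolerance = 1e-10)
  # constants are in any B-spline span
  cfit <- smooth_profile(rep(1, 10), grid_500, b)
  xs <- seq(0, 500, length.out = 101)
  expect_equal(as.numeric(eval_basis(b, xs) %*% cfit), rep(1, 101), tolerance = 1e-10)
  # noisy curve: matches the dense normal-equations solve
  y2 <- y + rnorm(10, 0, 0.05)
  X <- eval_basis(b, grid_500)
  oracle <- solve(t(X) %*% X, t(X) %*% y2)
  expect_equal(smooth_profile(y2, grid_500, b), as.numeric(oracle), tolerance = 1e-8)
  # too many basis functions is rejected
  expect_error(smooth_profile(y2, grid_500, bspline_basis(500, 12)), "more functions")
})

test_that("fPCA eigenfunctions are orthonormal and identical curves give zero variance", {
  sh <- shape_library("women_k1_500")
  set.seed(3)
  S <- matrix(rnorm(300 * 4, 0, c(2, 1, 0.5, 0.25)), 300, 4, byrow = TRUE)
  C <- matrix(rep(sh$mean_coefs, 300), 300, byrow = TRUE) + S %*% t(sh$shape_coefs)
  Y <- C %*% t(eval_basis(sh$basis, grid_500))
  m <- fit_fpca(Y, K = 4, basis = sh$basis, grid = grid_500)
  IP <- t(m$eigenfunctions) %*% sh$basis$G %*% m$eigenfunctions
  expect_equal(IP, diag(4), tolerance = 1e-8)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  # identical curves: every eigenvalue 0 is rejected at K >= 1
  Yc <- Y[rep(1, 10), ]
  expect_error(fit_fpca(Yc, K = 2, basis = sh$basis, grid = grid_500), "rank")
})

test_that("planted factors are recovered with the right variance split", {
  sh <- shape_library("women_k1_500")
  set.seed(5)
  n <- 400
  # single factor, unit variance
  s1 <- rnorm(n)
  s1 <- (s1 - mean(s1)) / sd(s1)
  C1 <- matrix(rep(sh$mean_coefs, n), n, byrow = TRUE) + s1 %*% t(sh$shape_coefs[, 1, drop = FALSE])
  m1 <- fit_fpca(C1 %*% t(eval_basis(sh$basis, grid_500)), K = 1, basis = sh$basis, grid = grid_500)
  expect_gt(abs(t(m1$eigenfunctions[, 1]) %*% sh$basis$G %*% sh$shape_coefs[, 1]), 0.99)
  expect_gt(m1$varexp[1], 0.999)
  expect_equal(m1$eigenvalues[1], 1, tolerance = 0.05)

  # two factors with variances exactly 4 and 1: varexp (0.8, 0.2) within 2%
  S <- cbind(rnorm(n), rnorm(n))
  S <- scale(S) %*% diag(c(2, 1))
  C2 <- matrix(rep(sh$mean_coefs, n), n, byrow = TRUE) + S %*% t(sh$shape_coefs[, 1:2])
  m2 <- fit_fpca(C2 %*% t(eval_basis(sh$basis, grid_500)), K = 2, basis = sh$basis, grid = grid_500)
  expect_equal(m2$varexp, c(0.8, 0.2), tolerance = 0.02)
  expect_equal(variance_explained(m2), m2$varexp)
})

test_that("scores are exact inner products (quadrature oracle) and centre to zero", {
  cfg <- synthetic_config("women_k1_500", n_athletes = 30, races_range = c(8, 8), seed = 13)
  prof <- pacing_profiles(simulate_races(cfg)$races)
  m <- fit_fpca(prof, K = 4)
  # scores of the fitted sample have mean ~ 0 (mean-centred curves)
  sc <- as.matrix(m$scores[, paste0("PC", 1:4)])
  expect_equal(colMeans(sc), rep(0, 4), tolerance = 1e-10, ignore_attr = TRUE)
  # f = mean gives zero scores; f = mean + 2 Phi1 gives (2, 0, 0, 0)
  expect_equal(as.numeric(compute_scores(m, m$mean_coefs)), rep(0, 4), tolerance = 1e-8)
  f2 <- m$mean_coefs + 2 * m$eigenfunctions[, 1]
  expect_equal(as.numeric(compute_scores(m, f2)), c(2, 0, 0, 0), tolerance = 1e-8)
  # random curve: fine-grid trapezoid quadrature oracle
  set.seed(8)
  cf <- m$mean_coefs + as.numeric(m$eigenfunctions %*% rnorm(4, 0, 0.3))
  xs <- seq(0, 500, length.out = 20001)
  fx <- as.numeric(eval_basis(m$basis, xs) %*% (cf - m$mean_coefs))
  Phi <- eval_fpca(m, xs, "eigenfunctions")
  w <- rep(500 / 20000, 20001)
  w[c(1, 20001)] <- w[c(1, 20001)] / 2
  oracle <- as.numeric(t(Phi) %*% (fx * w))
  expect_equal(as.numeric(compute_scores(m, cf)), oracle, tolerance = 1e-6)
})

test_that("scores of the fitted sample are empirically uncorrelated", {
  cfg <- synthetic_config("women_k1_500", n_athletes = 40, races_range = c(6, 6), seed = 17)
  prof <- pacing_profiles(simulate_races(cfg)$races)
  m <- fit_fpca(prof, K = 4)
  cm <- cor(as.matrix(m$scores[, paste0("PC", 1:4)]))
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.05)
})

test_that("reconstruction error is monotone in the retained components", {
  cfg <- synthetic_config("women_k1_500", n_athletes = 10, races_range = c(4, 4), seed = 19)
  prof <- pacing_profiles(simulate_races(cfg)$races)
  m <- fit_fpca(prof, K = 4)
  wide <- tidyr::pivot_wider(
    dplyr::arrange(prof, athlete_id, race_index, distance_m)[, c("athlete_id", "race_index", "distance_m", "norm_velocity")],
    names_from = distance_m, values_from = norm_velocity
  )
  Y <- as.matrix(wide[, -(1:2)])
  C <- smooth_profile(Y, grid_500, m$basis)
  S <- compute_scores(m, C)
  G <- m$basis$G
  err <- sapply(0:4, function(k) {
    R <- reconstruct(m, S, K_used = k) - C
    sum(sapply(seq_len(nrow(R)), function(i) t(R[i, ]) %*% G %*% R[i, ]))
  })
  expect_true(all(diff(err) <= 1e-10))
  # K_used = 0 is the mean function
  expect_equal(
    reconstruct(m, S[1, ], K_used = 0)[1, ], m$mean_coefs,
    ignore_attr = TRUE
  )
  # full-K round trip for a curve in the span
  cf <- m$mean_coefs + as.numeric(m$eigenfunctions %*% c(0.3, -0.2, 0.1, 0.05))
  rt <- reconstruct(m, compute_scores(m, cf), K_used = 4)[1, ]
  expect_equal(rt, cf, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("with an indicator basis fPCA matches ordinary PCA of the grid values", {
  # order-1 B-splines on the 10 segments: Gram = 50 * I, so L2 fPCA reduces
  # to PCA of the gridded values (eigenvalues x 50, scores x sqrt(50))
  b1 <- bspline_basis(500, 10, order = 1)
  expect_equal(b1$G, diag(50, 10), tolerance = 1e-10)
  set.seed(23)
  Y <- matrix(rnorm(60 * 10, 1, 0.05), 60, 10)
  m <- fit_fpca(Y, K = 4, basis = b1, grid = grid_500)
  ev_grid <- eigen(cov(Y), symmetric = TRUE)
  expect_equal(m$eigenvalues[1:4], 50 * ev_grid$values[1:4], tolerance = 1e-8)
  expect_equal(
    m$varexp,
    (ev_grid$values / sum(ev_grid$values))[1:4],
    tolerance = 1e-8
  )
  for (k in 1:4) {
    expect_equal(
      abs(sum(m$eigenfunctions[, k] * ev_grid$vectors[, k]) * sqrt(50)), 1,
      tolerance = 1e-8
    )
  }
})

test_that("fPCA model serialises to JSON and back", {
  cfg <- synthetic_config("women_k1_500", n_athletes = 8, races_range = c(4, 4), seed = 29)
  prof <- pacing_profiles(simulate_races(cfg)$races)
  m <- fit_fpca(prof, K = 4)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_fpca_json(m, tmp)
  m2 <- read_fpca_json(tmp)
  expect_equal(m2$mean_coefs, m$mean_coefs)
  expect_equal(m2$eigenfunctions, m$eigenfunctions, ignore_attr = TRUE)
  expect_equal(m2$eigenvalues, m$eigenvalues)
  cf <- m$mean_coefs + 0.1 * m$eigenfunctions[, 2]
  expect_equal(compute_scores(m2, cf), compute_scores(m, cf))
})

test_that("tidy and glance summarise an fPCA fit", {
  cfg <- synthetic_config("women_k1_500", n_athletes = 8, races_range = c(4, 4), seed = 31)
  m <- fit_fpca(pacing_profiles(simulate_races(cfg)$races), K = 4)
  td <- tidy(m)
  expect_equal(td$component, paste0("PC", 1:4))
  expect_equal(td$cumulative, cumsum(td$varexp))
  expect_equal(glance(m)$K, 4)
})
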