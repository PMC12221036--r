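test_that("published parameter tables load with the printed values", {
  pw <- published_hmm_params("women_k1_500")
  # baseline centroids (intercepts)
  expect_equal(emission_mean(pw, 1, rep(0, 4)), c(0.173, 0.230, -0.003, -0.028))
  expect_equal(emission_mean(pw, 2, rep(0, 4)), c(-0.418, 0.552, -0.136, 0.168))
  # covariate shift: state 3, World Champs, Open -> PC1 = -0.373 + 0.618
  z_wc <- c(0, 0, 0, 1)
  expect_equal(emission_mean(pw, 3, z_wc)[1], -0.373 + 0.618)
  # transition rows are simplex and match the printed diagonal
  expect_equal(rowSums(pw$A), rep(1, 4))
  expect_equal(diag(pw$A), c(0.976, 0.917, 0.853, 0.903))
  pm <- published_hmm_params("men_k1_1000")
  expect_equal(emission_mean(pm, 2, rep(0, 5))[1], 0.979)
  expect_equal(diag(pm$A)[4], 0.475 / sum(c(0.167, 0.234, 0.124, 0.475)))
  expect_equal(rowSums(pm$A), rep(1, 4))
  # men's model has the U18 indicator, women's does not
  expect_equal(length(pm$covariates), 5)
  expect_equal(length(pw$covariates), 4)
  # stationary initial distribution
  expect_equal(as.numeric(pw$pi %*% pw$A), pw$pi, tolerance = 1e-12)
})

test_that("mixture mean is the probability-weighted state mean", {
  pw <- published_hmm_params("women_k1_500")
  # degenerate probability reduces to the state mean
  expect_equal(mixture_mean(pw, c(1, 0, 0, 0), rep(0, 4)), emission_mean(pw, 1, rep(0, 4)))
  # uniform mixture of the baseline PC1 column
  expect_equal(
    mixture_mean(pw, rep(0.25, 4), rep(0, 4))[1],
    (0.173 - 0.418 - 0.373 + 0.063) / 4
  )
  # two-state toy
  toy <- hmm_params(
    pi = c(0.5, 0.5), A = diag(2),
    B = array(c(1, 1, 1, 1, 3, 3, 3, 3), c(4, 2, 1)),
    sigma = matrix(1, 2, 4)
  )
  expect_equal(mixture_mean(toy, c(0.5, 0.5)), rep(2, 4))
  expect_error(mixture_mean(pw, c(0.6, 0.5, 0, 0), rep(0, 4)), "sum to 1")
})

test_that("emission log-density matches the closed form and a dense oracle", {
  toy <- random_params(3, seed = 41)
  # observation at the mean with unit SDs: -d/2 log(2 pi)
  unit <- hmm_params(
    pi = c(1), A = matrix(1), B = array(0, c(4, 1, 1)), sigma = matrix(1, 1, 4)
  )
  expect_equal(
    emission_logdensity(unit, 1, rep(0, 4)), -2 * log(2 * pi),
    tolerance = 1e-12
  )
  # dense multivariate normal with diagonal covariance as oracle
  set.seed(42)
  for (j in 1:3) {
    O <- rnorm(4)
    m <- emission_mean(toy, j)
    S <- diag(toy$sigma[j, ]^2)
    dens <- -0.5 * (4 * log(2 * pi) + determinant(S)$modulus +
      t(O - m) %*% solve(S) %*% (O - m))
    expect_equal(emission_logdensity(toy, j, O), as.numeric(dens), tolerance = 1e-12)
  }
})

test_that("forward-backward matches brute-force path enumeration", {
  set.seed(43)
  for (n in 1:3) {
    params <- random_params(n, seed = 43 + n)
    for (Tt in c(1, 3, 6)) {
      O <- matrix(rnorm(Tt * 4), Tt)
      fb <- forward_backward(params, O)
      oracle <- enumerate_paths(params, O)
      expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-10)
      expect_equal(rowSums(fb$gamma), rep(1, Tt), tolerance = 1e-9)
      if (Tt > 1) {
        expect_equal(apply(fb$xi, 1, sum), rep(1, Tt - 1), tolerance = 1e-9)
      }
    }
  }
  # single state: gamma is 1 and loglik is the emission sum
  p1 <- random_params(1, seed = 50)
  O <- matrix(rnorm(5 * 4), 5)
  fb1 <- forward_backward(p1, O)
  expect_equal(as.numeric(fb1$gamma), rep(1, 5))
  expect_equal(fb1$loglik, sum(sapply(1:5, function(t) emission_logdensity(p1, 1, O[t, ]))))
})

test_that("viterbi matches enumeration and breaks ties to the lowest state", {
  set.seed(47)
  for (rep in 1:5) {
    params <- random_params(3, seed = 100 + rep)
    O <- matrix(rnorm(6 * 4), 6)
    expect_equal(viterbi(params, O), enumerate_paths(params, O)$best_path)
  }
  # symmetric two-state model with identical emissions: all-1 path
  sym <- hmm_params(
    pi = c(0.5, 0.5), A = matrix(0.5, 2, 2),
    B = array(0, c(4, 2, 1)), sigma = matrix(1, 2, 4)
  )
  expect_equal(viterbi(sym, matrix(rnorm(4 * 4), 4)), rep(1L, 4))
  # single state: constant path
  expect_equal(viterbi(random_params(1, seed = 51), matrix(rnorm(8), 2)), rep(1L, 2))
})

test_that("batched E-step agrees with the per-sequence recursion", {
  dat <- simulate_score_dataset(n_athletes = 15, T_len = 7, seed = 53)
  fit <- em_fit(dat, 4, use_covariates = FALSE, n_restarts = 2, seed = 3, max_iter = 50)
  ll <- sum(sapply(split(dat, dat$athlete_id), function(x) {
    forward_backward(fit$params, as.matrix(x[order(x$race_index), paste0("PC", 1:4)]))$loglik
  }))
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
})

test_that("single-state EM reduces to least-squares regression", {
  # with one state the weighted least squares has unit weights, so the
  # coefficients are the OLS fit of scores on covariates
  set.seed(59)
  n <- 120
  dat <- tibble::tibble(
    athlete_id = rep(sprintf("a%02d", 1:10), each = 12),
    race_index = rep(1:12, 10),
    age_group = sample(c("U21", "U23", "Open"), n, replace = TRUE),
    event_type = sample(kayak_event_types, n, replace = TRUE)
  )
  Z <- covariate_matrix(dat, "women_k1_500")
  O <- matrix(rnorm(n * 4), n) + Z %*% matrix(rnorm(16), 4)
  colnames(O) <- paste0("PC", 1:4)
  dat <- dplyr::bind_cols(dat, tibble::as_tibble(O))
  fit <- em_fit(dat, 1, event = "women_k1_500", n_restarts = 1, seed = 7)
  ols <- lm(O ~ Z)
  expect_equal(
    t(matrix(fit$params$B[, 1, ], 4)), unname(coef(ols)),
    tolerance = 1e-6
  )
  resid_var <- colMeans(residuals(ols)^2)
  expect_equal(fit$params$sigma[1, ]^2, unname(resid_var), tolerance = 1e-6)
})

test_that("EM log-likelihood is non-decreasing and recovery works at study scale", {
  dat <- simulate_score_dataset(n_athletes = 60, T_len = 25, seed = 61)
  fit <- em_fit(dat, 4, use_covariates = FALSE, n_restarts = 4, seed = 15)
  # monotone trace (tolerance for float roundoff)
  expect_true(all(diff(fit$ll_trace) >= -1e-8 * pmax(abs(fit$ll_trace[-length(fit$ll_trace)]), 1)))
  # parameter recovery after label alignment
  pw <- published_hmm_params("women_k1_500", include_covariates = FALSE)
  truem <- t(sapply(1:4, function(j) emission_mean(pw, j)))
  estm <- t(sapply(1:4, function(j) emission_mean(fit$params, j)))
  perm <- align_states(estm, truem)
  expect_lt(max(abs(estm[perm, ] - truem)), 0.08)
  expect_lt(max(abs(fit$params$A[perm, perm] - pw$A)), 0.08)
  # permuting the truth's labels leaves the likelihood unchanged
  p2 <- hmm_params(
    pi = pw$pi[c(2, 1, 4, 3)], A = pw$A[c(2, 1, 4, 3), c(2, 1, 4, 3)],
    B = pw$B[, c(2, 1, 4, 3), , drop = FALSE], sigma = pw$sigma[c(2, 1, 4, 3), ]
  )
  O <- as.matrix(dat[dat$athlete_id == "a001", paste0("PC", 1:4)])
  expect_equal(
    forward_backward(pw, O)$loglik, forward_backward(p2, O)$loglik,
    tolerance = 1e-10
  )
})

test_that("AIC uses the documented parameter count", {
  expect_equal(hmm_n_params(1, 4, 4), 24)
  expect_equal(hmm_n_params(4, 4, 4), 3 + 12 + 80 + 16)
  expect_equal(hmm_n_params(4, 4, 0), 3 + 12 + 32)
  dat <- simulate_score_dataset(n_athletes = 10, T_len = 10, seed = 67)
  f2 <- em_fit(dat, 2, use_covariates = FALSE, n_restarts = 2, seed = 5, max_iter = 100)
  expect_equal(f2$aic, -2 * f2$loglik + 2 * hmm_n_params(2, 4, 0))
  expect_equal(aic_hmm(f2), f2$aic)
})

test_that("state-number selection finds no material structure in single-state data", {
  # On iid Gaussian data the spurious log-likelihood gain of an extra HMM
  # state sits near the AIC penalty (the boundary-parameter behaviour of
  # mixture order tests), so the exact argmin between 1 and 2 states is not
  # stable; what must hold is that no candidate gains materially over the
  # single state, in sharp contrast to data with real state structure.
  set.seed(71)
  dat <- tibble::tibble(
    athlete_id = rep(sprintf("a%02d", 1:20), each = 15),
    race_index = rep(1:15, 20)
  ) |>
    dplyr::bind_cols(tibble::as_tibble(matrix(rnorm(300 * 4, 0, 0.2), 300,
      dimnames = list(NULL, paste0("PC", 1:4))
    )))
  scan <- select_n_states(dat, 1:3, use_covariates = FALSE, n_restarts = 5, seed = 73)
  expect_equal(nrow(scan$table), 3)
  aic1 <- scan$table$aic[scan$table$n_states == 1]
  expect_lt(aic1 - min(scan$table$aic, na.rm = TRUE), 25)
  # against real 4-state structure the same scan margin is enormous
  dat4 <- simulate_score_dataset(n_athletes = 20, T_len = 15, seed = 75)
  scan4 <- select_n_states(dat4, c(1, 4), use_covariates = FALSE, n_restarts = 5, seed = 77)
  expect_equal(scan4$best_n, 4L)
  aic1b <- scan4$table$aic[scan4$table$n_states == 1]
  expect_gt(aic1b - min(scan4$table$aic), 200)
})

test_that("decoded self-transitions on simulated careers track the true diagonal", {
  dat <- simulate_score_dataset(n_athletes = 110, T_len = 30, seed = 79)
  pw <- published_hmm_params("women_k1_500", include_covariates = FALSE)
  # decode with the true parameters; empirical self-transition frequency of
  # the decoded paths approaches the simulated diagonal
  built <- dat |>
    dplyr::group_by(athlete_id) |>
    dplyr::group_map(function(x, k) {
      viterbi(pw, as.matrix(x[order(x$race_index), paste0("PC", 1:4)]))
    })
  trans <- table(
    from = unlist(lapply(built, function(p) p[-length(p)])),
    to = unlist(lapply(built, function(p) p[-1]))
  )
  emp <- diag(trans / rowSums(trans))
  expect_lt(max(abs(emp - diag(pw$A))), 0.05)
})

test_that("HMM parameters round-trip through JSON at full precision", {
  pw <- published_hmm_params("women_k1_500")
  tmp <- withr::local_tempfile(fileext = ".json")
  write_hmm_json(pw, tmp)
  back <- read_hmm_json(tmp)
  expect_equal(back$pi, pw$pi, tolerance = 1e-14)
  expect_equal(back$A, pw$A, tolerance = 1e-14)
  expect_identical(as.numeric(back$B), as.numeric(pw$B)) # printed decimals
  expect_equal(back$sigma, pw$sigma, tolerance = 1e-14)
  expect_identical(back$covariates, pw$covariates)
  # a decoded path under the restored parameters is unchanged
  O <- matrix(rnorm(40), 10)
  Z <- matrix(0, 10, 4)
  expect_identical(viterbi(back, O, Z), viterbi(pw, O, Z))
})

test_that("tidy and glance expose HMM coefficients and fit summary", {
  dat <- simulate_score_dataset(n_athletes = 10, T_len = 10, seed = 83)
  fit <- em_fit(dat, 2, use_covariates = FALSE, n_restarts = 2, seed = 5, max_iter = 100)
  td <- tidy(fit)
  expect_equal(nrow(td), 2 * 4 * 1)
  expect_equal(unique(td$term), "(Intercept)")
  gl <- glance(fit)
  expect_equal(gl$n_states, 2)
  expect_equal(gl$n_obs, 100)
})

test_that("parameter validation rejects malformed inputs", {
  expect_error(
    hmm_params(c(0.5, 0.6), diag(2), array(0, c(4, 2, 1)), matrix(1, 2, 4)),
    "sum to 1"
  )
  A_bad <- matrix(c(0.9, 0.2, 0.2, 0.8), 2)
  expect_error(
    hmm_params(c(0.5, 0.5), A_bad, array(0, c(4, 2, 1)), matrix(1, 2, 4)),
    "rows of A"
  )
  expect_error(
    hmm_params(c(0.5, 0.5), diag(2), array(0, c(4, 2, 1)), matrix(0, 2, 4)),
    "strictly positive"
  )
})
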