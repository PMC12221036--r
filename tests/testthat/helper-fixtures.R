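# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files are read.

# A tiny hand-buildable race table: 5 races, 2 of them domestic heats.
toy_races <- function() {
  base <- tibble::tibble(
    athlete_id = c("a1", "a1", "a1", "a2", "a2"),
    race_index = c(1L, 2L, 3L, 1L, 2L),
    event = "women_k1_500",
    age_group = c("U21", "U21", "U23", "Open", "Open"),
    event_type = c("Domestic", "Domestic", "WorldCupJuniors", "Domestic", "WorldChampsOlympics"),
    phase = c("heat", "final", "heat", "heat", "final")
  )
  splits <- matrix(12.5, nrow(base), 10,
    dimnames = list(NULL, sprintf("split_%02d", 1:10))
  )
  splits[2, ] <- seq(11.5, 13.5, length.out = 10) # one non-constant race
  dplyr::bind_cols(base, tibble::as_tibble(splits))
}

# Random valid HMM parameters for oracle tests (no covariates).
random_params <- function(n, d = 4, seed = 1) {
  set.seed(seed)
  A <- matrix(stats::runif(n * n, 0.2, 1), n, n)
  A <- A / rowSums(A)
  pi0 <- stats::runif(n, 0.2, 1)
  pi0 <- pi0 / sum(pi0)
  B <- array(stats::rnorm(d * n), c(d, n, 1))
  sigma <- matrix(stats::runif(n * d, 0.5, 1.5), n, d)
  hmm_params(pi0, A, B, sigma)
}

# Brute-force path enumeration: log-likelihood and most probable path.
enumerate_paths <- function(params, O, Z = NULL) {
  n <- params$n_states
  Tt <- nrow(O)
  grid <- do.call(expand.grid, rep(list(seq_len(n)), Tt))
  lp <- apply(grid, 1, function(s) {
    z1 <- if (is.null(Z)) numeric(0) else Z[1, ]
    lp <- log(params$pi[s[1]]) + emission_logdensity(params, s[1], O[1, ], z1)
    if (Tt > 1) {
      for (t in 2:Tt) {
        zt <- if (is.null(Z)) numeric(0) else Z[t, ]
        lp <- lp + log(params$A[s[t - 1], s[t]]) +
          emission_logdensity(params, s[t], O[t, ], zt)
      }
    }
    lp
  })
  m <- max(lp)
  list(
    loglik = m + log(sum(exp(lp - m))),
    best_path = as.integer(grid[which.max(lp), ])
  )
}

# Score-level dataset simulated from the published women's parameters
# (intercepts + transition matrix, emission SD 0.2, no covariate effects).
simulate_score_dataset <- function(n_athletes = 100, T_len = 30, seed = 11,
                                   event = "women_k1_500") {
  params <- published_hmm_params(event, include_covariates = FALSE)
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(n_athletes), function(i) {
    s <- simulate_states(params$A, params$pi, T_len)
    O <- simulate_scores(params, s, NULL)
    dplyr::bind_cols(
      tibble::tibble(
        athlete_id = sprintf("a%03d", i), race_index = seq_len(T_len),
        true_state = s
      ),
      tibble::as_tibble(O)
    )
  }))
}

# Best label alignment of estimated states to true states by matching
# emission intercepts (minimum total squared distance over permutations).
align_states <- function(est_means, true_means) {
  n <- nrow(true_means)
  perms <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), , drop = FALSE]
  cost <- apply(perms, 1, function(p) sum((est_means[p, , drop = FALSE] - true_means)^2))
  as.integer(perms[which.min(cost), ])
}
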