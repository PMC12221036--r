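#' Hidden Markov model parameters for PC-score trajectories
#'
#' Container for an n-state HMM over d-dimensional PC-score observations
#' with diagonal-covariance Gaussian emissions whose means are linear in 0/1
#' covariate indicators: m_{j,i}(z) = beta_{ij0} + sum_k beta_{ijk} z_k for
#' state j and score dimension i.
#'
#' @param pi Initial state probabilities (length n, sums to 1).
#' @param A n x n transition matrix; `A[i, j]` is P(S_{t+1}=j | S_t=i), rows
#'   sum to 1.
#' @param B Emission coefficient array, dim `c(d, n, 1 + c)`: dimension by
#'   state by coefficient (intercept first, then one slice per covariate).
#' @param sigma n x d matrix of emission standard deviations (all > 0).
#' @param covariates Character vector of covariate indicator names (length
#'   c); may be empty for intercept-only emissions.
#' @param event Optional event name the parameters belong to.
#' @return A `kayak_hmm_params` object.
#' @export
hmm_params <- function(pi, A, B, sigma, covariates = character(), event = NULL) {
  n <- length(pi)
  stopifnot(is.matrix(A), nrow(A) == n, ncol(A) == n)
  if (length(dim(B)) != 3) stop("B must be a d x n x (1+c) array")
  d <- dim(B)[1]
  if (dim(B)[2] != n) stop("B's state dimension disagrees with pi")
  if (dim(B)[3] != 1 + length(covariates)) {
    stop("B's coefficient dimension must be 1 + length(covariates)")
  }
  sigma <- as.matrix(sigma)
  stopifnot(nrow(sigma) == n, ncol(sigma) == d)
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  if (any(pi < -1e-12)) stop("pi must be non-negative")
  if (any(abs(rowSums(A) - 1) > 1e-10)) stop("rows of A must sum to 1 (tol 1e-10)")
  if (any(A < -1e-12)) stop("A must be non-negative")
  if (any(sigma <= 0)) stop("all emission SDs must be strictly positive")
  structure(
    list(
      n_states = n, dims = d, pi = as.numeric(pi), A = unname(A), B = B,
      sigma = unname(sigma), covariates = covariates, event = event
    ),
    class = "kayak_hmm_params"
  )
}

#' @export
print.kayak_hmm_params <- function(x, ...) {
  cat(
    "HMM parameters:", x$n_states, "states,", x$dims, "dimensions,",
    length(x$covariates), "covariates\n"
  )
  cat("diag(A):", paste(sprintf("%.3f", diag(x$A)), collapse = " "), "\n")
  invisible(x)
}

check_covariate_vector <- function(params, z) {
  c_n <- length(params$covariates)
  if (length(z) != c_n) {
    stop("covariate vector has length ", length(z), ", expected ", c_n)
  }
  invisible(z)
}

#' State-conditional emission mean
#'
#' @param params A `kayak_hmm_params`.
#' @param state State index j.
#' @param z Covariate indicator vector (length c, model order).
#' @return Numeric d-vector of emission means for state j.
#' @export
emission_mean <- function(params, state, z = numeric(length(params$covariates))) {
  check_covariate_vector(params, z)
  as.numeric(matrix(params$B[, state, ], nrow = params$dims) %*% c(1, z))
}

#' Mixture emission mean under state probabilities
#'
#' The predicted score vector is the state-probability-weighted mixture of
#' the state-conditional means: mu_i = sum_j P(S_j) m_{j,i}(z).
#'
#' @param params A `kayak_hmm_params`.
#' @param state_probs Probability vector over states (sums to 1 within 1e-6).
#' @param z Covariate indicator vector.
#' @return Numeric d-vector.
#' @export
mixture_mean <- function(params, state_probs, z = numeric(length(params$covariates))) {
  if (length(state_probs) != params$n_states) stop("state_probs has the wrong length")
  if (abs(sum(state_probs) - 1) > 1e-6) stop("state probabilities must sum to 1 (tol 1e-6)")
  M <- emission_mean_matrix(params, z)
  as.numeric(state_probs %*% M)
}

# n x d matrix of state-conditional means at one covariate vector
emission_mean_matrix <- function(params, z) {
  check_covariate_vector(params, z)
  t(apply_coefs(params$B, c(1, z)))
}

apply_coefs <- function(B, x) {
  # B: d x n x (1+c); returns d x n
  d <- dim(B)[1]; n <- dim(B)[2]
  matrix(matrix(B, d * n) %*% x, d, n)
}

#' Log-density of one observation under a state
#'
#' Sum over dimensions of independent Gaussian log-densities with the
#' state's covariate-dependent mean and state-specific variance.
#'
#' @param params A `kayak_hmm_params`.
#' @param state State index.
#' @param obs Observation d-vector.
#' @param z Covariate indicator vector.
#' @return Log-density (scalar).
#' @export
emission_logdensity <- function(params, state, obs, z = numeric(length(params$covariates))) {
  m <- emission_mean(params, state, z)
  sum(stats::dnorm(obs, mean = m, sd = params$sigma[state, ], log = TRUE))
}

# T x n matrix of per-observation, per-state emission log-densities.
# O: T x d, Z: T x c (or NULL when the model has no covariates).
emission_logdensity_matrix <- function(params, O, Z = NULL) {
  n <- params$n_states; d <- params$dims
  Tt <- nrow(O)
  X <- if (length(params$covariates) > 0) cbind(1, Z) else matrix(1, Tt, 1)
  out <- matrix(0, Tt, n)
  for (j in seq_len(n)) {
    Mu <- X %*% t(matrix(params$B[, j, ], d)) # T x d means
    sd_j <- params$sigma[j, ]
    R <- sweep(O - Mu, 2, sd_j, "/")
    out[, j] <- -0.5 * rowSums(R^2) - sum(log(sd_j)) - d / 2 * log(2 * pi)
  }
  out
}

#' Forward-backward posteriors for one sequence
#'
#' Scaled forward-backward recursion; per-time-step rescaling makes
#' underflow impossible by construction. Returns exact smoothed posteriors
#' and the log-likelihood of the sequence (log of the sum over all n^T state
#' paths of the joint density).
#'
#' @param params A `kayak_hmm_params`.
#' @param obs T x d matrix of observations (a single observation vector is
#'   accepted for T = 1).
#' @param z T x c covariate matrix (ignored when the model has no
#'   covariates).
#' @return A list with `gamma` (T x n state posteriors), `xi`
#'   ((T-1) x n x n pairwise posteriors), and `loglik`.
#' @export
forward_backward <- function(params, obs, z = NULL) {
  if (!is.matrix(obs)) obs <- matrix(obs, nrow = 1)
  Tt <- nrow(obs); n <- params$n_states
  lb <- emission_logdensity_matrix(params, obs, z)
  mx <- apply(lb, 1, max)
  bt <- exp(lb - mx)
  A <- params$A
  alpha <- matrix(0, Tt, n)
  cc <- numeric(Tt)
  a <- params$pi * bt[1, ]
  cc[1] <- sum(a)
  alpha[1, ] <- a / cc[1]
  if (Tt > 1) {
    for (t in 2:Tt) {
      a <- as.numeric(alpha[t - 1, ] %*% A) * bt[t, ]
      cc[t] <- sum(a)
      alpha[t, ] <- a / cc[t]
    }
  }
  beta <- matrix(0, Tt, n)
  beta[Tt, ] <- 1
  xi <- if (Tt > 1) array(0, c(Tt - 1, n, n)) else array(0, c(0, n, n))
  if (Tt > 1) {
    for (t in (Tt - 1):1) {
      bb <- bt[t + 1, ] * beta[t + 1, ]
      xi[t, , ] <- (alpha[t, ] %o% bb) * A / cc[t + 1]
      beta[t, ] <- as.numeric(A %*% bb) / cc[t + 1]
    }
  }
  list(gamma = alpha * beta, xi = xi, loglik = sum(log(cc) + mx))
}

#' Most probable state path (global decoding)
#'
#' Viterbi dynamic programme in log space; ties are broken toward the lowest
#' state index.
#'
#' @inheritParams forward_backward
#' @return Integer vector of length T.
#' @export
viterbi <- function(params, obs, z = NULL) {
  if (!is.matrix(obs)) obs <- matrix(obs, nrow = 1)
  Tt <- nrow(obs); n <- params$n_states
  lb <- emission_logdensity_matrix(params, obs, z)
  logA <- log(params$A)
  delta <- log(params$pi) + lb[1, ]
  back <- matrix(0L, Tt, n)
  if (Tt > 1) {
    for (t in 2:Tt) {
      cand <- delta + logA # [i, j] = delta_i + log a_ij
      back[t, ] <- apply(cand, 2, which.max)
      delta <- cand[cbind(back[t, ], seq_len(n))] + lb[t, ]
    }
  }
  path <- integer(Tt)
  path[Tt] <- which.max(delta)
  if (Tt > 1) {
    for (t in (Tt - 1):1) path[t] <- back[t + 1, path[t + 1]]
  }
  path
}

# ---- multi-sequence EM ------------------------------------------------------

# Build the internal sequence list from a tidy score tibble.
# scores: athlete_id, race_index, PC1..PCd (+ age_group/event_type if the
# model uses covariates).
build_sequences <- function(scores, event = NULL, use_covariates = TRUE) {
  pc_cols <- grep("^PC[0-9]+$", names(scores), value = TRUE)
  if (length(pc_cols) == 0) stop("no PC score columns (PC1, PC2, ...) found")
  pc_cols <- paste0("PC", seq_along(pc_cols))
  scores <- dplyr::arrange(scores, .data$athlete_id, .data$race_index)
  covs <- character()
  Zall <- NULL
  if (use_covariates) {
    if (is.null(event)) stop("`event` is required to build covariate indicators")
    covs <- covariate_names(event)
    Zall <- covariate_matrix(scores, event)
  }
  ids <- unique(scores$athlete_id)
  seqs <- lapply(ids, function(id) {
    rows <- which(scores$athlete_id == id)
    list(
      athlete_id = id,
      race_index = scores$race_index[rows],
      O = as.matrix(scores[rows, pc_cols]),
      Z = if (is.null(Zall)) NULL else Zall[rows, , drop = FALSE]
    )
  })
  list(seqs = seqs, covariates = covs, pc_cols = pc_cols)
}

# Batching structure: sequences grouped by length so the E-step recursion
# runs once per time step over all of a group's chains at once.
make_groups <- function(seqs) {
  T_len <- vapply(seqs, function(s) nrow(s$O), 0L)
  offsets <- cumsum(c(0L, utils::head(T_len, -1)))
  lapply(split(seq_along(seqs), T_len), function(ix) {
    Tt <- T_len[ix[1]]
    rows <- vapply(ix, function(s) offsets[s] + seq_len(Tt), integer(Tt))
    # rows: m x Tt matrix of row indices into the stacked observation matrix
    list(Tt = Tt, rows = t(matrix(rows, nrow = Tt)))
  })
}

# Batched E-step over all sequences. Returns stacked posteriors (rows in the
# original stacking order), summed pairwise transition posteriors, total
# log-likelihood, and the first-observation row indices.
em_estep <- function(params, O_all, Z_all, groups) {
  n <- params$n_states
  lb <- emission_logdensity_matrix(params, O_all, Z_all)
  mx <- lb[, 1]
  if (n > 1) for (j in 2:n) mx <- pmax(mx, lb[, j])
  bt_all <- exp(lb - mx)
  A <- params$A
  gamma_all <- matrix(0, nrow(O_all), n)
  Exi <- matrix(0, n, n)
  ll <- 0
  for (g in groups) {
    m <- nrow(g$rows); Tt <- g$Tt
    bt <- array(bt_all[as.vector(g$rows), ], c(m, Tt, n))
    alpha <- array(0, c(m, Tt, n))
    cc <- matrix(0, m, Tt)
    a <- matrix(params$pi, m, n, byrow = TRUE) * bt[, 1, , drop = TRUE]
    a <- matrix(a, m, n)
    cc[, 1] <- rowSums(a)
    alpha[, 1, ] <- a / cc[, 1]
    if (Tt > 1) {
      for (t in 2:Tt) {
        a <- (matrix(alpha[, t - 1, ], m, n) %*% A) * matrix(bt[, t, ], m, n)
        cc[, t] <- rowSums(a)
        alpha[, t, ] <- a / cc[, t]
      }
    }
    ll <- ll + sum(log(cc)) + sum(mx[as.vector(g$rows)])
    beta <- matrix(1, m, n)
    gamma_all[g$rows[, Tt], ] <- matrix(alpha[, Tt, ], m, n)
    if (Tt > 1) {
      for (t in (Tt - 1):1) {
        bb <- matrix(bt[, t + 1, ], m, n) * beta / cc[, t + 1]
        Exi <- Exi + A * crossprod(matrix(alpha[, t, ], m, n), bb)
        beta <- bb %*% t(A)
        gamma_all[g$rows[, t], ] <- matrix(alpha[, t, ], m, n) * beta
      }
    }
  }
  list(gamma = gamma_all, Exi = Exi, loglik = ll)
}

# One EM run from given starting parameters. Returns params, loglik trace,
# posteriors, convergence flags.
# Valid covariate cells: baseline plus each (at most one age, at most one
# event-type) indicator combination.
covariate_cells <- function(covariates) {
  c_n <- length(covariates)
  if (c_n == 0) {
    return(matrix(numeric(0), 1, 0))
  }
  is_age <- covariates %in% kayak_age_groups
  age_opts <- c(0, which(is_age))
  type_opts <- c(0, which(!is_age))
  cells <- expand.grid(age = age_opts, type = type_opts)
  Z <- matrix(0, nrow(cells), c_n)
  for (r in seq_len(nrow(cells))) {
    if (cells$age[r] > 0) Z[r, cells$age[r]] <- 1
    if (cells$type[r] > 0) Z[r, cells$type[r]] <- 1
  }
  Z
}

# Redundant-state check on a converged solution: two states whose emission
# means, averaged (RMS) over all valid covariate cells, differ by less than
# `tol` of their pooled emission SD are operationally the same state; such a
# solution is a degenerate reparameterisation, not a genuine extra state.
states_redundant <- function(params, tol = 0.5) {
  n <- params$n_states
  if (n < 2) return(FALSE)
  cells <- covariate_cells(params$covariates)
  # per state: stacked emission means over cells (cells x d)
  M <- lapply(seq_len(n), function(j) {
    t(vapply(
      seq_len(nrow(cells)),
      function(r) emission_mean(params, j, cells[r, ]),
      numeric(params$dims)
    ))
  })
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      rms <- sqrt(mean((M[[i]] - M[[j]])^2))
      scale <- sqrt(mean((params$sigma[i, ]^2 + params$sigma[j, ]^2) / 2))
      if (rms < tol * scale) return(TRUE)
    }
  }
  FALSE
}

em_run <- function(seqs, params, tol = 1e-8, max_iter = 500,
                   starve_tol = NULL, groups = NULL,
                   var_collapse_ratio = 0.1, redundancy_tol = 0.5) {
  n <- params$n_states; d <- params$dims
  c_n <- length(params$covariates)
  O_all <- do.call(rbind, lapply(seqs, `[[`, "O"))
  Z_all <- if (c_n > 0) do.call(rbind, lapply(seqs, `[[`, "Z")) else NULL
  X_all <- if (c_n > 0) cbind(1, Z_all) else matrix(1, nrow(O_all), 1)
  if (is.null(starve_tol)) starve_tol <- ncol(X_all) + 1
  if (is.null(groups)) groups <- make_groups(seqs)
  first_idx <- cumsum(c(1, utils::head(vapply(seqs, function(s) nrow(s$O), 0L), -1)))
  ll_trace <- numeric(0)
  ll_old <- -Inf
  degenerate <- FALSE
  converged <- FALSE
  gamma_all <- NULL
  for (iter in seq_len(max_iter)) {
    es <- em_estep(params, O_all, Z_all, groups)
    gamma_all <- es$gamma
    Exi <- es$Exi
    ll <- es$loglik
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) &&
      abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # M-step
    occ <- colSums(gamma_all)
    if (any(occ < starve_tol)) {
      degenerate <- TRUE
      break
    }
    pi_new <- colMeans(gamma_all[first_idx, , drop = FALSE])
    pi_new <- pi_new / sum(pi_new)
    A_new <- Exi / rowSums(Exi)
    B_new <- params$B
    sigma_new <- params$sigma
    for (j in seq_len(n)) {
      w <- gamma_all[, j]
      XtWX <- crossprod(X_all, X_all * w)
      coefs <- tryCatch(
        solve(XtWX, crossprod(X_all, O_all * w)),
        error = function(e) NULL
      )
      if (is.null(coefs)) {
        degenerate <- TRUE
        break
      }
      B_new[, j, ] <- t(coefs)
      resid <- O_all - X_all %*% coefs
      sigma_new[j, ] <- sqrt(pmax(colSums(resid^2 * w) / sum(w), 1e-10))
    }
    # variance collapse: a state whose emission variance shrinks far below
    # the other states' marks the unbounded-likelihood pathology of Gaussian
    # mixtures (a near-empty state locking onto a few points); such
    # solutions are invalid, not better fits
    if (n > 1) {
      med <- apply(sigma_new^2, 2, stats::median)
      if (any(sweep(sigma_new^2, 2, med, "/") < var_collapse_ratio)) {
        degenerate <- TRUE
      }
    }
    if (degenerate) break
    params <- hmm_params(pi_new, A_new, B_new, sigma_new,
      covariates = params$covariates, event = params$event
    )
  }
  if (!converged && !degenerate) {
    # max_iter exhausted after an M-step: report the likelihood of the
    # parameters actually returned
    es <- em_estep(params, O_all, Z_all, groups)
    gamma_all <- es$gamma
    ll_trace <- c(ll_trace, es$loglik)
  }
  if (!degenerate && states_redundant(params, redundancy_tol)) degenerate <- TRUE
  list(
    params = params, loglik = ll_trace[length(ll_trace)], ll_trace = ll_trace,
    converged = converged, degenerate = degenerate, n_iter = length(ll_trace),
    gamma = gamma_all
  )
}

# Random starting parameters, deterministic given the RNG state.
em_init <- function(seqs, n_states, covariates, event) {
  O_all <- do.call(rbind, lapply(seqs, `[[`, "O"))
  d <- ncol(O_all)
  n <- n_states
  c_n <- length(covariates)
  A <- matrix(stats::runif(n * n), n, n)
  diag(A) <- 0
  A <- 0.15 * A / pmax(rowSums(A), .Machine$double.eps)
  diag(A) <- 1 - rowSums(A)
  if (n == 1) A <- matrix(1, 1, 1)
  B <- array(0,
    dim = c(d, n, 1 + c_n),
    dimnames = list(
      paste0("PC", seq_len(d)), paste0("state", seq_len(n)),
      c("(Intercept)", covariates)
    )
  )
  for (j in seq_len(n)) {
    q <- stats::runif(d, 0.1, 0.9)
    B[, j, 1] <- vapply(seq_len(d), function(i) {
      stats::quantile(O_all[, i], q[i], names = FALSE)
    }, 0)
  }
  sigma <- matrix(apply(O_all, 2, stats::sd), n, d, byrow = TRUE)
  sigma[sigma <= 0] <- 1
  hmm_params(rep(1 / n, n), A, B, sigma, covariates = covariates, event = event)
}

#' Fit the covariate-emission HMM by EM with random restarts
#'
#' Each athlete's ordered score vectors form one chain; the initial
#' distribution, transition matrix and emission coefficients are shared
#' across athletes. The E-step runs the scaled forward-backward recursion per
#' sequence; the M-step re-estimates pi from first-step posteriors, the
#' transition matrix from summed pairwise posteriors, the emission
#' coefficients by per-state weighted least squares (weights = state
#' posteriors) and the variances as weighted residual variances. The restart
#' with the highest final log-likelihood is kept. Restarts showing either
#' symptom of the unbounded-likelihood pathology of Gaussian mixtures -- a
#' state starving (total posterior mass below the regression's column count
#' plus one) or an emission variance collapsing below `var_collapse_ratio`
#' times the cross-state median for that dimension -- are flagged degenerate
#' and excluded from selection, as are converged solutions in which two
#' states are operationally identical (redundant states): a solution with a
#' collapsed or duplicated state is an invalid model, not a better fit.
#'
#' @param scores Tidy score tibble: `athlete_id`, `race_index`,
#'   `PC1`...`PCd`, plus `age_group` and `event_type` when covariates are
#'   used.
#' @param n_states Number of hidden states.
#' @param event Event name (`"women_k1_500"` or `"men_k1_1000"`); required
#'   when `use_covariates = TRUE` to define the indicator coding.
#' @param use_covariates Include the age-group/event-type regression in the
#'   emission means (default `TRUE`).
#' @param n_restarts Number of random EM restarts (the study protocol used
#'   200; tests use fewer).
#' @param seed Integer seed controlling all restarts.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @param var_collapse_ratio Degeneracy guard: smallest allowed ratio of a
#'   state's emission variance to the cross-state median (per dimension).
#' @param redundancy_tol Degeneracy guard: a converged restart in which two
#'   states' emission coefficient vectors differ (root-mean-square) by less
#'   than this fraction of their pooled emission SD is discarded as a
#'   redundant-state solution.
#' @return A `kayak_hmm` fit: `params`, `loglik`, `aic`, `n_params`,
#'   `posteriors` (tibble with per-race state posteriors, Viterbi state and
#'   its posterior probability), `ll_trace`, `restarts` (per-restart summary
#'   tibble), `seed`.
#' @export
em_fit <- function(scores, n_states, event = NULL, use_covariates = TRUE,
                   n_restarts = 200, seed = 1, tol = 1e-8, max_iter = 500,
                   var_collapse_ratio = 0.1, redundancy_tol = 0.5) {
  built <- build_sequences(scores, event = event, use_covariates = use_covariates)
  seqs <- built$seqs
  n_obs <- sum(vapply(seqs, function(s) nrow(s$O), 0L))
  d <- ncol(seqs[[1]]$O)
  k <- hmm_n_params(n_states, d, length(built$covariates))
  if (n_obs <= k) {
    stop("only ", n_obs, " observations for ", k, " parameters; need more data")
  }
  set.seed(seed)
  restart_seeds <- sample.int(.Machine$integer.max - 1, n_restarts)
  groups <- make_groups(seqs)
  runs <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(restart_seeds[r])
    init <- em_init(seqs, n_states, built$covariates, event)
    runs[[r]] <- em_run(seqs, init,
      tol = tol, max_iter = max_iter, groups = groups,
      var_collapse_ratio = var_collapse_ratio, redundancy_tol = redundancy_tol
    )
  }
  restart_tbl <- tibble::tibble(
    restart = seq_len(n_restarts),
    seed = restart_seeds,
    loglik = vapply(runs, `[[`, 0, "loglik"),
    n_iter = vapply(runs, `[[`, 0L, "n_iter"),
    converged = vapply(runs, `[[`, FALSE, "converged"),
    degenerate = vapply(runs, `[[`, FALSE, "degenerate")
  )
  ok <- which(!restart_tbl$degenerate & is.finite(restart_tbl$loglik))
  if (length(ok) == 0) stop("all ", n_restarts, " restarts degenerated; no usable fit")
  best_i <- ok[which.max(restart_tbl$loglik[ok])]
  best <- runs[[best_i]]
  fit <- structure(
    list(
      params = best$params, loglik = best$loglik, n_params = k,
      aic = -2 * best$loglik + 2 * k,
      ll_trace = best$ll_trace, converged = best$converged,
      restarts = restart_tbl, best_restart = best_i,
      seed = seed, n_obs = n_obs, event = event,
      use_covariates = use_covariates
    ),
    class = "kayak_hmm"
  )
  fit$posteriors <- decode_sequences(best$params, seqs)
  fit
}

# Viterbi + posterior tibble for a sequence list
decode_sequences <- function(params, seqs) {
  purrr::map_dfr(seqs, function(s) {
    fb <- forward_backward(params, s$O, s$Z)
    path <- viterbi(params, s$O, s$Z)
    g <- fb$gamma
    colnames(g) <- paste0("p_state", seq_len(ncol(g)))
    tibble::tibble(
      athlete_id = s$athlete_id,
      race_index = s$race_index,
      state = path,
      posterior = g[cbind(seq_along(path), path)]
    ) |>
      dplyr::bind_cols(tibble::as_tibble(g))
  })
}

#' Number of free parameters of the HMM
#'
#' (n-1) initial probabilities + n(n-1) transition probabilities +
#' n d (c+1) emission coefficients + n d variances.
#'
#' @param n_states,d,n_covariates Model dimensions.
#' @return Integer count.
#' @export
hmm_n_params <- function(n_states, d = 4, n_covariates = 0) {
  (n_states - 1) + n_states * (n_states - 1) +
    n_states * d * (n_covariates + 1) + n_states * d
}

#' Akaike information criterion of a fit
#'
#' @param fit A `kayak_hmm`.
#' @return `-2 loglik + 2 k` with `k` from [hmm_n_params()].
#' @export
aic_hmm <- function(fit) {
  -2 * fit$loglik + 2 * fit$n_params
}

#' Select the number of states by AIC
#'
#' Fits every candidate state count with [em_fit()] and returns the count
#' minimising AIC together with the full scan table. Candidates whose every
#' restart degenerates are reported in the table with `NA` log-likelihood
#' (and a warning), not silently dropped.
#'
#' @inheritParams em_fit
#' @param state_range Integer vector of candidate state counts.
#' @return A `kayak_hmm_scan`: `best_n`, `table` (n, loglik, aic,
#'   converged), and `best_fit`.
#' @export
select_n_states <- function(scores, state_range = 2:6, event = NULL,
                            use_covariates = TRUE, n_restarts = 20, seed = 1,
                            tol = 1e-8, max_iter = 500,
                            var_collapse_ratio = 0.1, redundancy_tol = 0.5) {
  stopifnot(length(state_range) >= 1)
  fits <- vector("list", length(state_range))
  rows <- vector("list", length(state_range))
  for (i in seq_along(state_range)) {
    n <- state_range[i]
    fit <- tryCatch(
      em_fit(scores, n,
        event = event, use_covariates = use_covariates,
        n_restarts = n_restarts, seed = seed + i, tol = tol,
        max_iter = max_iter, var_collapse_ratio = var_collapse_ratio,
        redundancy_tol = redundancy_tol
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      warning("candidate n = ", n, " failed: ", conditionMessage(fit))
      rows[[i]] <- tibble::tibble(
        n_states = n, loglik = NA_real_, aic = NA_real_, converged = NA
      )
    } else {
      fits[[i]] <- fit
      rows[[i]] <- tibble::tibble(
        n_states = n, loglik = fit$loglik, aic = fit$aic,
        converged = fit$converged
      )
    }
  }
  tab <- dplyr::bind_rows(rows)
  if (all(is.na(tab$aic))) stop("no candidate state count produced a usable fit")
  best_i <- which.min(tab$aic)
  structure(
    list(best_n = tab$n_states[best_i], table = tab, best_fit = fits[[best_i]]),
    class = "kayak_hmm_scan"
  )
}

#' @export
print.kayak_hmm_scan <- function(x, ...) {
  cat("AIC scan over state counts\n")
  print(as.data.frame(x$table), row.names = FALSE)
  cat("selected:", x$best_n, "states\n")
  invisible(x)
}

#' @export
print.kayak_hmm <- function(x, ...) {
  cat(
    "HMM fit:", x$params$n_states, "states,", x$n_obs, "observations,",
    length(x$params$covariates), "covariates\n"
  )
  cat(sprintf(
    "loglik %.3f | AIC %.3f (k = %d) | best of %d restarts%s\n",
    x$loglik, x$aic, x$n_params, nrow(x$restarts),
    if (x$converged) "" else " [not converged]"
  ))
  invisible(x)
}

#' Serialise HMM parameters to JSON (and back)
#'
#' Full-precision round trip of every parameter block.
#'
#' @param params A `kayak_hmm_params`.
#' @param path Output file.
#' @return `path` invisibly; `read_hmm_json()` returns the restored object.
#' @export
write_hmm_json <- function(params, path) {
  obj <- list(
    n_states = params$n_states, dims = params$dims, event = params$event,
    covariates = as.list(params$covariates),
    pi = params$pi, A = params$A,
    B = as.numeric(params$B), B_dim = dim(params$B),
    sigma = params$sigma
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_hmm_json
#' @export
read_hmm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  B <- array(obj$B, dim = obj$B_dim)
  dimnames(B) <- list(
    paste0("PC", seq_len(obj$B_dim[1])),
    paste0("state", seq_len(obj$B_dim[2])),
    c("(Intercept)", unlist(obj$covariates))
  )
  hmm_params(
    pi = obj$pi, A = matrix(unlist(obj$A), obj$n_states, byrow = FALSE),
    B = B, sigma = matrix(unlist(obj$sigma), obj$n_states),
    covariates = as.character(unlist(obj$covariates)),
    event = obj$event
  )
}
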