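#' Shape library: mean pacing curve and perturbation shapes
#'
#' The generator's curve model for an event: a parametric mean pacing curve
#' and four orthonormal perturbation shapes, all represented as coefficients
#' in the event's B-spline basis so that planted curves lie exactly in the
#' span the fPCA stage fits.
#'
#' The mean curve rises quickly from the standing start to a peak of about
#' 1.08 near 80 m (500 m) or 100 m (1000 m) and then declines; the 1000 m
#' curve flattens mid-race and adds a small late-race "kick" bump. The raw
#' perturbation shapes encode dropoff (early +, late -), kick (late +),
#' early-vs-late contrast, and a late-kick bump; they are projected onto the
#' basis and Gram-Schmidt orthonormalised under the exact L2 inner product.
#' The mean curve is scaled so its harmonic mean over the segment midpoints
#' is 1, which makes the time-weighted mean of a noise-free generated
#' profile exactly 1 (the normalisation contract of the data module).
#'
#' @param event `"women_k1_500"` or `"men_k1_1000"`.
#' @param basis Optional `kayak_basis`; defaults to the event's fPCA basis
#'   (cubic, 8 functions for 500 m, 12 for 1000 m).
#' @return A `kayak_shapes` object: `event`, `basis`, `grid` (segment
#'   midpoints), `mean_coefs`, `shape_coefs` (n_basis x 4).
#' @export
shape_library <- function(event, basis = NULL) {
  info <- event_info(event)
  p <- info$distance_m
  grid <- 50 * (seq_len(info$n_segments) - 0.5)
  if (is.null(basis)) basis <- default_basis_for_grid(grid)
  xs <- seq(0, p, length.out = 201)
  mean_fun <- if (p == 500) {
    function(x) 0.75 + 0.38 * (1 - exp(-x / 20)) - 0.14 * x / p
  } else {
    function(x) {
      0.75 + 0.38 * (1 - exp(-x / 25)) - 0.13 * (1 - exp(-x / 350)) +
        0.02 * exp(-((x - 0.9 * p) / (0.12 * p))^2)
    }
  }
  raw_shapes <- list(
    dropoff = function(x) cos(pi * x / p),
    kick = function(x) tanh((x - 0.7 * p) / (0.12 * p)),
    contrast = function(x) cos(2 * pi * x / p),
    late_kick = function(x) exp(-((x - 0.85 * p) / (0.08 * p))^2) - 0.15
  )
  proj <- function(f) smooth_profile(f(xs), xs, basis)
  mean_coefs <- proj(mean_fun)
  # harmonic-mean-1 scaling at the midpoints (time-weighted mean contract)
  u <- as.numeric(eval_basis(basis, grid) %*% mean_coefs)
  if (any(u <= 0)) stop("mean curve is non-positive at a segment midpoint")
  mean_coefs <- mean_coefs / (length(u) / sum(1 / u))
  u <- as.numeric(eval_basis(basis, grid) %*% mean_coefs)
  S <- vapply(raw_shapes, proj, numeric(basis$n_basis))
  # Make each shape leave the race-average velocity of a perturbed curve
  # unchanged to first order: d/de HM(u + e*phi) = 0 at the mean curve, i.e.
  # sum(phi_i / u_i^2) = 0 at the midpoints. Subtracting the right multiple
  # of the constant function (B-spline coefficients all 1) enforces this and
  # keeps the shapes in the basis span; without it, renormalising a
  # perturbed profile by its own race average would distort planted scores.
  Bg <- eval_basis(basis, grid)
  w <- 1 / u^2
  for (k in seq_len(ncol(S))) {
    ck <- sum(w * (Bg %*% S[, k])) / sum(w)
    S[, k] <- S[, k] - ck
  }
  G <- basis$G
  for (k in seq_len(ncol(S))) {
    if (k > 1) {
      for (j in seq_len(k - 1)) {
        S[, k] <- S[, k] - as.numeric(crossprod(S[, j], G %*% S[, k])) * S[, j]
      }
    }
    nrm <- sqrt(as.numeric(crossprod(S[, k], G %*% S[, k])))
    if (nrm < 1e-10) stop("perturbation shapes are not linearly independent")
    S[, k] <- S[, k] / nrm
  }
  colnames(S) <- names(raw_shapes)
  structure(
    list(event = info$event, basis = basis, grid = grid,
         mean_coefs = mean_coefs, shape_coefs = S),
    class = "kayak_shapes"
  )
}

#' Configuration for the synthetic-data generator
#'
#' Defaults are the package's synthetic study conditions: the published
#' 4-state parameters (intercepts, covariate effects and transition matrix)
#' with per-state, per-PC emission SD 0.2; race-average velocities drawn per
#' race from N(4.29, 0.23^2) m/s for the women's 500 m and N(4.80, 0.24^2)
#' for the men's 1000 m; event types Domestic / World Cup-Juniors / World
#' Champs-Olympics with probabilities 0.6 / 0.25 / 0.15; phases heat / semi /
#' final with probabilities 0.2 / 0.3 / 0.5 (domestic heats are generated so
#' that the filtering rule is exercised); and small grid-level profile noise
#' (SD 0.01 normalised-velocity units, the scale of 50 m split timing error).
#'
#' @param event Event name.
#' @param n_athletes Number of athletes (default 70, the women's cohort
#'   size).
#' @param races_range Inclusive range of career lengths, drawn uniformly.
#' @param params True `kayak_hmm_params` (default: published parameters with
#'   `sigma`).
#' @param sigma Emission SD used when `params` is NULL.
#' @param include_covariates Use the published covariate effects in the
#'   truth (default TRUE).
#' @param mean_velocity,mean_velocity_sd Race-average velocity distribution;
#'   event defaults as above.
#' @param profile_noise_sd SD of independent noise added to each segment's
#'   normalised velocity.
#' @param event_type_probs,phase_probs Sampling probabilities for race
#'   covariates.
#' @param seed Mandatory integer seed.
#' @return A `kayak_synth_config` list.
#' @export
synthetic_config <- function(event, n_athletes = 70, races_range = c(3, 40),
                             params = NULL, sigma = 0.2,
                             include_covariates = TRUE,
                             mean_velocity = NULL, mean_velocity_sd = NULL,
                             profile_noise_sd = 0.01,
                             event_type_probs = c(Domestic = 0.6, WorldCupJuniors = 0.25, WorldChampsOlympics = 0.15),
                             phase_probs = c(heat = 0.2, semi = 0.3, final = 0.5),
                             seed) {
  if (missing(seed)) stop("a seed is mandatory for the synthetic generator")
  info <- event_info(event)
  if (is.null(params)) {
    params <- published_hmm_params(info$event, sigma = sigma,
                                   include_covariates = include_covariates)
  }
  if (is.null(mean_velocity)) {
    mean_velocity <- if (info$event == "women_k1_500") 4.29 else 4.80
  }
  if (is.null(mean_velocity_sd)) {
    mean_velocity_sd <- if (info$event == "women_k1_500") 0.23 else 0.24
  }
  stopifnot(
    length(races_range) == 2, races_range[1] >= 1,
    races_range[2] >= races_range[1],
    abs(sum(event_type_probs) - 1) < 1e-8, abs(sum(phase_probs) - 1) < 1e-8,
    mean_velocity_sd >= 0, profile_noise_sd >= 0
  )
  structure(
    list(
      event = info$event, n_athletes = n_athletes, races_range = races_range,
      params = params, mean_velocity = mean_velocity,
      mean_velocity_sd = mean_velocity_sd, profile_noise_sd = profile_noise_sd,
      event_type_probs = event_type_probs, phase_probs = phase_probs,
      seed = as.integer(seed)
    ),
    class = "kayak_synth_config"
  )
}

#' Sample one athlete's covariate schedule
#'
#' Draws a career length uniformly from the configured range, a monotone
#' age-group progression (U18 ->) U21 -> U23 -> Open with random block
#' lengths starting from a random entry group, and independent event types
#' and phases per race. Uses the current RNG state; [simulate_races()] seeds
#' it once per dataset.
#'
#' @param config A `kayak_synth_config`.
#' @param athlete_index Athlete number (used for the id label).
#' @return Tibble: `athlete_id`, `race_index`, `age_group`, `event_type`,
#'   `phase`.
#' @export
sample_career <- function(config, athlete_index) {
  info <- event_info(config$event)
  groups <- c(info$age_groups, "Open") # already in progression order
  T_len <- config$races_range[1] +
    sample.int(config$races_range[2] - config$races_range[1] + 1L, 1) - 1L
  start <- sample(seq_along(groups), 1)
  span <- groups[start:length(groups)]
  w <- stats::runif(length(span), 0.2, 1)
  sizes <- floor(T_len * w / sum(w))
  rem <- T_len - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  age <- rep(span, times = sizes)
  tibble::tibble(
    athlete_id = sprintf("ath%03d", athlete_index),
    race_index = seq_len(T_len),
    age_group = age,
    event_type = sample(names(config$event_type_probs), T_len,
      replace = TRUE, prob = config$event_type_probs
    ),
    phase = sample(names(config$phase_probs), T_len,
      replace = TRUE, prob = config$phase_probs
    )
  )
}

#' Simulate a hidden state path
#'
#' @param A Transition matrix (row-stochastic).
#' @param pi Initial distribution.
#' @param T_len Path length.
#' @param seed Optional seed (omit to use the current RNG state).
#' @return Integer state vector of length `T_len`.
#' @export
simulate_states <- function(A, pi, T_len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(abs(rowSums(A) - 1) > 1e-8)) stop("A must be row-stochastic")
  n <- length(pi)
  s <- integer(T_len)
  s[1] <- sample.int(n, 1, prob = pi)
  if (T_len > 1) {
    for (t in 2:T_len) s[t] <- sample.int(n, 1, prob = A[s[t - 1], ])
  }
  s
}

#' Simulate PC-score observations given states and covariates
#'
#' Each observation is drawn from the diagonal Gaussian with mean
#' m_{s_t}(z_t) and the state's per-dimension variances.
#'
#' @param params A `kayak_hmm_params`.
#' @param states Integer state path.
#' @param Z Covariate indicator matrix (rows = time points), or NULL for a
#'   covariate-free model.
#' @param seed Optional seed.
#' @return Matrix, `length(states)` x d, columns `PC1`...
#' @export
simulate_scores <- function(params, states, Z = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Tt <- length(states)
  if (length(params$covariates) > 0) {
    if (is.null(Z) || nrow(Z) != Tt) stop("Z must have one row per state")
  }
  O <- matrix(0, Tt, params$dims)
  for (t in seq_len(Tt)) {
    z <- if (length(params$covariates) > 0) Z[t, ] else numeric(0)
    m <- emission_mean(params, states[t], z)
    O[t, ] <- stats::rnorm(params$dims, m, params$sigma[states[t], ])
  }
  colnames(O) <- paste0("PC", seq_len(params$dims))
  O
}

#' Convert planted PC scores to 50 m split durations
#'
#' Builds the normalised curve u(x) = mean(x) + sum_k beta_k Phi_k(x),
#' evaluates it at the segment midpoints, adds independent grid noise, and
#' converts to splits via v_i = u_i * vbar and dt_i = 50 / v_i. Draws whose
#' noisy curve is non-positive anywhere are resampled (up to 100 times).
#'
#' @param shapes A `kayak_shapes`.
#' @param scores Numeric vector of planted scores (length 4).
#' @param mean_velocity Race-average velocity vbar in m/s.
#' @param profile_noise_sd SD of per-segment noise on the normalised scale.
#' @param seed Optional seed.
#' @return Numeric vector of split durations (seconds).
#' @export
scores_to_splits <- function(shapes, scores, mean_velocity,
                             profile_noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (mean_velocity <= 0) stop("mean velocity must be positive")
  base <- as.numeric(
    eval_basis(shapes$basis, shapes$grid) %*%
      (shapes$mean_coefs + shapes$shape_coefs %*% scores)
  )
  for (try in 1:100) {
    u <- base + stats::rnorm(length(base), 0, profile_noise_sd)
    if (all(u > 0)) {
      return(50 / (u * mean_velocity))
    }
  }
  stop("could not draw a positive profile; scores are pathological for the shape library")
}

#' Simulate a complete synthetic dataset
#'
#' Generates careers, latent state paths, PC scores, and raw split times for
#' every athlete under one master seed. The hidden chain runs over all of an
#' athlete's races, including domestic heats (which the analysis filter
#' later removes).
#'
#' @param config A `kayak_synth_config`.
#' @return A list: `races` (race-record tibble in the input-CSV schema) and
#'   `truth` (tibble with the true state, planted scores and race-average
#'   velocity per race, plus attributes `params` and `shapes`).
#' @export
simulate_races <- function(config) {
  set.seed(config$seed)
  info <- event_info(config$event)
  shapes <- shape_library(config$event)
  params <- config$params
  race_rows <- list()
  truth_rows <- list()
  for (i in seq_len(max(config$n_athletes, 0))) {
    career <- sample_career(config, i)
    Tt <- nrow(career)
    Z <- if (length(params$covariates) > 0) {
      covariate_matrix(career, config$event)
    } else {
      NULL
    }
    states <- simulate_states(params$A, params$pi, Tt)
    O <- simulate_scores(params, states, Z)
    vbar <- stats::rnorm(Tt, config$mean_velocity, config$mean_velocity_sd)
    vbar <- pmax(vbar, 0.5) # physical floor; draws this low never occur at the defaults
    splits <- matrix(NA_real_, Tt, 20)
    for (t in seq_len(Tt)) {
      splits[t, seq_len(info$n_segments)] <-
        scores_to_splits(shapes, O[t, ], vbar[t], config$profile_noise_sd)
    }
    colnames(splits) <- split_cols(20)
    race_rows[[i]] <- dplyr::bind_cols(
      career[, c("athlete_id", "race_index")],
      tibble::tibble(event = info$event),
      career[, c("age_group", "event_type", "phase")],
      tibble::as_tibble(splits)
    )
    truth_rows[[i]] <- dplyr::bind_cols(
      career,
      tibble::tibble(state = states, mean_velocity = vbar),
      tibble::as_tibble(O)
    )
  }
  races <- dplyr::bind_rows(race_rows)
  truth <- dplyr::bind_rows(truth_rows)
  if (config$n_athletes == 0) {
    races <- tibble::tibble(
      athlete_id = character(), race_index = integer(), event = character(),
      age_group = character(), event_type = character(), phase = character()
    ) |> dplyr::bind_cols(tibble::as_tibble(matrix(numeric(0), 0, 20,
      dimnames = list(NULL, split_cols(20))
    )))
    truth <- tibble::tibble()
  }
  attr(truth, "params") <- params
  attr(truth, "shapes") <- shapes
  attr(truth, "seed") <- config$seed
  list(races = races, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Writes the race CSV in the schema [read_race_csv()] expects plus a truth
#' JSON sidecar (per-race states, planted scores, true parameters, seed) for
#' recovery testing. Identical config and seed give byte-identical files.
#'
#' @param config A `kayak_synth_config`.
#' @param dir Output directory (created if missing).
#' @return Named character vector with the paths written.
#' @export
generate_dataset <- function(config, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create output directory: ", dir)
  }
  sim <- simulate_races(config)
  csv_path <- file.path(dir, paste0(config$event, "_races.csv"))
  json_path <- file.path(dir, paste0(config$event, "_truth.json"))
  utils::write.csv(sim$races, csv_path, row.names = FALSE, quote = FALSE)
  params <- attr(sim$truth, "params")
  truth <- list(
    seed = config$seed,
    event = config$event,
    params = list(
      pi = params$pi, A = params$A, B = as.numeric(params$B),
      B_dim = dim(params$B), sigma = params$sigma,
      covariates = as.list(params$covariates)
    ),
    races = as.list(sim$truth[, setdiff(names(sim$truth), character(0))])
  )
  jsonlite::write_json(truth, json_path, digits = NA, auto_unbox = TRUE)
  c(races = csv_path, truth = json_path)
}
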