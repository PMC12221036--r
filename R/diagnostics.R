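#' Sojourn times of decoded state paths
#'
#' Maximal runs of consecutive identical states, extracted per athlete (runs
#' never merge across athletes). Under a time-homogeneous Markov chain the
#' sojourn time in state j is Geometric with success probability 1 - a_jj.
#'
#' @param decoded Tibble with columns `athlete_id`, `race_index`, `state`
#'   (e.g. the `posteriors` element of a [em_fit()] result), or a bare
#'   integer vector for a single path.
#' @return A tibble with columns `athlete_id`, `state`, `length` (one row
#'   per maximal run).
#' @export
sojourn_times <- function(decoded) {
  if (is.atomic(decoded)) {
    decoded <- tibble::tibble(
      athlete_id = "athlete", race_index = seq_along(decoded), state = decoded
    )
  }
  if (nrow(decoded) == 0) stop("no decoded states supplied")
  decoded |>
    dplyr::arrange(.data$athlete_id, .data$race_index) |>
    dplyr::group_by(.data$athlete_id) |>
    dplyr::reframe({
      r <- rle(.data$state)
      tibble::tibble(state = r$values, length = r$lengths)
    })
}

#' Geometric goodness of fit for sojourn times
#'
#' Fits Geometric(p) to run lengths by maximum likelihood under the support
#' convention L >= 1, P(L = l) = (1-p)^(l-1) p, so p-hat = 1/mean(L). A
#' chi-square goodness-of-fit statistic is computed on binned run lengths
#' with upper-tail bins merged until every expected count is at least 5;
#' degrees of freedom are bins - 2 (one for the estimated p).
#'
#' @param lengths Integer run lengths (>= 1). Fewer than `min_runs` lengths
#'   gives an explicit insufficient-data result rather than a p-value.
#' @param min_runs Minimum number of runs for a test (default 20).
#' @return A list: `p_hat`, `statistic`, `df`, `p_value`, `n_runs`,
#'   `sufficient` (FALSE when the test was not run).
#' @export
geometric_gof <- function(lengths, min_runs = 20) {
  if (any(lengths < 1)) stop("run lengths must be >= 1")
  n <- length(lengths)
  p_hat <- 1 / mean(lengths)
  if (n < min_runs) {
    return(list(
      p_hat = p_hat, statistic = NA_real_, df = NA_real_,
      p_value = NA_real_, n_runs = n, sufficient = FALSE
    ))
  }
  if (p_hat >= 1) {
    # all runs of length 1: the geometric MLE is degenerate at p = 1 and
    # fits the data perfectly
    return(list(
      p_hat = 1, statistic = 0, df = 0, p_value = 1, n_runs = n,
      sufficient = TRUE
    ))
  }
  lmax <- max(lengths)
  probs <- stats::dgeom(0:(lmax - 1), p_hat) # length l has geom count l-1
  probs <- c(probs, 1 - sum(probs)) # tail bin: L > lmax
  expected <- n * probs
  observed <- c(tabulate(lengths, nbins = lmax), 0)
  # merge the upper tail until every expected count reaches 5
  while (length(expected) > 2 && expected[length(expected)] < 5) {
    k <- length(expected)
    expected[k - 1] <- expected[k - 1] + expected[k]
    observed[k - 1] <- observed[k - 1] + observed[k]
    expected <- expected[-k]
    observed <- observed[-k]
  }
  # a short head bin can also fall under 5 when p-hat is extreme
  while (length(expected) > 2 && expected[1] < 5) {
    expected[2] <- expected[2] + expected[1]
    observed[2] <- observed[2] + observed[1]
    expected <- expected[-1]
    observed <- observed[-1]
  }
  df <- length(expected) - 2
  if (df < 1) {
    return(list(
      p_hat = p_hat, statistic = NA_real_, df = df, p_value = NA_real_,
      n_runs = n, sufficient = FALSE
    ))
  }
  stat <- sum((observed - expected)^2 / expected)
  list(
    p_hat = p_hat, statistic = stat, df = df,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE),
    n_runs = n, sufficient = TRUE
  )
}

#' Per-component residual RMSE under the decoded states
#'
#' Residuals are taken against the emission mean of the Viterbi-decoded
#' state at each race's covariates (global decoding, matching the model's
#' reported state assignments): r_t = O_t - m_{s-hat_t}(z_t). The marginal
#' SD of each component is reported alongside for comparison.
#'
#' @param fit A `kayak_hmm` from [em_fit()].
#' @param scores The score tibble the model was fitted to.
#' @return A tibble with one row per PC: `component`, `rmse`, `marginal_sd`.
#' @export
residual_rmse <- function(fit, scores) {
  built <- build_sequences(scores, event = fit$event, use_covariates = fit$use_covariates)
  res <- purrr::map_dfr(built$seqs, function(s) {
    path <- viterbi(fit$params, s$O, s$Z)
    M <- t(vapply(seq_along(path), function(t) {
      z <- if (is.null(s$Z)) numeric(0) else s$Z[t, ]
      emission_mean(fit$params, path[t], z)
    }, numeric(ncol(s$O))))
    tibble::as_tibble(s$O - M)
  })
  O_all <- do.call(rbind, lapply(built$seqs, `[[`, "O"))
  tibble::tibble(
    component = paste0("PC", seq_len(ncol(O_all))),
    rmse = unname(sqrt(colMeans(as.matrix(res)^2))),
    marginal_sd = unname(apply(O_all, 2, stats::sd))
  )
}

#' Career state timelines and summaries
#'
#' Per-athlete ordered timeline of decoded states with covariates, plus the
#' per-athlete state-transition counts and the modal state per age group —
#' the tabular content behind career state plots.
#'
#' @param decoded Decoded states tibble (`athlete_id`, `race_index`,
#'   `state`, and optionally `posterior`), e.g. `fit$posteriors`.
#' @param covariates Tibble with `athlete_id`, `race_index`, `age_group`,
#'   `event_type` to join onto the timeline (e.g. the score tibble).
#' @return A list of tibbles: `timeline`, `transition_counts` (athlete_id,
#'   from, to, n), `modal_state` (athlete_id, age_group, state, n_races).
#' @export
career_summary <- function(decoded, covariates = NULL) {
  timeline <- decoded |>
    dplyr::select(dplyr::any_of(c("athlete_id", "race_index", "state", "posterior"))) |>
    dplyr::arrange(.data$athlete_id, .data$race_index)
  if (!is.null(covariates)) {
    timeline <- dplyr::left_join(
      timeline,
      dplyr::select(
        covariates,
        dplyr::any_of(c("athlete_id", "race_index", "age_group", "event_type"))
      ),
      by = c("athlete_id", "race_index")
    )
  }
  transition_counts <- timeline |>
    dplyr::group_by(.data$athlete_id) |>
    dplyr::reframe({
      s <- .data$state
      if (length(s) > 1) {
        tibble::tibble(from = s[-length(s)], to = s[-1])
      } else {
        tibble::tibble(from = integer(0), to = integer(0))
      }
    }) |>
    dplyr::count(.data$athlete_id, .data$from, .data$to)
  modal_state <- NULL
  if ("age_group" %in% names(timeline)) {
    modal_state <- timeline |>
      dplyr::count(.data$athlete_id, .data$age_group, .data$state, name = "n_races") |>
      dplyr::group_by(.data$athlete_id, .data$age_group) |>
      dplyr::slice_max(.data$n_races, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  list(
    timeline = timeline,
    transition_counts = transition_counts,
    modal_state = modal_state
  )
}

#' Full diagnostics report for a fitted HMM
#'
#' Bundles the sojourn-time geometric tests (one per state), the residual
#' RMSE table, and the AIC into one list; [write_diagnostics_json()] writes
#' it to disk.
#'
#' @param fit A `kayak_hmm`.
#' @param scores The score tibble the model was fitted to.
#' @return A list with elements `sojourn_gof` (tibble, one row per state),
#'   `rmse` and `aic`.
#' @export
hmm_diagnostics <- function(fit, scores) {
  soj <- sojourn_times(fit$posteriors)
  gof <- purrr::map_dfr(sort(unique(soj$state)), function(j) {
    g <- geometric_gof(soj$length[soj$state == j])
    tibble::tibble(
      state = j, n_runs = g$n_runs, p_hat = g$p_hat,
      mean_sojourn = 1 / g$p_hat, statistic = g$statistic,
      df = g$df, p_value = g$p_value, sufficient = g$sufficient
    )
  })
  list(
    sojourn_gof = gof,
    rmse = residual_rmse(fit, scores),
    aic = fit$aic
  )
}

#' @rdname hmm_diagnostics
#' @param diagnostics Result of [hmm_diagnostics()].
#' @param path Output JSON file.
#' @export
write_diagnostics_json <- function(diagnostics, path) {
  jsonlite::write_json(diagnostics, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname hmm_diagnostics
#' @export
format_diagnostics <- function(diagnostics) {
  lines <- c(
    "Sojourn-time geometric goodness of fit (per state):",
    utils::capture.output(print(as.data.frame(diagnostics$sojourn_gof), row.names = FALSE)),
    "",
    "Residual RMSE per component (vs marginal SD):",
    utils::capture.output(print(as.data.frame(diagnostics$rmse), row.names = FALSE)),
    "",
    sprintf("AIC: %.3f", diagnostics$aic)
  )
  paste(lines, collapse = "\n")
}
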