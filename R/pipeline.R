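#' Configure the two-stage analysis pipeline
#'
#' Bundles every stage setting: paths, event, basis size, number of fPCA
#' components, HMM state selection and EM controls, and the optional
#' exclusion list standing in for expert outlier review.
#'
#' @param input_csv Path to the race-record CSV.
#' @param output_dir Directory for all artifacts.
#' @param event Event name.
#' @param K Number of fPCA components kept as HMM observations (default 4).
#' @param n_basis Basis size; default 8 (500 m) or 12 (1000 m).
#' @param n_states Fixed state count, or NULL to scan `state_range` by AIC.
#' @param state_range Candidate state counts for the AIC scan.
#' @param n_restarts EM restarts per fit.
#' @param seed Master seed.
#' @param tol,max_iter EM convergence controls.
#' @param use_covariates Include age-group/event-type effects in the
#'   emission means.
#' @param exclude Optional data frame (`athlete_id`, `race_index`) of races
#'   to drop.
#' @return A `kayak_pipeline_config` list.
#' @export
pipeline_config <- function(input_csv, output_dir, event, K = 4,
                            n_basis = NULL, n_states = 4, state_range = 2:6,
                            n_restarts = 20, seed = 1, tol = 1e-8,
                            max_iter = 500, use_covariates = TRUE,
                            exclude = NULL) {
  info <- event_info(event)
  if (is.null(n_basis)) n_basis <- if (info$n_segments >= 20) 12 else 8
  stopifnot(K >= 1, is.null(n_states) || (n_states >= 1 && n_states <= 10))
  if (!is.null(state_range)) stopifnot(all(state_range >= 1), all(state_range <= 10))
  structure(
    list(
      input_csv = input_csv, output_dir = output_dir, event = info$event,
      K = K, n_basis = n_basis, n_states = n_states,
      state_range = state_range, n_restarts = n_restarts, seed = seed,
      tol = tol, max_iter = max_iter, use_covariates = use_covariates,
      exclude = exclude
    ),
    class = "kayak_pipeline_config"
  )
}

#' Run the full pipeline: filter, normalise, fPCA, HMM, decode, diagnose
#'
#' Executes the two-stage analysis on a race CSV and writes every
#' intermediate artifact as plain CSV/JSON so each stage can be inspected
#' independently: normalised profiles, fPCA model and scores, the fitted HMM
#' (and AIC scan table when a state range is scanned), decoded states,
#' diagnostics, and a run manifest capturing the config, seed and package
#' version. A failing stage aborts with the stage name in the error.
#'
#' @param config A `kayak_pipeline_config`.
#' @return Invisibly, a list with the in-memory results (`profiles`,
#'   `fpca`, `scores`, `fit`, `scan`, `diagnostics`, `files`).
#' @export
run_pipeline <- function(config) {
  out <- config$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  races <- stage("read", read_race_csv(config$input_csv))
  races <- stage("filter", filter_races(races, exclude = config$exclude))
  profiles <- stage("normalise", pacing_profiles(races))
  prof_path <- file.path(out, "profiles.csv")
  utils::write.csv(
    profiles[, c("athlete_id", "race_index", "distance_m", "norm_velocity")],
    prof_path,
    row.names = FALSE
  )
  info <- event_info(config$event)
  basis <- bspline_basis(info$distance_m, config$n_basis)
  fpca <- stage("fpca", fit_fpca(profiles, K = config$K, basis = basis))
  fpca_path <- file.path(out, "fpca_model.json")
  write_fpca_json(fpca, fpca_path)
  scores <- fpca$scores # per-race covariates travel with the scores
  scores_path <- file.path(out, "scores.csv")
  utils::write.csv(scores, scores_path, row.names = FALSE)
  scan <- NULL
  if (is.null(config$n_states)) {
    scan <- stage("select", select_n_states(
      scores, config$state_range,
      event = config$event, use_covariates = config$use_covariates,
      n_restarts = config$n_restarts, seed = config$seed,
      tol = config$tol, max_iter = config$max_iter
    ))
    fit <- scan$best_fit
    utils::write.csv(scan$table, file.path(out, "aic_scan.csv"), row.names = FALSE)
  } else {
    fit <- stage("fit", em_fit(
      scores, config$n_states,
      event = config$event, use_covariates = config$use_covariates,
      n_restarts = config$n_restarts, seed = config$seed,
      tol = config$tol, max_iter = config$max_iter
    ))
  }
  hmm_path <- file.path(out, "hmm_model.json")
  write_hmm_json(fit$params, hmm_path)
  decoded_path <- file.path(out, "decoded_states.csv")
  utils::write.csv(
    fit$posteriors[, c("athlete_id", "race_index", "state", "posterior")],
    decoded_path,
    row.names = FALSE
  )
  diagnostics <- stage("diagnose", hmm_diagnostics(fit, scores))
  diag_path <- file.path(out, "diagnostics.json")
  write_diagnostics_json(diagnostics, diag_path)
  writeLines(format_diagnostics(diagnostics), file.path(out, "diagnostics.txt"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("kayakpace")),
    r_version = R.version.string,
    config = config[setdiff(names(config), "exclude")],
    seed = config$seed,
    n_races_used = dplyr::n_distinct(paste(scores$athlete_id, scores$race_index)),
    loglik = fit$loglik, aic = fit$aic, n_states = fit$params$n_states
  )
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(
    profiles = profiles, fpca = fpca, scores = scores, fit = fit,
    scan = scan, diagnostics = diagnostics,
    files = c(
      profiles = prof_path, fpca = fpca_path, scores = scores_path,
      hmm = hmm_path, decoded = decoded_path, diagnostics = diag_path,
      manifest = manifest_path
    )
  ))
}
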