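#' Plot normalised pacing profiles
#'
#' Spaghetti plot of per-race normalised velocity against distance with the
#' pointwise mean overlaid.
#'
#' @param profiles Tidy profile tibble from [pacing_profiles()].
#' @param max_races Cap on the number of individual races drawn.
#' @return A ggplot.
#' @export
plot_profiles <- function(profiles, max_races = 200) {
  keys <- dplyr::distinct(profiles, .data$athlete_id, .data$race_index)
  if (nrow(keys) > max_races) {
    keys <- keys[seq_len(max_races), ]
    profiles <- dplyr::semi_join(profiles, keys, by = c("athlete_id", "race_index"))
  }
  mp <- mean_profile(profiles)
  ggplot2::ggplot(profiles, ggplot2::aes(.data$distance_m, .data$norm_velocity)) +
    ggplot2::geom_line(
      ggplot2::aes(group = interaction(.data$athlete_id, .data$race_index)),
      alpha = 0.15, colour = "grey40"
    ) +
    ggplot2::geom_line(data = mp, colour = "firebrick", linewidth = 1) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(
      x = "Distance (m)", y = "Normalised velocity",
      title = "Pacing profiles (mean in red)"
    )
}

#' Plot fPCA mean function and eigenfunctions
#'
#' @param object A `kayak_fpca`.
#' @param n_points Evaluation grid resolution.
#' @param ... Unused.
#' @return A ggplot, faceted by component.
#' @export
autoplot.kayak_fpca <- function(object, n_points = 200, ...) {
  xs <- seq(object$basis$domain[1], object$basis$domain[2], length.out = n_points)
  Phi <- eval_fpca(object, xs, "eigenfunctions")
  df <- purrr::map_dfr(seq_len(object$K), function(k) {
    tibble::tibble(
      distance_m = xs, value = Phi[, k],
      component = sprintf("PC%d (%.1f%%)", k, 100 * object$varexp[k])
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$distance_m, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(
      x = "Distance (m)", y = "Eigenfunction",
      title = "Functional principal components"
    )
}

#' Career state timeline plot
#'
#' Decoded state per race across one or more athletes' careers, coloured by
#' age group when available.
#'
#' @param timeline Timeline tibble from [career_summary()].
#' @param athletes Optional athlete ids to keep.
#' @return A ggplot.
#' @export
plot_state_timeline <- function(timeline, athletes = NULL) {
  if (!is.null(athletes)) {
    timeline <- dplyr::filter(timeline, .data$athlete_id %in% athletes)
  }
  aes_pts <- if ("age_group" %in% names(timeline)) {
    ggplot2::aes(.data$race_index, .data$state, colour = .data$age_group)
  } else {
    ggplot2::aes(.data$race_index, .data$state)
  }
  ggplot2::ggplot(timeline, aes_pts) +
    ggplot2::geom_step(ggplot2::aes(group = .data$athlete_id), colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~athlete_id, ncol = 1) +
    ggplot2::scale_y_continuous(breaks = function(l) seq(ceiling(l[1]), floor(l[2]))) +
    ggplot2::labs(
      x = "Race (career order)", y = "Decoded state",
      title = "Career state timeline"
    )
}

#' Sojourn-time histogram with fitted geometric pmf
#'
#' @param sojourns Tibble from [sojourn_times()].
#' @return A ggplot, faceted by state.
#' @export
plot_sojourns <- function(sojourns) {
  fits <- sojourns |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(p_hat = 1 / mean(.data$length), n = dplyr::n(), .groups = "drop")
  lmax <- max(sojourns$length)
  pmf <- purrr::pmap_dfr(fits, function(state, p_hat, n) {
    tibble::tibble(
      state = state, length = seq_len(lmax),
      count = n * stats::dgeom(seq_len(lmax) - 1, p_hat)
    )
  })
  ggplot2::ggplot(sojourns, ggplot2::aes(.data$length)) +
    ggplot2::geom_bar() +
    ggplot2::geom_line(data = pmf, ggplot2::aes(y = .data$count), colour = "firebrick") +
    ggplot2::facet_wrap(~state, scales = "free") +
    ggplot2::labs(
      x = "Sojourn length (races)", y = "Count",
      title = "Sojourn times vs fitted geometric"
    )
}
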