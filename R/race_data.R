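#' Read race records from CSV
#'
#' Expects one row per race with columns `athlete_id`, `race_index`, `event`,
#' `age_group`, `event_type`, `phase` and `split_01`...`split_20` (seconds per
#' 50 m segment; columns 11-20 empty for 500 m races). Records are validated:
#' the split count must match the event distance, every duration must be
#' strictly positive, and U18 is only accepted for the men's 1000 m event.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A tibble of race records in long-checked wide form (one `split_*`
#'   column per segment), as used by [pacing_profiles()].
#' @export
read_race_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  validate_races(tibble::as_tibble(df))
}

split_cols <- function(n) sprintf("split_%02d", seq_len(n))

#' Validate a race-record data frame
#'
#' @param races Data frame with the schema described in [read_race_csv()].
#' @return The input as a tibble, invisibly unchanged apart from type
#'   coercion; stops with an informative error on the first violated record.
#' @export
validate_races <- function(races) {
  races <- tibble::as_tibble(races)
  needed <- c("athlete_id", "race_index", "event", "age_group", "event_type", "phase")
  missing <- setdiff(needed, names(races))
  if (length(missing) > 0) {
    stop("race data is missing column(s): ", paste(missing, collapse = ", "))
  }
  bad_event <- setdiff(unique(races$event), names(kayak_events))
  if (length(bad_event) > 0) {
    stop("unknown event(s): ", paste(bad_event, collapse = ", "))
  }
  for (r in seq_len(nrow(races))) {
    info <- event_info(races$event[r])
    cols <- split_cols(info$n_segments)
    miss <- setdiff(cols, names(races))
    if (length(miss) > 0) {
      stop("record ", r, ": missing split column(s) ", paste(miss, collapse = ", "))
    }
    splits <- as.numeric(races[r, cols])
    bad <- which(!is.finite(splits) | splits <= 0)
    if (length(bad) > 0) {
      stop(
        "record ", r, " (athlete ", races$athlete_id[r], ", race ",
        races$race_index[r], "): non-positive or missing split in segment(s) ",
        paste(bad, collapse = ", ")
      )
    }
    if (races$age_group[r] == "U18" && info$event == "women_k1_500") {
      stop("record ", r, ": U18 is not a valid age group for the Women's K1 500m")
    }
  }
  races
}

#' Convert 50 m split durations to segment velocities
#'
#' Each segment velocity is the segment length divided by its duration,
#' v_i = 50 / dt_i, preserving order.
#'
#' @param split_durations Numeric vector of per-segment durations in seconds.
#' @param segment_m Segment length in metres (50 for this data).
#' @return Numeric vector of velocities in m/s, one per segment.
#' @export
#' @examples
#' compute_segment_velocities(rep(12.5, 10)) # all 4 m/s
compute_segment_velocities <- function(split_durations, segment_m = 50) {
  bad <- which(!is.finite(split_durations) | split_durations <= 0)
  if (length(bad) > 0) {
    stop("non-positive or missing duration in segment(s) ", paste(bad, collapse = ", "))
  }
  segment_m / split_durations
}

#' Normalise segment velocities by the race-average velocity
#'
#' The race-average velocity is total distance over total time (not the
#' unweighted mean of segment velocities; the two differ by ~0.1% on typical
#' profiles). With that convention the time-weighted mean of the normalised
#' values is exactly 1: sum(dt_i * u_i) = total time.
#'
#' @param velocities Segment velocities in m/s.
#' @param split_durations Matching per-segment durations in seconds.
#' @param segment_m Segment length in metres.
#' @return A list with `grid` (segment midpoints in metres), `values`
#'   (normalised velocities, dimensionless) and `race_mean_velocity` (m/s).
#' @export
normalize_profile <- function(velocities, split_durations, segment_m = 50) {
  if (length(velocities) != length(split_durations)) {
    stop(
      "velocities (", length(velocities), ") and durations (",
      length(split_durations), ") differ in length"
    )
  }
  total_dist <- segment_m * length(split_durations)
  vbar <- total_dist / sum(split_durations)
  list(
    grid = segment_m * (seq_along(velocities) - 0.5),
    values = velocities / vbar,
    race_mean_velocity = vbar
  )
}

#' Drop domestic heats (and optional listed outliers) from a race set
#'
#' The analysis removes heat races from domestic competitions; international
#' heats are retained. Expert-judgement outlier removal is supported only as
#' an explicit exclusion list, never an automatic rule. Surviving records are
#' returned unchanged and in their original order.
#'
#' @param races Race-record data frame.
#' @param exclude Optional data frame with columns `athlete_id` and
#'   `race_index` naming individual races to drop.
#' @return Filtered tibble.
#' @export
filter_races <- function(races, exclude = NULL) {
  races <- tibble::as_tibble(races)
  keep <- !(races$event_type == "Domestic" & races$phase == "heat")
  if (!is.null(exclude)) {
    if (!all(c("athlete_id", "race_index") %in% names(exclude))) {
      stop("`exclude` needs columns athlete_id and race_index")
    }
    key <- paste(races$athlete_id, races$race_index, sep = "\r")
    drop <- paste(exclude$athlete_id, exclude$race_index, sep = "\r")
    keep <- keep & !(key %in% drop)
  }
  races[keep, , drop = FALSE]
}

#' Tidy normalised pacing profiles for a set of races
#'
#' Converts validated race records into one row per 50 m segment:
#' `athlete_id`, `race_index`, `distance_m` (segment midpoint),
#' `norm_velocity`, and `race_mean_velocity`, carrying the race covariates
#' along. This is the tidy CSV-ready form consumed by [fit_fpca()].
#'
#' @param races Validated race records (see [read_race_csv()]).
#' @return A tibble, `n_segments` rows per race.
#' @export
pacing_profiles <- function(races) {
  races <- tibble::as_tibble(races)
  if (nrow(races) == 0) {
    return(tibble::tibble(
      athlete_id = character(), race_index = integer(), event = character(),
      age_group = character(), event_type = character(), phase = character(),
      distance_m = numeric(), norm_velocity = numeric(),
      race_mean_velocity = numeric()
    ))
  }
  purrr::map_dfr(seq_len(nrow(races)), function(r) {
    info <- event_info(races$event[r])
    dt <- as.numeric(races[r, split_cols(info$n_segments)])
    v <- compute_segment_velocities(dt)
    prof <- normalize_profile(v, dt)
    tibble::tibble(
      athlete_id = races$athlete_id[r],
      race_index = races$race_index[r],
      event = info$event,
      age_group = races$age_group[r],
      event_type = races$event_type[r],
      phase = races$phase[r],
      distance_m = prof$grid,
      norm_velocity = prof$values,
      race_mean_velocity = prof$race_mean_velocity
    )
  })
}

#' Mean pacing profile across races
#'
#' Pointwise arithmetic mean of normalised velocity over all races sharing a
#' common midpoint grid.
#'
#' @param profiles Tidy profile tibble from [pacing_profiles()].
#' @return A tibble with `distance_m` and `norm_velocity`.
#' @export
mean_profile <- function(profiles) {
  grids <- profiles |>
    dplyr::group_by(.data$athlete_id, .data$race_index) |>
    dplyr::summarise(g = paste(.data$distance_m, collapse = ","), .groups = "drop")
  if (dplyr::n_distinct(grids$g) > 1) {
    stop("profiles are not on a common distance grid")
  }
  profiles |>
    dplyr::group_by(.data$distance_m) |>
    dplyr::summarise(norm_velocity = mean(.data$norm_velocity), .groups = "drop")
}
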