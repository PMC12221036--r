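#' Event, age-group and event-type vocabularies
#'
#' The package models two individual (K1) sprint-kayak events: the Women's K1
#' 500 m and the Men's K1 1000 m. Split times are recorded every 50 m, so a
#' 500 m race contributes 10 segment velocities and a 1000 m race 20.
#'
#' @format `kayak_events` is a named list with one entry per event, each a
#'   list with elements `distance_m`, `n_segments`, `label`, and
#'   `age_groups` (the age-group indicators the emission model uses for that
#'   event; the women's model has no U18 category).
#' @name kayak-vocab
NULL

#' @rdname kayak-vocab
#' @export
kayak_events <- list(
  women_k1_500 = list(
    event = "women_k1_500",
    label = "Women's K1 500m",
    distance_m = 500,
    n_segments = 10L,
    age_groups = c("U21", "U23")
  ),
  men_k1_1000 = list(
    event = "men_k1_1000",
    label = "Men's K1 1000m",
    distance_m = 1000,
    n_segments = 20L,
    age_groups = c("U18", "U21", "U23")
  )
)

#' @rdname kayak-vocab
#' @export
kayak_age_groups <- c("U18", "U21", "U23", "Open")

#' @rdname kayak-vocab
#' @export
kayak_event_types <- c("Domestic", "WorldCupJuniors", "WorldChampsOlympics")

#' @rdname kayak-vocab
#' @export
kayak_phases <- c("heat", "semi", "final")

event_info <- function(event) {
  event <- match.arg(event, names(kayak_events))
  kayak_events[[event]]
}

#' Covariate indicator names for an event's emission model
#'
#' The emission means are linear in 0/1 indicators relative to the baseline
#' of a Domestic race in the Open age group. The women's model uses four
#' indicators (U21, U23, World Cup/Juniors, World Champs/Olympics); the
#' men's adds U18.
#'
#' @param event `"women_k1_500"` or `"men_k1_1000"`.
#' @return Character vector of indicator names, in model order.
#' @export
covariate_names <- function(event) {
  info <- event_info(event)
  c(info$age_groups, "WorldCupJuniors", "WorldChampsOlympics")
}

#' Build the covariate indicator matrix from race metadata
#'
#' @param data A data frame with columns `age_group` and `event_type`.
#' @param event Event name; decides whether a U18 indicator exists.
#' @return A numeric matrix, one row per row of `data`, columns named as
#'   [covariate_names()].
#' @export
covariate_matrix <- function(data, event) {
  nms <- covariate_names(event)
  missing <- setdiff(c("age_group", "event_type"), names(data))
  if (length(missing) > 0) {
    stop("covariate data is missing column(s): ", paste(missing, collapse = ", "))
  }
  age <- as.character(data$age_group)
  type <- as.character(data$event_type)
  bad_age <- setdiff(unique(age), kayak_age_groups)
  if (length(bad_age) > 0) {
    stop("unknown age group(s): ", paste(bad_age, collapse = ", "))
  }
  if (event_info(event)$event == "women_k1_500" && any(age == "U18")) {
    stop("age group U18 is not defined for the Women's K1 500m model")
  }
  bad_type <- setdiff(unique(type), kayak_event_types)
  if (length(bad_type) > 0) {
    stop("unknown event type(s): ", paste(bad_type, collapse = ", "))
  }
  Z <- sapply(nms, function(nm) {
    if (nm %in% kayak_age_groups) as.numeric(age == nm) else as.numeric(type == nm)
  })
  Z <- matrix(Z, nrow = nrow(data), dimnames = list(NULL, nms))
  Z
}
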