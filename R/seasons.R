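#' Season structure for a robust-design survey
#'
#' Builds the primary/secondary sampling structure of a camera-trap survey:
#' an alternating sequence of summer and winter seasons (primary periods),
#' each comprising a fixed number of survey months (secondary periods).
#' The latent use state is assumed closed within a season and may change
#' only between consecutive seasons.
#'
#' @param n_summer number of summer seasons.
#' @param n_winter number of winter seasons.
#' @param summer_len months per summer season.
#' @param winter_len months per winter season.
#' @param first label of the first season, `"summer"` or `"winter"`.
#'
#' @return An object of class `season_structure`: a list with components
#'   `n_seasons`, `labels` (character vector of `"summer"`/`"winter"`),
#'   `months_per_season` (integer vector), `n_months`, and the month maps
#'   `month_season` and `month_within` (season index and within-season
#'   month index of every global month, 1-based).
#'
#' @examples
#' s <- season_structure(11, 11, 6, 4)
#' s$n_seasons  # 22
#' s$n_months   # 110
#' @export
season_structure <- function(n_summer, n_winter, summer_len = 6L,
                             winter_len = 4L,
                             first = c("summer", "winter")) {
  first <- match.arg(first)
  for (v in c(n_summer = n_summer, n_winter = n_winter,
              summer_len = summer_len, winter_len = winter_len)) {
    if (length(v) != 1L || !is.finite(v) || v < 1 || v != round(v)) {
      stop("season counts and lengths must be positive integers", call. = FALSE)
    }
  }
  n_summer <- as.integer(n_summer); n_winter <- as.integer(n_winter)
  if (abs(n_summer - n_winter) > 1L) {
    stop("seasons alternate: summer and winter counts may differ by at most 1",
         call. = FALSE)
  }
  n <- n_summer + n_winter
  labels <- character(n)
  other <- if (first == "summer") "winter" else "summer"
  labels[seq(1L, n, by = 2L)] <- first
  if (n > 1L) labels[seq(2L, n, by = 2L)] <- other
  if (sum(labels == "summer") != n_summer) {
    stop("cannot alternate ", n_summer, " summers and ", n_winter,
         " winters starting from ", first, call. = FALSE)
  }
  lens <- ifelse(labels == "summer", summer_len, winter_len)
  new_season_structure(labels, as.integer(lens))
}

#' Season structure from explicit labels and lengths
#'
#' Lower-level constructor used when reading a season table from file; the
#' default [season_structure()] enforces alternation, this one accepts any
#' label sequence.
#'
#' @param labels character vector of `"summer"`/`"winter"` labels, one per
#'   primary season.
#' @param months_per_season integer vector of months per season.
#' @return A `season_structure` object.
#' @export
new_season_structure <- function(labels, months_per_season) {
  labels <- as.character(labels)
  months_per_season <- as.integer(months_per_season)
  if (length(labels) != length(months_per_season)) {
    stop("labels and months_per_season must have the same length", call. = FALSE)
  }
  if (!all(labels %in% c("summer", "winter"))) {
    stop("season labels must be 'summer' or 'winter'", call. = FALSE)
  }
  if (any(months_per_season < 1L)) {
    stop("every season needs at least one month", call. = FALSE)
  }
  n <- length(labels)
  structure(list(
    n_seasons = n,
    labels = labels,
    months_per_season = months_per_season,
    n_months = sum(months_per_season),
    month_season = rep.int(seq_len(n), months_per_season),
    month_within = unlist(lapply(months_per_season, seq_len), use.names = FALSE)
  ), class = "season_structure")
}

#' @export
print.season_structure <- function(x, ...) {
  cat("Season structure: ", x$n_seasons, " primary seasons (",
      sum(x$labels == "summer"), " summer, ", sum(x$labels == "winter"),
      " winter), ", x$n_months, " survey months\n", sep = "")
  invisible(x)
}

# month -> (season, within-season month) map as a two-column matrix
month_map <- function(seasons) {
  cbind(season = seasons$month_season, month = seasons$month_within)
}
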