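# Per-trip summary statistics and period grouping.

#' Summarise one trip
#'
#' Duration spans the fixes outside the colony radius (departure = first fix
#' beyond the radius, return = last); total distance is the sum of
#' consecutive-fix great-circle distances over the whole trip; maximum range
#' the largest distance from the colony. Departure and return times are
#' reported as local clock hours (decimal) using the configured UTC offset.
#'
#' @param trip Single-trip fix tibble (with boundary fixes) carrying a
#'   `complete` flag column.
#' @param colony A [colony_site()].
#' @param colony_radius_m Colony radius in metres (default 500).
#' @param utc_offset_h Local-time offset from UTC in hours (default +3).
#' @return One-row tibble: `trip_id`, `bird_id`, `age_class`, `complete`,
#'   `duration_h`, `total_distance_km`, `max_range_km`, `departure_time`,
#'   `return_time` (local clock hours), `departure_t` (POSIXct, for period
#'   assignment).
#' @export
summarise_trip <- function(trip, colony, colony_radius_m = 500,
                           utc_offset_h = 3) {
  n <- nrow(trip)
  rng <- haversine_m(trip$lat, trip$lon, colony$lat, colony$lon)
  out <- which(rng > colony_radius_m)
  if (length(out) == 0) out <- seq_len(n)
  dep <- trip$t[out[1]]
  ret <- trip$t[out[length(out)]]
  step_km <- if (n > 1) {
    sum(haversine_m(trip$lat[-n], trip$lon[-n],
                    trip$lat[-1], trip$lon[-1])) / 1000
  } else 0
  local_hour <- function(t) {
    tl <- t + utc_offset_h * 3600
    as.numeric(difftime(tl, trunc(tl, "days"), units = "hours"))
  }
  tibble::tibble(
    trip_id = trip$trip_id[1],
    bird_id = trip$bird_id[1],
    age_class = trip$age_class[1],
    complete = isTRUE(trip$complete[1]),
    duration_h = as.numeric(difftime(ret, dep, units = "hours")),
    total_distance_km = step_km,
    max_range_km = max(rng) / 1000,
    departure_time = local_hour(dep),
    return_time = local_hour(ret),
    departure_t = dep
  )
}

#' Summarise every trip of a long trip tibble
#'
#' @param trips Long tibble from [split_trips()] (several birds allowed).
#' @inheritParams summarise_trip
#' @param periods Optional period table (see [assign_period()]); when given,
#'   a `period` column is added from each trip's departure time.
#' @return Tibble with one row per trip.
#' @export
summarise_trips <- function(trips, colony, colony_radius_m = 500,
                            utc_offset_h = 3, periods = NULL) {
  if (nrow(trips) == 0) {
    out <- summarise_trip(
      tibble::tibble(trip_id = "x", bird_id = "x", age_class = "juvenile",
                     complete = TRUE,
                     t = as.POSIXct("2014-02-01", tz = "UTC"),
                     lat = colony$lat, lon = colony$lon),
      colony, colony_radius_m, utc_offset_h)[0, ]
  } else {
    out <- dplyr::bind_rows(lapply(split(trips, trips$trip_id),
                                   summarise_trip, colony = colony,
                                   colony_radius_m = colony_radius_m,
                                   utc_offset_h = utc_offset_h))
  }
  if (!is.null(periods)) {
    out$period <- assign_period(out$departure_t, periods, utc_offset_h)
  }
  out
}

#' The study's three 12-day monitoring periods
#'
#' P1: 27 Jan - 7 Feb 2014, P2: 8 - 19 Feb 2014, P3: 20 Feb - 4 Mar 2014.
#'
#' @return Tibble with columns `period`, `start`, `end` (Dates, inclusive).
#' @export
paper_periods <- function() {
  tibble::tibble(
    period = c("P1", "P2", "P3"),
    start = as.Date(c("2014-01-27", "2014-02-08", "2014-02-20")),
    end = as.Date(c("2014-02-07", "2014-02-19", "2014-03-04"))
  )
}

#' Assign timestamps to monitoring periods
#'
#' @param t POSIXct vector (UTC).
#' @param periods Period table with disjoint inclusive date ranges
#'   (default [paper_periods()]).
#' @param utc_offset_h Offset applied before taking the calendar date.
#' @return Character vector of period ids (NA outside all ranges).
#' @export
assign_period <- function(t, periods = paper_periods(), utc_offset_h = 3) {
  periods <- periods[order(periods$start), ]
  if (any(periods$start > periods$end)) {
    stop("period start after end", call. = FALSE)
  }
  if (nrow(periods) > 1 &&
      any(periods$start[-1] <= periods$end[-nrow(periods)])) {
    stop("period ranges overlap", call. = FALSE)
  }
  d <- as.Date(t + utc_offset_h * 3600, tz = "UTC")
  out <- rep(NA_character_, length(t))
  for (i in seq_len(nrow(periods))) {
    hit <- d >= periods$start[i] & d <= periods$end[i]
    out[hit] <- periods$period[i]
  }
  out
}

#' Mean +/- SD trip metrics per group
#'
#' @param summaries Trip-summary tibble from [summarise_trips()].
#' @param by Grouping columns (default period x age class).
#' @param metrics Metric columns to summarise.
#' @return Tidy tibble: group columns, `metric`, `mean`, `sd` (0 for a single
#'   trip), `n`.
#' @export
group_summaries <- function(summaries,
                            by = c("age_class", "period"),
                            metrics = c("duration_h", "total_distance_km",
                                        "max_range_km")) {
  summaries |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "metric")))) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
      n = dplyr::n(),
      .groups = "drop"
    )
}
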