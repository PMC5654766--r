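# Track cleaning, regularisation and trip delimitation.
#
# The cleaning order mirrors the field-data workflow: implied-speed filter on
# the raw fixes, linear interpolation onto a regular grid, then splitting at
# a colony-radius threshold into central-place trips. The maximum-speed rule
# is a *filter* (fixes whose implied speed from the last retained fix exceeds
# the cap are removed), not a value cap: capping would fabricate positions.

#' Remove fixes implying unrealistic speeds
#'
#' Forward pass over a time-sorted single-bird track: a fix is dropped when
#' the speed implied from the last *retained* fix exceeds `vmax_kmh`. The
#' output therefore has all consecutive implied speeds at or below the cap.
#'
#' @param track Single-bird fix tibble, time-sorted.
#' @param vmax_kmh Maximum plausible speed in km/h (default 90).
#' @return The filtered track; the number of removed fixes is reported via
#'   `message()` when positive and attached as attribute `n_removed`.
#' @export
filter_speed <- function(track, vmax_kmh = 90) {
  n <- nrow(track)
  if (n < 2) return(track)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- 1L
  tt <- as.numeric(track$t)
  for (i in 2:n) {
    dt_h <- (tt[i] - tt[last]) / 3600
    d_km <- haversine_m(track$lat[last], track$lon[last],
                        track$lat[i], track$lon[i]) / 1000
    if (d_km / dt_h <= vmax_kmh) {
      keep[i] <- TRUE
      last <- i
    }
  }
  removed <- sum(!keep)
  if (removed > 0) {
    message(removed, " fix(es) removed by the ", vmax_kmh, " km/h filter for ",
            track$bird_id[1])
  }
  out <- track[keep, ]
  attr(out, "n_removed") <- removed
  out
}

#' Linearly interpolate a track onto a regular time grid
#'
#' Output timestamps form an arithmetic grid of `step_s` seconds anchored at
#' the first fix; latitude and longitude are interpolated linearly between
#' bracketing fixes. The grid never extends beyond the last fix, so the
#' operation never extrapolates, and a track already on the grid is returned
#' unchanged up to floating point.
#'
#' @param track Single-bird fix tibble with at least 2 fixes.
#' @param step_s Grid step in seconds (default 120, the analysis grid).
#' @return Interpolated fix tibble.
#' @export
interpolate_track <- function(track, step_s = 120) {
  if (nrow(track) < 2) {
    stop("cannot interpolate a track with fewer than 2 fixes", call. = FALSE)
  }
  tt <- as.numeric(track$t)
  grid <- seq(tt[1], tt[length(tt)], by = step_s)
  tibble::tibble(
    bird_id = track$bird_id[1],
    age_class = track$age_class[1],
    t = as.POSIXct(grid, tz = "UTC",
                   origin = as.POSIXct("1970-01-01", tz = "UTC")),
    lat = stats::approx(tt, track$lat, xout = grid)$y,
    lon = stats::approx(tt, track$lon, xout = grid)$y
  )
}

#' Split a track into central-place trips
#'
#' A trip is a maximal run of fixes beyond `colony_radius_m` of the colony
#' point, extended by one boundary fix on each side where available. Trips
#' whose excursion touches the start or end of the track are flagged
#' incomplete.
#'
#' @param track Single-bird (cleaned, interpolated) fix tibble.
#' @param colony A [colony_site()].
#' @param colony_radius_m Colony radius in metres (default 500).
#' @return A tibble of trip fixes with added columns `trip_id` and
#'   `complete`; zero rows when the bird never leaves the radius.
#' @export
split_trips <- function(track, colony, colony_radius_m = 500) {
  n <- nrow(track)
  empty <- dplyr::mutate(track[0, ], trip_id = character(),
                         complete = logical())
  if (n == 0) return(empty)
  out <- haversine_m(track$lat, track$lon, colony$lat, colony$lon) >
    colony_radius_m
  r <- rle(out)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- which(r$values)
  if (length(k) == 0) return(empty)
  trips <- lapply(seq_along(k), function(q) {
    s <- starts[k[q]]; e <- ends[k[q]]
    complete <- s > 1 && e < n
    rows <- track[max(1, s - 1):min(n, e + 1), ]
    dplyr::mutate(rows,
                  trip_id = sprintf("%s_T%02d", track$bird_id[1], q),
                  complete = complete)
  })
  dplyr::bind_rows(trips)
}

#' Flag outlier and incomplete trips
#'
#' Nothing is deleted: trips whose duration falls outside the configured
#' bounds, and incomplete trips, are flagged `excluded` for downstream
#' summaries.
#'
#' @param trips Long trip tibble from [split_trips()] (possibly several
#'   birds bound together).
#' @param duration_bounds_h Length-2 numeric, inclusive duration bounds in
#'   hours.
#' @return One row per trip: `trip_id`, `bird_id`, `age_class`, `duration_h`,
#'   `complete`, `excluded`.
#' @export
flag_outlier_trips <- function(trips, duration_bounds_h = c(0, 24)) {
  stopifnot(length(duration_bounds_h) == 2,
            duration_bounds_h[1] <= duration_bounds_h[2])
  if (nrow(trips) == 0) {
    return(tibble::tibble(trip_id = character(), bird_id = character(),
                          age_class = character(), duration_h = numeric(),
                          complete = logical(), excluded = logical()))
  }
  trips |>
    dplyr::group_by(.data$trip_id) |>
    dplyr::summarise(
      bird_id = .data$bird_id[1],
      age_class = .data$age_class[1],
      duration_h = as.numeric(difftime(max(.data$t), min(.data$t),
                                       units = "hours")),
      complete = .data$complete[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(excluded = !.data$complete |
                    .data$duration_h < duration_bounds_h[1] |
                    .data$duration_h > duration_bounds_h[2])
}
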