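# Geodesy primitives and fix-table I/O shared by every pipeline stage.
#
# Unit convention used throughout the package: coordinates are signed decimal
# degrees (WGS84), internal distances metres, speeds km/h, angles radians,
# timestamps POSIXct in UTC. Distances are great-circle on a sphere of radius
# 6,371 km; all proximity thresholds in this domain are coarse (tens to
# hundreds of metres), so the ellipsoid correction is irrelevant.

EARTH_RADIUS_M <- 6371000
DEG2RAD <- pi / 180

# metres of one degree in the local flat approximation used by the simulator
# and the hull/kernel projections
M_PER_DEG <- 111320

validate_coords <- function(lat, lon) {
  if (length(lat) != length(lon)) {
    stop("lat and lon must have the same length", call. = FALSE)
  }
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (any(lat < -90 | lat > 90)) {
    stop("latitude out of range [-90, 90]", call. = FALSE)
  }
  if (any(lon < -180 | lon > 180)) {
    stop("longitude out of range [-180, 180]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of radius 6,371,000 m. Vectorised over all
#' four arguments with the usual recycling rules.
#'
#' @param lat1,lon1 First point(s), decimal degrees WGS84.
#' @param lat2,lon2 Second point(s), decimal degrees WGS84.
#' @return Numeric vector of distances in metres.
#' @examples
#' haversine_m(0, 0, 0, 1) # one degree of longitude at the equator
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  validate_coords(lat1, lon1)
  validate_coords(lat2, lon2)
  phi1 <- lat1 * DEG2RAD
  phi2 <- lat2 * DEG2RAD
  dphi <- (lat2 - lat1) * DEG2RAD
  dlam <- (lon2 - lon1) * DEG2RAD
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
}

#' Initial great-circle bearing
#'
#' Bearing from the first point towards the second, in radians clockwise from
#' north, in (-pi, pi]. Undefined (NA) for coincident points.
#'
#' @inheritParams haversine_m
#' @return Numeric vector of bearings in radians.
#' @export
initial_bearing <- function(lat1, lon1, lat2, lon2) {
  validate_coords(lat1, lon1)
  validate_coords(lat2, lon2)
  phi1 <- lat1 * DEG2RAD
  phi2 <- lat2 * DEG2RAD
  dlam <- (lon2 - lon1) * DEG2RAD
  y <- sin(dlam) * cos(phi2)
  x <- cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam)
  b <- atan2(y, x)
  b[x == 0 & y == 0] <- NA_real_
  b
}

#' Absolute turning angle between two bearings
#'
#' Folds the difference between an incoming and an outgoing bearing to
#' `[0, pi]`; the analysis only uses the magnitude of a turn, never its sign.
#'
#' @param b_in,b_out Bearings in radians.
#' @return Absolute turning angle(s) in `[0, pi]`.
#' @export
turn_angle <- function(b_in, b_out) {
  d <- abs(b_out - b_in) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Colony reference point
#'
#' The central place all trips start and end at. Defaults to the study colony
#' at 22.3 deg S, 40.3 deg E.
#'
#' @param lat,lon Colony coordinates in decimal degrees.
#' @param nests Optional tibble of per-bird nest coordinates with columns
#'   `bird_id`, `lat`, `lon`.
#' @return A list with elements `lat`, `lon`, `nests` (class `colony_site`).
#' @export
colony_site <- function(lat = -22.3, lon = 40.3, nests = NULL) {
  validate_coords(lat, lon)
  if (!is.null(nests)) {
    stopifnot(all(c("bird_id", "lat", "lon") %in% names(nests)))
    validate_coords(nests$lat, nests$lon)
  }
  structure(list(lat = lat, lon = lon, nests = nests), class = "colony_site")
}

#' @export
print.colony_site <- function(x, ...) {
  cat(sprintf("<colony_site> %.4f, %.4f (%d nests)\n",
              x$lat, x$lon, if (is.null(x$nests)) 0L else nrow(x$nests)))
  invisible(x)
}

fix_columns <- c("bird_id", "age_class", "t", "lat", "lon")

empty_fixes <- function() {
  tibble::tibble(
    bird_id = character(),
    age_class = character(),
    t = as.POSIXct(character(), tz = "UTC"),
    lat = numeric(),
    lon = numeric()
  )
}

#' Validate, sort and deduplicate a fix table
#'
#' Ensures the five canonical columns are present, coordinates are in range,
#' age classes are known, fixes are time-sorted within bird, and duplicate
#' timestamps within a bird are dropped (a warning reports how many).
#'
#' @param fixes A data frame with columns `bird_id`, `age_class`, `t`
#'   (POSIXct, UTC), `lat`, `lon`.
#' @return A validated tibble sorted by bird and time.
#' @export
as_fix_table <- function(fixes) {
  missing <- setdiff(fix_columns, names(fixes))
  if (length(missing)) {
    stop("fix table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fixes <- tibble::as_tibble(fixes)[fix_columns]
  if (nrow(fixes) == 0) return(empty_fixes())
  if (!inherits(fixes$t, "POSIXct")) {
    stop("column t must be POSIXct", call. = FALSE)
  }
  validate_coords(fixes$lat, fixes$lon)
  bad_age <- setdiff(unique(fixes$age_class), c("juvenile", "adult"))
  if (length(bad_age)) {
    stop("unknown age_class value(s): ", paste(bad_age, collapse = ", "),
         call. = FALSE)
  }
  fixes <- fixes[order(fixes$bird_id, fixes$t), ]
  dup <- duplicated(fixes[c("bird_id", "t")])
  if (any(dup)) {
    warning(sum(dup), " duplicate-timestamp fix(es) dropped", call. = FALSE)
    fixes <- fixes[!dup, ]
  }
  fixes
}

#' Read a GPS fix table from CSV
#'
#' Reads a CSV with a header row, renames the configured columns to the
#' package's canonical names, parses ISO-8601 timestamps as UTC, sorts each
#' bird's track by time and drops duplicated timestamps with a warning.
#'
#' @param path CSV file path.
#' @param columns Named character vector mapping canonical names
#'   (`bird_id`, `age_class`, `timestamp`, `lat`, `lon`) to the column names
#'   used in the file.
#' @return A fix tibble (see [as_fix_table()]).
#' @export
read_fix_table <- function(path,
                           columns = c(bird_id = "bird_id",
                                       age_class = "age_class",
                                       timestamp = "timestamp",
                                       lat = "lat", lon = "lon")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    stop("empty fix file: ", path, call. = FALSE)
  }
  missing <- setdiff(unname(columns), names(raw))
  if (length(missing)) {
    stop("fix file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0) return(empty_fixes())
  raw_ts <- as.character(raw[[columns[["timestamp"]]]])
  ts <- as.POSIXct(rep(NA_real_, length(raw_ts)), tz = "UTC",
                   origin = as.POSIXct("1970-01-01", tz = "UTC"))
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")) {
    miss <- is.na(ts)
    if (!any(miss)) break
    ts[miss] <- as.POSIXct(strptime(raw_ts[miss], fmt, tz = "UTC"))
  }
  if (any(is.na(ts))) {
    stop(sum(is.na(ts)), " unparsable timestamp(s) in ", path, call. = FALSE)
  }
  as_fix_table(tibble::tibble(
    bird_id = as.character(raw[[columns[["bird_id"]]]]),
    age_class = as.character(raw[[columns[["age_class"]]]]),
    t = ts,
    lat = as.numeric(raw[[columns[["lat"]]]]),
    lon = as.numeric(raw[[columns[["lon"]]]])
  ))
}

#' Write a fix table to CSV
#'
#' Inverse of [read_fix_table()]: `read_fix_table(write_fix_table(x, p))`
#' recovers `x` up to floating-point formatting.
#'
#' @param fixes A fix tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fix_table <- function(fixes, path) {
  fixes <- if (nrow(fixes)) as_fix_table(fixes) else empty_fixes()
  out <- data.frame(
    bird_id = fixes$bird_id,
    age_class = fixes$age_class,
    timestamp = format(fixes$t, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    lat = sprintf("%.10f", fixes$lat),
    lon = sprintf("%.10f", fixes$lon)
  )
  if (nrow(out) == 0) {
    out <- data.frame(bird_id = character(), age_class = character(),
                      timestamp = character(), lat = character(),
                      lon = character())
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
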