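# Area-restricted search (ARS) zones and kernel utilisation areas.
#
# An ARS zone starts from a run of at least 3 consecutive fixes labelled
# intensive foraging; runs separated by fewer than 4 fixes of other
# behaviours are merged transitively (sub-threshold foraging runs are
# discarded before merging and cannot be resurrected by the gap rule). Zone
# surface is the convex-hull area of the member fixes in a local
# equirectangular metre projection — the original surface method is
# unpublished, the hull is chosen for determinism.

#' Segment runs of intensive foraging
#'
#' Maximal runs of consecutive `intensive_foraging` labels of length at least
#' `min_run` (NA labels break runs).
#'
#' @param labels Character vector of behaviour labels along one trip.
#' @param min_run Minimum run length (default 3).
#' @return Tibble with `start` and `end` fix indices (possibly zero rows).
#' @export
segment_ars <- function(labels, min_run = 3) {
  is_if <- !is.na(labels) & labels == "intensive_foraging"
  r <- rle(is_if)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- which(r$values & r$lengths >= min_run)
  tibble::tibble(start = starts[k], end = ends[k])
}

#' Merge nearby ARS runs
#'
#' Consecutive runs separated by fewer than `max_gap + 1` fixes labelled with
#' another behaviour are merged transitively; a merged zone spans from the
#' first to the last member fix, gap fixes included. Fixes of sub-threshold
#' intensive-foraging runs inside a gap do not count towards the gap size
#' (they are not "another behaviour").
#'
#' @param runs Tibble from [segment_ars()].
#' @param labels The label vector the runs were segmented from.
#' @param max_gap Maximum number of other-behaviour fixes bridged (default 3,
#'   i.e. "fewer than 4").
#' @return Tibble with `start`, `end` of the merged zones.
#' @export
merge_ars <- function(runs, labels, max_gap = 3) {
  if (nrow(runs) <= 1) return(runs)
  is_if <- !is.na(labels) & labels == "intensive_foraging"
  starts <- runs$start
  ends <- runs$end
  out_s <- starts[1]
  out_e <- ends[1]
  for (i in 2:nrow(runs)) {
    gap_idx <- seq(out_e[length(out_e)] + 1, starts[i] - 1)
    n_other <- sum(!is_if[gap_idx])
    if (n_other <= max_gap) {
      out_e[length(out_e)] <- ends[i]
    } else {
      out_s <- c(out_s, starts[i])
      out_e <- c(out_e, ends[i])
    }
  }
  tibble::tibble(start = out_s, end = out_e)
}

# local equirectangular projection (metres) about a reference point
project_local <- function(lat, lon, lat0 = mean(lat), lon0 = mean(lon)) {
  cbind(x = (lon - lon0) * M_PER_DEG * cos(lat0 * DEG2RAD),
        y = (lat - lat0) * M_PER_DEG)
}

# convex hull area via the shoelace formula, 0 for degenerate hulls
hull_area_m2 <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) < 3) return(0)
  h <- grDevices::chull(xy)
  px <- xy[h, 1]; py <- xy[h, 2]
  abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2
}

#' Summarise an ARS zone
#'
#' Centroid is the coordinate-wise median of the member fixes; duration the
#' time span of the zone; range the great-circle distance from the centroid
#' to the colony; surface the convex-hull area of the member fixes in a
#' local metre projection (0 for collinear or coincident fixes).
#'
#' @param zone_fixes Fix tibble rows belonging to one merged zone.
#' @param colony A [colony_site()].
#' @return One-row tibble: `start`, `end`, `n_fixes`, `centroid_lat`,
#'   `centroid_lon`, `duration_min`, `range_km`, `surface_km2`.
#' @export
ars_metrics <- function(zone_fixes, colony) {
  clat <- stats::median(zone_fixes$lat)
  clon <- stats::median(zone_fixes$lon)
  tibble::tibble(
    start = min(zone_fixes$t),
    end = max(zone_fixes$t),
    n_fixes = nrow(zone_fixes),
    centroid_lat = clat,
    centroid_lon = clon,
    duration_min = as.numeric(difftime(max(zone_fixes$t), min(zone_fixes$t),
                                       units = "mins")),
    range_km = haversine_m(clat, clon, colony$lat, colony$lon) / 1000,
    surface_km2 = hull_area_m2(project_local(zone_fixes$lat,
                                             zone_fixes$lon)) / 1e6
  )
}

#' ARS table for a set of labelled trips
#'
#' Runs segmentation, merging and per-zone metrics over every trip of a long
#' labelled tibble.
#'
#' @param labelled Long labelled-trip tibble (columns `trip_id`, `bird_id`,
#'   `behaviour`, coordinates, time).
#' @param colony A [colony_site()].
#' @param min_run,max_gap Segmentation parameters (defaults 3 and 3).
#' @return Tibble with one row per ARS zone (`bird_id`, `trip_id`, zone
#'   metrics).
#' @export
ars_table <- function(labelled, colony, min_run = 3, max_gap = 3) {
  per_trip <- lapply(split(labelled, labelled$trip_id), function(tr) {
    zones <- merge_ars(segment_ars(tr$behaviour, min_run), tr$behaviour,
                       max_gap)
    if (nrow(zones) == 0) return(NULL)
    dplyr::bind_rows(lapply(seq_len(nrow(zones)), function(i) {
      m <- ars_metrics(tr[zones$start[i]:zones$end[i], ], colony)
      dplyr::mutate(m, bird_id = tr$bird_id[1], trip_id = tr$trip_id[1],
                    .before = 1)
    }))
  })
  out <- dplyr::bind_rows(per_trip)
  if (nrow(out) == 0) {
    out <- tibble::tibble(bird_id = character(), trip_id = character(),
                          start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          n_fixes = integer(), centroid_lat = numeric(),
                          centroid_lon = numeric(), duration_min = numeric(),
                          range_km = numeric(), surface_km2 = numeric())
  }
  out
}

#' ARS rate of a trip
#'
#' @param n_zones Number of ARS zones on the trip.
#' @param duration_h Trip duration in hours (> 0).
#' @return Zones per hour.
#' @export
ars_rate <- function(n_zones, duration_h) {
  if (any(duration_h <= 0)) stop("trip duration must be positive",
                                 call. = FALSE)
  n_zones / duration_h
}

#' Kernel utilisation-distribution areas
#'
#' Points are projected to a local metric plane about their centroid and
#' smoothed with a bivariate normal kernel using the reference bandwidth
#' h = sigma * n^(-1/6) per axis (sigma = mean of the two axis standard
#' deviations) on a regular grid covering the data plus 3 bandwidths. The
#' area of an isopleth is the number of grid cells inside the smallest
#' density region holding that share of the total mass, times the cell area.
#'
#' @param lat,lon Point coordinates (ARS member fixes by default in the
#'   pipeline; centroids are a configurable alternative).
#' @param isopleths Percent levels (default 50 and 95).
#' @param grid_n Grid resolution per axis (default 256).
#' @return Named numeric vector of areas in km2, one per isopleth.
#' @export
kernel_ud <- function(lat, lon, isopleths = c(50, 95), grid_n = 256) {
  n <- length(lat)
  if (n < 5) stop("kernel UD needs at least 5 points", call. = FALSE)
  xy <- project_local(lat, lon)
  sigma <- (stats::sd(xy[, 1]) + stats::sd(xy[, 2])) / 2
  if (sigma == 0) stop("degenerate point cloud (zero spread)", call. = FALSE)
  h <- sigma * n^(-1 / 6)
  # MASS::kde2d uses h/4 as the normal-kernel sd
  dens <- MASS::kde2d(xy[, 1], xy[, 2], h = 4 * h, n = grid_n,
                      lims = c(range(xy[, 1]) + c(-3, 3) * h,
                               range(xy[, 2]) + c(-3, 3) * h))
  cell <- diff(dens$x[1:2]) * diff(dens$y[1:2])
  mass <- sort(as.numeric(dens$z) * cell, decreasing = TRUE)
  mass <- mass / sum(mass)
  cum <- cumsum(mass)
  areas <- vapply(isopleths, function(p) {
    k <- which(cum >= p / 100)[1]
    k * cell / 1e6
  }, numeric(1))
  stats::setNames(areas, as.character(isopleths))
}
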