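# Dyadic at-sea association detection.
#
# Two birds' fixes form an association event when both coordinate
# differences are strictly below 0.002 degrees and the fixes are at most
# 30 s apart (strict degree thresholds, inclusive time threshold — the
# published wording reads "lower than 0.002" but "within ... 30 s").
# Detection runs on the raw (speed-filtered, non-interpolated) tracks: on
# the 2-min analysis grid a 30-s window would only ever match simultaneous
# grid points.

# sorted time-window join: all (i, j) with |ta[i] - tb[j]| <= dt_s
time_window_join <- function(ta, tb, dt_s) {
  lo <- findInterval(ta - dt_s, tb, left.open = TRUE) + 1L
  hi <- findInterval(ta + dt_s, tb)
  cnt <- pmax(hi - lo + 1L, 0L)
  keep <- which(cnt > 0L)
  if (length(keep) == 0) return(data.frame(i = integer(), j = integer()))
  data.frame(
    i = rep(keep, cnt[keep]),
    j = sequence(cnt[keep]) + rep(lo[keep] - 1L, cnt[keep])
  )
}

#' Detect association events between two tracks
#'
#' Time-window sort-merge join (never a full temporal cross-product)
#' followed by the strict per-axis degree rule. Each fix of one track may
#' match several fixes of the other inside the window; events are unique per
#' fix pair.
#'
#' @param track_a,track_b Fix tibbles of two different birds, time-sorted.
#' @param dlat,dlon Strict degree thresholds (default 0.002).
#' @param dt_s Inclusive time window in seconds (default 30).
#' @return Tibble of events: `bird_a`, `bird_b`, `t_a`, `t_b`, `lat_a`,
#'   `lon_a`, `lat_b`, `lon_b` (bird ids sorted within the pair).
#' @export
detect_pairs <- function(track_a, track_b, dlat = 0.002, dlon = 0.002,
                         dt_s = 30) {
  if (track_a$bird_id[1] == track_b$bird_id[1]) {
    stop("cannot associate a bird with itself", call. = FALSE)
  }
  if (track_a$bird_id[1] > track_b$bird_id[1]) {
    # canonical orientation: bird_a is the lexicographically smaller id
    return(detect_pairs(track_b, track_a, dlat, dlon, dt_s))
  }
  m <- time_window_join(as.numeric(track_a$t), as.numeric(track_b$t), dt_s)
  if (nrow(m)) {
    close <- abs(track_a$lat[m$i] - track_b$lat[m$j]) < dlat &
      abs(track_a$lon[m$i] - track_b$lon[m$j]) < dlon
    m <- m[close, ]
  }
  tibble::tibble(
    bird_a = rep(track_a$bird_id[1], nrow(m)),
    bird_b = rep(track_b$bird_id[1], nrow(m)),
    t_a = track_a$t[m$i], t_b = track_b$t[m$j],
    lat_a = track_a$lat[m$i], lon_a = track_a$lon[m$i],
    lat_b = track_b$lat[m$j], lon_b = track_b$lon[m$j]
  )
}

#' Detect association events across every bird pair
#'
#' @param fixes Multi-bird fix tibble.
#' @inheritParams detect_pairs
#' @return Event tibble over all unordered bird pairs.
#' @export
detect_all_pairs <- function(fixes, dlat = 0.002, dlon = 0.002, dt_s = 30) {
  tracks <- split(fixes, fixes$bird_id)
  ids <- names(tracks)
  out <- list()
  if (length(ids) >= 2) {
    pairs <- utils::combn(ids, 2)
    out <- lapply(seq_len(ncol(pairs)), function(k) {
      detect_pairs(tracks[[pairs[1, k]]], tracks[[pairs[2, k]]],
                   dlat, dlon, dt_s)
    })
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) res <- empty_events()
  res
}

empty_events <- function() {
  tibble::tibble(bird_a = character(), bird_b = character(),
                 t_a = as.POSIXct(character(), tz = "UTC"),
                 t_b = as.POSIXct(character(), tz = "UTC"),
                 lat_a = numeric(), lon_a = numeric(),
                 lat_b = numeric(), lon_b = numeric())
}

#' Remove events near the nest
#'
#' Drops any event where *either* member lies within `radius_m` of the nest
#' (colony) point, restricting the association analysis to events at sea.
#'
#' @param events Event tibble.
#' @param colony A [colony_site()] (the colony point stands in for the nest
#'   when per-bird nests are not recorded).
#' @param radius_m Exclusion radius in metres (default 50).
#' @return Filtered event tibble.
#' @export
filter_nest <- function(events, colony, radius_m = 50) {
  if (nrow(events) == 0) return(events)
  da <- haversine_m(events$lat_a, events$lon_a, colony$lat, colony$lon)
  db <- haversine_m(events$lat_b, events$lon_b, colony$lat, colony$lon)
  events[da > radius_m & db > radius_m, ]
}

#' Drop bird pairs with a single event
#'
#' Very short random encounters are excluded by ignoring any unordered bird
#' pair contributing exactly one event.
#'
#' @param events Event tibble (nest-filtered).
#' @return Pruned event tibble.
#' @export
prune_single <- function(events) {
  if (nrow(events) == 0) return(events)
  key <- paste(pmin(events$bird_a, events$bird_b),
               pmax(events$bird_a, events$bird_b))
  counts <- table(key)
  events[counts[key] > 1, ]
}

#' Per-bin association group sizes
#'
#' Events are binned on the clock (bin start = floor of the event mid-time);
#' within a bin, birds are nodes and events edges, and a bird's partner
#' count is the size of its connected component minus one — "simultaneously
#' associated" is transitive through shared partners.
#'
#' @param events Pruned event tibble.
#' @param bin_s Bin width in seconds (default 60).
#' @return Tibble: `bin_start` (POSIXct), `bird_id`, `n_partners`.
#' @export
group_sizes <- function(events, bin_s = 60) {
  if (nrow(events) == 0) {
    return(tibble::tibble(bin_start = as.POSIXct(character(), tz = "UTC"),
                          bird_id = character(), n_partners = integer()))
  }
  mid <- (as.numeric(events$t_a) + as.numeric(events$t_b)) / 2
  bin <- floor(mid / bin_s) * bin_s
  out <- lapply(split(seq_along(bin), bin), function(rows) {
    g <- igraph::graph_from_data_frame(
      unique(data.frame(events$bird_a[rows], events$bird_b[rows])),
      directed = FALSE)
    comp <- igraph::components(g)
    tibble::tibble(bird_id = names(comp$membership),
                   n_partners = comp$csize[comp$membership] - 1L)
  })
  bins <- as.numeric(names(out))
  res <- dplyr::bind_rows(out, .id = "key")
  res$bin_start <- as.POSIXct(bins[match(res$key, names(out))], tz = "UTC",
                              origin = as.POSIXct("1970-01-01", tz = "UTC"))
  res[c("bin_start", "bird_id", "n_partners")]
}

#' Fraction of a track's fixes that are associated
#'
#' @param track Single-bird fix tibble (non-empty).
#' @param events Pruned event tibble.
#' @return Share of the track's fixes appearing in at least one event, in
#'   `[0, 1]`.
#' @export
association_fraction <- function(track, events) {
  if (nrow(track) == 0) stop("empty track", call. = FALSE)
  bird <- track$bird_id[1]
  t_assoc <- c(events$t_a[events$bird_a == bird],
               events$t_b[events$bird_b == bird])
  length(unique(t_assoc[t_assoc %in% track$t])) / nrow(track)
}
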