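# Shared fixtures and independent oracles. The simulated colony and the
# full pipeline bundle are expensive, so they are built once per test run
# and cached; every consumer uses the generator's default study conditions.

ft_cache <- new.env(parent = emptyenv())

cached_bundle <- function() {
  if (!exists("bundle", envir = ft_cache)) {
    assign("bundle", suppressMessages(run_pipeline(default_run_config())),
           envir = ft_cache)
  }
  get("bundle", envir = ft_cache)
}

# behaviour labels computed at each bird's native sampling interval, joined
# with the simulator's ground-truth states
cached_native_labels <- function() {
  if (!exists("native", envir = ft_cache)) {
    bundle <- cached_bundle()
    truth <- bundle$truth$states
    lab <- dplyr::bind_rows(lapply(split(bundle$fixes, bundle$fixes$bird_id),
                                   function(b) {
      fs <- suppressMessages(filter_speed(b))
      step <- if (b$age_class[1] == "juvenile") 60 else 120
      trips <- split_trips(interpolate_track(fs, step), colony_site())
      if (nrow(trips) == 0) return(NULL)
      dplyr::bind_rows(lapply(split(trips, trips$trip_id), label_trip))
    }))
    key <- paste(lab$bird_id, lab$t)
    tkey <- paste(truth$bird_id, truth$t)
    lab$true_state <- truth$true_state[match(key, tkey)]
    assign("native", lab, envir = ft_cache)
  }
  get("native", envir = ft_cache)
}

# simple straight out-and-back track fixture
make_track <- function(lats, lons, step_s = 120, bird_id = "B1",
                       age_class = "juvenile",
                       t0 = as.POSIXct("2014-02-01 08:00:00", tz = "UTC")) {
  tibble::tibble(
    bird_id = bird_id, age_class = age_class,
    t = t0 + (seq_along(lats) - 1) * step_s,
    lat = lats, lon = lons
  )
}

# independent scan-based oracle for ARS segmentation + merging: walks the
# label string character by character, then merges with an explicit gap count
oracle_ars_zones <- function(labels, min_run = 3, max_gap = 3) {
  n <- length(labels)
  isF <- !is.na(labels) & labels == "intensive_foraging"
  runs <- list()
  s <- NA_integer_
  for (i in seq_len(n + 1)) {
    inside <- i <= n && isF[i]
    if (inside && is.na(s)) s <- i
    if (!inside && !is.na(s)) {
      if ((i - 1) - s + 1 >= min_run) runs[[length(runs) + 1]] <- c(s, i - 1)
      s <- NA_integer_
    }
  }
  if (length(runs) == 0) return(tibble::tibble(start = integer(),
                                               end = integer()))
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    gap_other <- sum(!isF[(last[2] + 1):(r[1] - 1)])
    if (gap_other <= max_gap) {
      merged[[length(merged)]] <- c(last[1], r[2])
    } else {
      merged[[length(merged) + 1]] <- r
    }
  }
  m <- do.call(rbind, merged)
  tibble::tibble(start = m[, 1], end = m[, 2])
}

# brute-force all-pairs association oracle (full cross product)
oracle_detect_pairs <- function(track_a, track_b, dlat = 0.002,
                                dlon = 0.002, dt_s = 30) {
  hit <- abs(outer(as.numeric(track_a$t), as.numeric(track_b$t), "-")) <= dt_s &
    abs(outer(track_a$lat, track_b$lat, "-")) < dlat &
    abs(outer(track_a$lon, track_b$lon, "-")) < dlon
  idx <- which(hit, arr.ind = TRUE)
  tibble::tibble(t_a = track_a$t[idx[, 1]], t_b = track_b$t[idx[, 2]])
}

# textbook Pearson homogeneity statistic, written out longhand
oracle_pearson <- function(tab) {
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  stat
}

random_label_string <- function(n) {
  sample(c("intensive_foraging", "travelling", "resting", "relocating"),
         n, replace = TRUE, prob = c(0.45, 0.25, 0.15, 0.15))
}
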