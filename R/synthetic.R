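# Seeded simulator of a central-place-foraging colony.
#
# Movement is a discrete-time correlated random walk in a local flat
# approximation around the colony (1 deg lat = 111.32 km, 1 deg lon scaled by
# cos(lat)), adequate at the <= 100 km ranges simulated here. At each step a
# behavioural state is drawn from a 4-state Markov chain, a speed and an
# absolute turning angle are drawn from per-state truncated normals, and the
# heading is rotated by +/- the turn. The turn *sign* carries no behavioural
# information (the analysis folds angles to [0, pi]) and is therefore free:
# the simulator uses it to steer birds along per-bird azimuthal corridors
# (separable mode) and back to the colony at the end of a trip, without ever
# breaking the (speed, turn) ground truth attached to each fix.

behaviour_states <- c("resting", "intensive_foraging", "travelling",
                      "relocating")

#' Truncated-normal draws
#'
#' Inverse-CDF sampler for a normal truncated to `[lo, hi]`; used for all
#' per-state speed/turn and schedule draws so that a single seed determines
#' the whole colony.
#'
#' @param n Number of draws.
#' @param mean,sd,lo,hi Distribution parameters.
#' @return Numeric vector of length `n`.
#' @export
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    stop("infeasible truncation bounds [", lo, ", ", hi, "]", call. = FALSE)
  }
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

rtn <- function(n, p) rtruncnorm(n, p[["mean"]], p[["sd"]], p[["lo"]], p[["hi"]])

ang_diff <- function(a, b) atan2(sin(a - b), cos(a - b))

#' Default colony simulation configuration
#'
#' In separable mode every per-state (speed, turn) distribution is confined
#' strictly inside one behaviour class box and outside the doubly-claimed
#' rectangle v in \[6, 14\) km/h x theta in \[0.30, 0.43\) rad, so the box
#' labeller can recover the planted states exactly; birds are additionally
#' confined to per-bird azimuthal sectors so that non-planted birds never
#' approach each other at sea. Realistic mode lets the state distributions
#' overlap the class boundaries.
#'
#' Defaults emulate the study conditions: colony at 22.3 deg S, 40.3 deg E,
#' 60-s (juvenile) / 120-s (adult) sampling, one (occasionally two) trips per
#' day with juvenile trips of roughly 4.8 +/- 2.6 h and adult trips of
#' 9.1 +/- 4.0 h, bounded to 0.3-14.9 h, and a handful of planted co-movement
#' episodes among juveniles.
#'
#' @param separable Logical; strict class separation and sector confinement.
#' @param n_juveniles,n_adults Birds per age class.
#' @param n_days Days simulated.
#' @param seed RNG seed stored in the config; [simulate_colony()] sets it.
#' @return A `sim_config` list.
#' @export
default_sim_config <- function(separable = TRUE, n_juveniles = 6,
                               n_adults = 4, n_days = 5, seed = 42) {
  speed <- if (separable) list(
    resting            = c(mean = 2,  sd = 1,   lo = 0.5, hi = 5.5),
    intensive_foraging = c(mean = 3,  sd = 1.2, lo = 0.5, hi = 5.5),
    travelling         = c(mean = 35, sd = 8,   lo = 20,  hi = 60),
    relocating         = c(mean = 30, sd = 8,   lo = 16,  hi = 60)
  ) else list(
    resting            = c(mean = 2,  sd = 1.5, lo = 0,   hi = 6.8),
    intensive_foraging = c(mean = 4,  sd = 2,   lo = 0,   hi = 12),
    travelling         = c(mean = 35, sd = 10,  lo = 5,   hi = 80),
    relocating         = c(mean = 28, sd = 10,  lo = 12,  hi = 80)
  )
  turn <- if (separable) list(
    resting            = c(mean = 0.10, sd = 0.06, lo = 0.01, hi = 0.28),
    intensive_foraging = c(mean = 1.20, sd = 0.50, lo = 0.50, hi = 2.80),
    travelling         = c(mean = 0.10, sd = 0.07, lo = 0.01, hi = 0.25),
    relocating         = c(mean = 1.00, sd = 0.45, lo = 0.50, hi = 2.50)
  ) else list(
    resting            = c(mean = 0.12, sd = 0.08, lo = 0,    hi = 0.40),
    intensive_foraging = c(mean = 1.10, sd = 0.50, lo = 0.25, hi = 3.14),
    travelling         = c(mean = 0.12, sd = 0.08, lo = 0,    hi = 0.50),
    relocating         = c(mean = 1.00, sd = 0.45, lo = 0.35, hi = 3.14)
  )
  transition <- matrix(c(
    0.90, 0.04, 0.04, 0.02,
    0.03, 0.85, 0.04, 0.08,
    0.03, 0.05, 0.84, 0.08,
    0.02, 0.20, 0.10, 0.68
  ), nrow = 4, byrow = TRUE,
  dimnames = list(behaviour_states, behaviour_states))
  episodes <- if (separable && n_juveniles >= 5) {
    tibble::tibble(
      leader   = c("J01", "J01", "J04"),
      follower = c("J02", "J03", "J05"),
      day      = c(2L, 2L, 4L)
    )
  } else {
    tibble::tibble(leader = character(), follower = character(),
                   day = integer())
  }
  cfg <- list(
    separable = separable,
    n_juveniles = n_juveniles,
    n_adults = n_adults,
    n_days = n_days,
    start = "2014-02-01",
    colony = colony_site(),
    colony_radius_m = 500,
    sampling_s = c(juvenile = 60, adult = 120),
    speed = speed,
    turn = turn,
    transition = transition,
    trip_duration_h = list(juvenile = c(mean = 4.8, sd = 2.6, lo = 0.3, hi = 14.9),
                           adult    = c(mean = 9.1, sd = 4.0, lo = 0.3, hi = 14.9)),
    departure_h = list(juvenile = c(mean = 11, sd = 1, lo = 6, hi = 15),
                       adult    = c(mean = 9,  sd = 1, lo = 5, hi = 13)),
    p_second_trip = c(juvenile = 0.036, adult = 0.055),
    forage_range_km = list(juvenile = c(mean = 15, sd = 5,  lo = 6,  hi = 30),
                           adult    = c(mean = 60, sd = 25, lo = 20, hi = 100)),
    sector_confine = separable,
    associations = episodes,
    assoc_jitter_deg = 0.001,
    seed = seed
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_juveniles >= 0, cfg$n_adults >= 0, cfg$n_days >= 1)
  if (any(cfg$sampling_s <= 0)) stop("sampling interval must be > 0",
                                     call. = FALSE)
  if (any(abs(rowSums(cfg$transition) - 1) > 1e-8)) {
    stop("transition-matrix rows must sum to 1", call. = FALSE)
  }
  if (any(cfg$transition < 0)) stop("negative transition probability",
                                    call. = FALSE)
  for (st in behaviour_states) {
    for (comp in c("speed", "turn")) {
      p <- cfg[[comp]][[st]]
      if (is.null(p)) stop("missing ", comp, " parameters for ", st,
                           call. = FALSE)
      if (p[["lo"]] >= p[["hi"]]) {
        stop("empty ", comp, " bounds for state ", st, call. = FALSE)
      }
    }
  }
  invisible(cfg)
}

#' Simulate a Markov behaviour-state sequence
#'
#' @param n Number of steps.
#' @param transition Row-stochastic 4x4 matrix over the behaviour states.
#' @param init Initial state.
#' @return Character vector of states, length `n` (the first element is a
#'   transition from `init`).
#' @export
simulate_state_sequence <- function(n, transition, init = "resting") {
  states <- rownames(transition)
  out <- character(n)
  cur <- init
  for (i in seq_len(n)) {
    cur <- sample(states, 1L, prob = transition[cur, ])
    out[i] <- cur
  }
  out
}

#' Simulate a free correlated random walk with behaviour states
#'
#' The raw movement engine underlying [simulate_colony()], without any trip
#' structure: states follow the configured Markov chain for `n_steps`, speeds
#' and turns are drawn per state and the heading is rotated by a random-sign
#' turn. Useful for chain-level calibration checks where the trip scaffolding
#' (commutes, return steering) would contaminate the state budget.
#'
#' @param n_steps Number of movement steps.
#' @param config A `sim_config` (for the state distributions and chain).
#' @param init_state Starting state.
#' @param lat0,lon0 Start position (defaults to the configured colony).
#' @param step_s Sampling interval in seconds (defaults to 60).
#' @param bird_id,age_class Identity attached to the fixes.
#' @return A list with `fixes` (tibble) and `states` (character, one per fix;
#'   the first fix carries `init_state`).
#' @export
simulate_crw_track <- function(n_steps, config = default_sim_config(),
                               init_state = "resting",
                               lat0 = config$colony$lat,
                               lon0 = config$colony$lon,
                               step_s = 60, bird_id = "B01",
                               age_class = "juvenile") {
  n <- n_steps + 1L
  lat <- numeric(n); lon <- numeric(n); st <- character(n)
  lat[1] <- lat0; lon[1] <- lon0; st[1] <- init_state
  heading <- stats::runif(1, -pi, pi)
  dt_h <- step_s / 3600
  cur <- init_state
  for (i in 2:n) {
    cur <- sample(behaviour_states, 1L, prob = config$transition[cur, ])
    v <- rtn(1, config$speed[[cur]])
    dturn <- rtn(1, config$turn[[cur]])
    heading <- heading + sample(c(-1, 1), 1L) * dturn
    step_km <- v * dt_h
    lat[i] <- lat[i - 1] + step_km * cos(heading) / 111.32
    lon[i] <- lon[i - 1] +
      step_km * sin(heading) / (111.32 * cos(lat[i - 1] * DEG2RAD))
    st[i] <- cur
  }
  t0 <- as.POSIXct(paste(config$start, "00:00:00"), tz = "UTC")
  fixes <- tibble::tibble(
    bird_id = bird_id, age_class = age_class,
    t = t0 + (seq_len(n) - 1L) * step_s, lat = lat, lon = lon
  )
  list(fixes = fixes, states = st)
}

# Simulate one bird's full multi-day track. Fixes default to the bird's nest
# in the "resting" state; trips overwrite slices of the position/state
# vectors. skip_days: days on which this bird performs no trip of its own
# (it will be planted onto a leader's trip afterwards).
simulate_bird <- function(bird_id, age_class, cfg, sector_centre,
                          skip_days = integer()) {
  dt_s <- cfg$sampling_s[[age_class]]
  dt_h <- dt_s / 3600
  n <- as.integer(cfg$n_days * 86400 / dt_s)
  col_lat <- cfg$colony$lat
  col_lon <- cfg$colony$lon
  nest_lat <- col_lat + stats::runif(1, -2e-4, 2e-4)
  nest_lon <- col_lon + stats::runif(1, -2e-4, 2e-4)
  lat <- rep(nest_lat, n)
  lon <- rep(nest_lon, n)
  state <- rep("resting", n)
  halfwidth <- 0.7 * pi / max(1, cfg$n_juveniles + cfg$n_adults)
  # far point along the bird's sector ray, used as the outbound target
  far_km <- 200
  far_lat <- col_lat + far_km * cos(sector_centre) / 111.32
  far_lon <- col_lon +
    far_km * sin(sector_centre) / (111.32 * cos(col_lat * DEG2RAD))
  sp <- cfg$speed; tu <- cfg$turn; trans <- cfg$transition
  cruise <- sp$travelling[["mean"]]
  turn_allow_h <- (pi / 2) / tu$travelling[["mean"]] * dt_h

  run_trip <- function(i0, dur_h) {
    heading <- sector_centre + stats::runif(1, -0.2, 0.2)
    target_m <- rtn(1, cfg$forage_range_km[[age_class]]) * 1000
    phase <- "out"
    fstate <- "intensive_foraging"
    j <- i0
    while (j < n) {
      j <- j + 1L
      if (phase == "forage") {
        fstate <- sample(behaviour_states, 1L, prob = trans[fstate, ])
        st <- fstate
      } else {
        st <- "travelling"
      }
      v <- rtn(1, sp[[st]])
      dturn <- rtn(1, tu[[st]])
      plat <- lat[j - 1]; plon <- lon[j - 1]
      if (phase == "out") {
        tgt <- initial_bearing(plat, plon, far_lat, far_lon)
        d <- ang_diff(tgt, heading)
        sgn <- if (is.na(d) || d == 0) sample(c(-1, 1), 1L) else sign(d)
      } else if (phase == "ret") {
        tgt <- initial_bearing(plat, plon, nest_lat, nest_lon)
        d <- ang_diff(tgt, heading)
        sgn <- if (is.na(d) || d == 0) sample(c(-1, 1), 1L) else sign(d)
      } else {
        sgn <- sample(c(-1, 1), 1L)
        if (cfg$sector_confine) {
          az <- initial_bearing(col_lat, col_lon, plat, plon)
          if (!is.na(az) && abs(ang_diff(az, sector_centre)) > 0.5 * halfwidth) {
            # pick the turn sign whose step keeps the bird nearer its sector
            dev <- vapply(c(-1, 1), function(s) {
              h2 <- heading + s * dturn
              la2 <- plat + v * dt_h * cos(h2) / 111.32
              lo2 <- plon +
                v * dt_h * sin(h2) / (111.32 * cos(plat * DEG2RAD))
              abs(ang_diff(initial_bearing(col_lat, col_lon, la2, lo2),
                           sector_centre))
            }, numeric(1))
            sgn <- c(-1, 1)[which.min(dev)]
          }
        }
      }
      heading <- heading + sgn * dturn
      step_km <- v * dt_h
      lat[j] <<- plat + step_km * cos(heading) / 111.32
      lon[j] <<- plon + step_km * sin(heading) / (111.32 * cos(plat * DEG2RAD))
      state[j] <<- st
      rng_m <- haversine_m(lat[j], lon[j], col_lat, col_lon)
      el_h <- (j - i0) * dt_h
      if (phase == "out" && rng_m >= target_m) phase <- "forage"
      if (phase != "ret" &&
          el_h + rng_m / 1000 / cruise + turn_allow_h >= dur_h) {
        phase <- "ret"
      }
      if (phase == "ret" && rng_m <= cfg$colony_radius_m) break
    }
    j
  }

  for (day in seq_len(cfg$n_days)) {
    if (day %in% skip_days) next
    n_trips <- if (stats::runif(1) < cfg$p_second_trip[[age_class]]) 2L else 1L
    dep_h <- rtn(1, cfg$departure_h[[age_class]])
    day_i0 <- as.integer((day - 1) * 86400 / dt_s)
    last_end <- day_i0 + 1L
    for (k in seq_len(n_trips)) {
      dur <- cfg$trip_duration_h[[age_class]]
      dur_h <- rtn(1, dur)
      if (n_trips == 2L) dur_h <- dur_h / 2
      dur_h <- min(dur_h, 21.5 - dep_h)
      if (dur_h < dur[["lo"]]) break
      i0 <- day_i0 + as.integer(floor(dep_h * 3600 / dt_s)) + 1L
      if (i0 <= last_end) i0 <- last_end + 1L
      if (i0 >= n) break
      last_end <- run_trip(i0, dur_h)
      if (k == 1L && n_trips == 2L) {
        dep_h <- (last_end - day_i0) * dt_h + 1
        if (dep_h > 16) break
      }
    }
  }
  t0 <- as.POSIXct(paste(cfg$start, "00:00:00"), tz = "UTC")
  t <- t0 + (seq_len(n) - 1L) * dt_s
  list(
    fixes = tibble::tibble(bird_id = bird_id, age_class = age_class,
                           t = t, lat = lat, lon = lon),
    states = tibble::tibble(bird_id = bird_id, t = t, true_state = state)
  )
}

#' Simulate a tracked colony with ground truth
#'
#' Generates every bird's multi-day track (central-place trips plus at-nest
#' fixes), then plants the configured co-movement episodes: each follower sits
#' out its own trip on the episode day and its positions over the leader's
#' at-sea window are replaced by the leader's positions plus independent
#' uniform jitter (see [plant_association()]). Deterministic for a fixed
#' `config$seed`.
#'
#' @param config A `sim_config`, e.g. [default_sim_config()].
#' @return A list with `fixes` (one tibble for all birds) and `truth`, itself
#'   a list with `states` (bird_id, t, true_state; NA where a planted window
#'   overrides the movement model) and `associations` (bird_a, bird_b, start,
#'   stop windows of true co-movement).
#' @export
simulate_colony <- function(config = default_sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  ids <- c(sprintf("J%02d", seq_len(config$n_juveniles)),
           sprintf("A%02d", seq_len(config$n_adults)))
  ages <- c(rep("juvenile", config$n_juveniles),
            rep("adult", config$n_adults))
  if (length(ids) == 0) {
    return(list(fixes = empty_fixes(),
                truth = list(states = tibble::tibble(bird_id = character(),
                                                     t = as.POSIXct(character(), tz = "UTC"),
                                                     true_state = character()),
                             associations = empty_assoc_windows())))
  }
  episodes <- config$associations
  episodes <- episodes[episodes$leader %in% ids & episodes$follower %in% ids &
                         episodes$day <= config$n_days, , drop = FALSE]
  skip <- split(episodes$day, episodes$follower)
  sectors <- 2 * pi * (seq_along(ids) - 1) / length(ids)
  sims <- lapply(seq_along(ids), function(i) {
    simulate_bird(ids[i], ages[i], config, sectors[i],
                  skip_days = skip[[ids[i]]] %||% integer())
  })
  fixes <- dplyr::bind_rows(lapply(sims, `[[`, "fixes"))
  states <- dplyr::bind_rows(lapply(sims, `[[`, "states"))
  truth <- list(states = states, associations = empty_assoc_windows())

  if (nrow(episodes)) {
    for (g in split(episodes, paste(episodes$leader, episodes$day))) {
      leader <- g$leader[1]; day <- g$day[1]
      win <- leader_at_sea_window(fixes, leader, day, config)
      if (is.null(win)) next
      for (fol in g$follower) {
        planted <- plant_association(fixes, truth, leader, fol,
                                     win[1], win[2],
                                     jitter_deg = config$assoc_jitter_deg)
        fixes <- planted$fixes
        truth <- planted$truth
      }
      if (length(g$follower) > 1) {
        pairs <- utils::combn(sort(g$follower), 2)
        truth$associations <- dplyr::bind_rows(
          truth$associations,
          tibble::tibble(bird_a = pairs[1, ], bird_b = pairs[2, ],
                         start = win[1], stop = win[2])
        )
      }
    }
  }
  fixes <- fixes[order(fixes$bird_id, fixes$t), ]
  list(fixes = fixes, truth = truth)
}

empty_assoc_windows <- function() {
  tibble::tibble(bird_a = character(), bird_b = character(),
                 start = as.POSIXct(character(), tz = "UTC"),
                 stop = as.POSIXct(character(), tz = "UTC"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Window of a leader's first at-sea excursion on a given day, excluding the
# within-colony boundary fixes (so no planted fix can fall inside the 50-m
# nest exclusion).
leader_at_sea_window <- function(fixes, leader, day, config) {
  f <- fixes[fixes$bird_id == leader, ]
  t0 <- as.POSIXct(paste(config$start, "00:00:00"), tz = "UTC")
  in_day <- f$t >= t0 + (day - 1) * 86400 & f$t < t0 + day * 86400
  f <- f[in_day, ]
  if (nrow(f) == 0) return(NULL)
  out <- haversine_m(f$lat, f$lon, config$colony$lat, config$colony$lon) >
    config$colony_radius_m
  r <- rle(out)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- which(r$values)
  if (length(k) == 0) return(NULL)
  c(f$t[starts[k[1]]], f$t[ends[k[1]]])
}

#' Plant a co-movement episode between two birds
#'
#' Within `[start, stop]`, bird `bird_b`'s positions are replaced by bird
#' `bird_a`'s positions (linearly interpolated onto b's fix times) plus
#' independent uniform jitter of at most `jitter_deg` per axis. The truth
#' record gains the association window for the pair, and b's true behaviour
#' states over the window (plus two fixes on each side, whose step metrics
#' are contaminated by the window edge) are set to NA: a planted follower's
#' movement no longer follows its own state machine.
#'
#' @param fixes Colony fix tibble containing both birds.
#' @param truth Truth list as returned by [simulate_colony()].
#' @param bird_a,bird_b Leader and follower ids.
#' @param start,stop POSIXct window bounds; a zero-length window is a no-op.
#' @param jitter_deg Per-axis jitter bound in degrees.
#' @return A list with updated `fixes` and `truth`.
#' @export
plant_association <- function(fixes, truth, bird_a, bird_b, start, stop,
                              jitter_deg = 0.001) {
  if (bird_a == bird_b) stop("cannot associate a bird with itself",
                             call. = FALSE)
  if (stop < start) stop("stop precedes start", call. = FALSE)
  if (stop == start) return(list(fixes = fixes, truth = truth))
  a <- fixes[fixes$bird_id == bird_a, ]
  b_all <- which(fixes$bird_id == bird_b)
  if (nrow(a) == 0 || length(b_all) == 0) {
    stop("unknown bird id", call. = FALSE)
  }
  if (start < min(a$t) || stop > max(a$t) ||
      start < min(fixes$t[b_all]) || stop > max(fixes$t[b_all])) {
    stop("association window outside track coverage", call. = FALSE)
  }
  sel <- b_all[fixes$t[b_all] >= start & fixes$t[b_all] <= stop]
  if (length(sel)) {
    tt <- as.numeric(fixes$t[sel])
    la <- stats::approx(as.numeric(a$t), a$lat, xout = tt)$y
    lo <- stats::approx(as.numeric(a$t), a$lon, xout = tt)$y
    jl <- if (jitter_deg > 0) stats::runif(length(sel), -jitter_deg, jitter_deg) else 0
    jn <- if (jitter_deg > 0) stats::runif(length(sel), -jitter_deg, jitter_deg) else 0
    fixes$lat[sel] <- la + jl
    fixes$lon[sel] <- lo + jn
  }
  dt_b <- stats::median(diff(as.numeric(fixes$t[b_all])))
  na_rows <- truth$states$bird_id == bird_b &
    truth$states$t >= start - 2 * dt_b & truth$states$t <= stop + 2 * dt_b
  truth$states$true_state[na_rows] <- NA_character_
  truth$associations <- dplyr::bind_rows(
    truth$associations,
    tibble::tibble(bird_a = min(bird_a, bird_b), bird_b = max(bird_a, bird_b),
                   start = start, stop = stop)
  )
  list(fixes = fixes, truth = truth)
}

#' Expand truth association windows to per-fix pairs
#'
#' Enumerates, for every true co-movement window, the fix pairs of the two
#' birds that fall inside the window within `dt_s` seconds of each other —
#' the ground truth against which the association detector's recall and
#' precision are scored.
#'
#' @param fixes Colony fix tibble.
#' @param truth Truth list from [simulate_colony()].
#' @param dt_s Pairing time window in seconds.
#' @return Tibble with `bird_a`, `bird_b` (sorted within pair), `t_a`, `t_b`.
#' @export
truth_association_pairs <- function(fixes, truth, dt_s = 30) {
  win <- truth$associations
  out <- vector("list", nrow(win))
  for (i in seq_len(nrow(win))) {
    a <- fixes[fixes$bird_id == win$bird_a[i] &
                 fixes$t >= win$start[i] & fixes$t <= win$stop[i], ]
    b <- fixes[fixes$bird_id == win$bird_b[i] &
                 fixes$t >= win$start[i] & fixes$t <= win$stop[i], ]
    if (nrow(a) == 0 || nrow(b) == 0) next
    m <- time_window_join(as.numeric(a$t), as.numeric(b$t), dt_s)
    if (nrow(m) == 0) next
    out[[i]] <- tibble::tibble(
      bird_a = win$bird_a[i], bird_b = win$bird_b[i],
      t_a = a$t[m$i], t_b = b$t[m$j]
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(bird_a = character(), bird_b = character(),
                          t_a = as.POSIXct(character(), tz = "UTC"),
                          t_b = as.POSIXct(character(), tz = "UTC")))
  }
  dplyr::distinct(res)
}
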