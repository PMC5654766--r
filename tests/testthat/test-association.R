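offshore <- function(bird = "B1", n = 10, lat0 = -22.8, lon0 = 40.8,
                     dlat = 0.001, step_s = 60, t0 = NULL) {
  tr <- make_track(lat0 + (0:(n - 1)) * dlat, rep(lon0, n), step_s = step_s,
                   bird_id = bird)
  if (!is.null(t0)) tr$t <- t0 + (0:(n - 1)) * step_s
  tr
}

test_that("identical tracks match fix for fix; displaced tracks do not", {
  a <- offshore("B1")
  b <- offshore("B2")
  ev <- detect_pairs(a, b)
  same <- ev[ev$t_a == ev$t_b, ]
  expect_equal(nrow(same), 10)
  expect_equal(same$lat_a, same$lat_b)

  far <- b
  far$lat <- far$lat + 0.003
  expect_equal(nrow(detect_pairs(a, far)), 0)
})

test_that("degree thresholds are strict and the time window inclusive", {
  t0 <- as.POSIXct("2014-02-01 12:00:00", tz = "UTC")
  # constant-position tracks with exactly representable offsets
  a <- make_track(rep(0, 3), rep(40.8, 3), step_s = 60, bird_id = "B1",
                  t0 = t0)
  edge <- make_track(rep(0.002, 3), rep(40.8, 3), step_s = 60,
                     bird_id = "B2", t0 = t0)
  expect_equal(nrow(detect_pairs(a, edge)), 0) # |dlat| = 0.002 exactly: no

  near <- make_track(rep(0.0019, 3), rep(40.8, 3), step_s = 60,
                     bird_id = "B2", t0 = t0)
  expect_equal(nrow(detect_pairs(a, near)), 3)

  # single-fix tracks isolate the time rule
  one <- make_track(0, 40.8, bird_id = "B1", t0 = t0)
  at30 <- make_track(0, 40.8, bird_id = "B2", t0 = t0 + 30)
  expect_equal(nrow(detect_pairs(one, at30)), 1) # |dt| = 30 s exactly: yes
  at31 <- make_track(0, 40.8, bird_id = "B2", t0 = t0 + 31)
  expect_equal(nrow(detect_pairs(one, at31)), 0)
})

test_that("detection is symmetric in its arguments and rejects self-pairs", {
  set.seed(51)
  a <- offshore("B1", n = 40, dlat = 0.0015)
  b <- offshore("B2", n = 40, dlat = 0.0012)
  ab <- dplyr::arrange(detect_pairs(a, b), t_a, t_b)
  ba <- dplyr::arrange(detect_pairs(b, a), t_a, t_b)
  expect_equal(ab, ba)
  expect_error(detect_pairs(a, a), "itself")
})

test_that("the time-window join equals the brute-force all-pairs oracle", {
  set.seed(52)
  for (rep in 1:30) {
    n1 <- sample(20:120, 1); n2 <- sample(20:120, 1)
    t0 <- as.POSIXct("2014-02-01", tz = "UTC")
    a <- tibble::tibble(bird_id = "B1", age_class = "juvenile",
                        t = t0 + sort(sample(0:5000, n1)),
                        lat = -22.8 + cumsum(rnorm(n1, 0, 5e-4)),
                        lon = 40.8 + cumsum(rnorm(n1, 0, 5e-4)))
    b <- tibble::tibble(bird_id = "B2", age_class = "juvenile",
                        t = t0 + sort(sample(0:5000, n2)),
                        lat = -22.8 + cumsum(rnorm(n2, 0, 5e-4)),
                        lon = 40.8 + cumsum(rnorm(n2, 0, 5e-4)))
    got <- detect_pairs(a, b)
    want <- oracle_detect_pairs(a, b)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_setequal(paste(got$t_a, got$t_b), paste(want$t_a, want$t_b))
    }
  }
})

test_that("events near the nest are excluded when either member is close", {
  colony <- colony_site()
  at_nest <- offshore("B1", lat0 = colony$lat, lon0 = colony$lon)
  at_nest$lat <- colony$lat # exactly at the nest
  b <- at_nest; b$bird_id <- "B2"
  ev <- detect_pairs(at_nest, b)
  expect_equal(nrow(filter_nest(ev, colony)), 0)

  sea_a <- offshore("B1")
  sea_b <- offshore("B2")
  ev2 <- detect_pairs(sea_a, sea_b)
  expect_equal(nrow(filter_nest(ev2, colony)), nrow(ev2))

  # one member 40 m out, the other 60 m out: still removed
  m40 <- 40 / 111194.9; m60 <- 60 / 111194.9
  a3 <- make_track(colony$lat + rep(m40, 2), rep(colony$lon, 2),
                   bird_id = "B1")
  b3 <- make_track(colony$lat + rep(m60, 2), rep(colony$lon, 2),
                   bird_id = "B2")
  ev3 <- detect_pairs(a3, b3)
  expect_equal(nrow(ev3), 2)
  expect_equal(nrow(filter_nest(ev3, colony)), 0)
})

test_that("bird pairs with exactly one event are pruned", {
  a <- offshore("B1", n = 2)
  b <- offshore("B2", n = 2)
  ev <- detect_pairs(a, b)[1, ]
  expect_equal(nrow(prune_single(ev)), 0)
  ev2 <- detect_pairs(a, b)[1:2, ]
  expect_equal(nrow(prune_single(ev2)), 2)
  none <- detect_pairs(a, dplyr::mutate(b, lat = lat + 1))
  expect_equal(nrow(prune_single(none)), 0)
})

test_that("group sizes are transitive through shared partners", {
  a <- offshore("A", n = 3)
  b <- offshore("B", n = 3)
  c3 <- offshore("C", n = 3, lat0 = -22.8 + 0.0015)
  ev <- dplyr::bind_rows(detect_pairs(a, b), detect_pairs(b, c3))
  g <- group_sizes(ev, bin_s = 60)
  expect_equal(sort(unique(g$bird_id)), c("A", "B", "C"))
  expect_true(all(g$n_partners == 2)) # one component of three birds
  empty <- group_sizes(ev[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("association fractions are well-defined shares of a track", {
  a <- offshore("B1", n = 10)
  b <- offshore("B2", n = 10)
  ev <- prune_single(detect_pairs(a, b))
  expect_equal(association_fraction(a, ev), 1)
  none <- ev[0, ]
  expect_equal(association_fraction(a, none), 0)
  expect_error(association_fraction(a[0, ], ev), "empty")
})

test_that("planted co-movement is recovered with full recall and precision", {
  bundle <- cached_bundle()
  expected <- truth_association_pairs(bundle$fixes, bundle$truth)
  got <- bundle$events
  k_got <- paste(got$bird_a, got$bird_b, got$t_a, got$t_b)
  k_exp <- paste(expected$bird_a, expected$bird_b, expected$t_a,
                 expected$t_b)
  expect_gt(nrow(expected), 500)
  expect_equal(mean(k_exp %in% k_got), 1) # recall
  expect_equal(mean(k_got %in% k_exp), 1) # precision
})

test_that("the planted three-bird episode forms one component across its window", {
  bundle <- cached_bundle()
  win <- bundle$truth$associations
  trio <- win[win$bird_a %in% c("J01", "J02") & win$bird_b %in% c("J02", "J03"), ]
  g <- group_sizes(bundle$events, bin_s = 60)
  mid <- trio$start[1] + (trio$stop[1] - trio$start[1]) / 2
  bin_mid <- g[abs(as.numeric(g$bin_start) - as.numeric(mid)) <= 120 &
                 g$bird_id %in% c("J01", "J02", "J03"), ]
  expect_gt(nrow(bin_mid), 0)
  expect_true(all(bin_mid$n_partners == 2))
})

test_that("association fractions of planted tracks cover the whole window", {
  bundle <- cached_bundle()
  win <- bundle$truth$associations
  w <- win[win$bird_a == "J01" & win$bird_b == "J02", ]
  day <- as.Date(w$start)
  track <- bundle$fixes[bundle$fixes$bird_id == "J02" &
                          as.Date(bundle$fixes$t) == day, ]
  frac <- association_fraction(track, bundle$events)
  in_window <- mean(track$t >= w$start & track$t <= w$stop)
  expect_gte(frac, in_window - 2 / nrow(track))
  expect_lte(frac, 1)
})
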