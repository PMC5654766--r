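test_that("step metrics recover speed and turning geometry", {
  straight <- make_track(c(0, 0.01, 0.02, 0.03), c(10, 10, 10, 10))
  m <- step_metrics(straight)
  expect_equal(m$theta_rad[3:4], c(0, 0), tolerance = 1e-9)
  expect_true(is.na(m$v_kmh[1]) && all(is.na(m$theta_rad[1:2])))

  back <- make_track(c(0, 0.01, 0), c(10, 10, 10))
  expect_equal(step_metrics(back)$theta_rad[3], pi, tolerance = 1e-9)

  # 2 km in 2 min = 60 km/h: 2 km of latitude is 2/111.1949 degrees
  fast <- make_track(c(0, 2 / 111.1949, 4 / 111.1949), c(0, 0, 0))
  expect_equal(step_metrics(fast)$v_kmh[2], 60, tolerance = 1e-4)

  expect_error(step_metrics(make_track(c(0, 1), c(0, 1))), "at least 3")
})

test_that("a stationary trip reads as slow and straight", {
  still <- make_track(rep(-22.3, 5), rep(40.3, 5))
  lab <- label_trip(still)
  expect_true(all(lab$behaviour[3:5] == "resting"))
})

test_that("turning angles are invariant to traversal direction", {
  set.seed(31)
  tr <- make_track(-22.3 + cumsum(rnorm(30, 0, 0.005)),
                   40.3 + cumsum(rnorm(30, 0, 0.005)))
  fwd <- step_metrics(tr)$theta_rad
  rev_tr <- tr
  rev_tr$lat <- rev(tr$lat); rev_tr$lon <- rev(tr$lon)
  bwd <- step_metrics(rev_tr)$theta_rad
  # initial and final great-circle bearings differ slightly, so reversal
  # symmetry is exact only in the planar limit
  expect_equal(stats::na.omit(bwd), rev(stats::na.omit(fwd)),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("class boxes assign the printed labels with half-open bounds", {
  expect_equal(classify_steps(5, 0.1), "resting")
  expect_equal(classify_steps(50, 1.0), "relocating")
  expect_equal(classify_steps(20, 0.2), "travelling")
  expect_equal(classify_steps(5, 0.35), "intensive_foraging")
  expect_equal(classify_steps(3, 2.0), "intensive_foraging")
  # delimiters belong to the upper class
  expect_equal(classify_steps(6, 0.1), "travelling")
  expect_equal(classify_steps(5, 0.30), "intensive_foraging")
  expect_equal(classify_steps(14, 0.43), "relocating")
  # ambiguous rectangle: theta against the (0.30 + 0.43)/2 midpoint
  expect_equal(classify_steps(10, 0.35), "travelling")
  expect_equal(classify_steps(10, 0.40), "intensive_foraging")
  expect_error(classify_steps(-1, 0.1), "negative")
  expect_true(is.na(classify_steps(NA, 0.1)))
})

test_that("every fix with defined metrics gets exactly one of the four labels", {
  lab <- cached_native_labels()
  ok <- !is.na(lab$v_kmh) & !is.na(lab$theta_rad)
  expect_true(all(!is.na(lab$behaviour[ok])))
  expect_true(all(lab$behaviour[ok] %in%
                    c("resting", "intensive_foraging", "travelling",
                      "relocating")))
  expect_true(all(is.na(lab$behaviour[!ok])))
})

test_that("labels recover the planted states exactly on separable tracks", {
  lab <- cached_native_labels()
  scored <- !is.na(lab$behaviour) & !is.na(lab$true_state)
  expect_gt(sum(scored), 5000)
  expect_equal(mean(lab$behaviour[scored] == lab$true_state[scored]), 1)
})

test_that("labelling accuracy stays high when class distributions overlap", {
  cfg <- default_sim_config(separable = FALSE, n_juveniles = 3, n_adults = 2,
                            n_days = 2, seed = 33)
  sim <- simulate_colony(cfg)
  truth <- sim$truth$states
  lab <- dplyr::bind_rows(lapply(split(sim$fixes, sim$fixes$bird_id),
                                 function(b) {
    step <- if (b$age_class[1] == "juvenile") 60 else 120
    trips <- split_trips(interpolate_track(
      suppressMessages(filter_speed(b)), step), colony_site())
    if (nrow(trips) == 0) return(NULL)
    dplyr::bind_rows(lapply(split(trips, trips$trip_id), label_trip))
  }))
  tru <- truth$true_state[match(paste(lab$bird_id, lab$t),
                                paste(truth$bird_id, truth$t))]
  scored <- !is.na(lab$behaviour) & !is.na(tru)
  expect_gte(mean(lab$behaviour[scored] == tru[scored]), 0.90)
})

test_that("behaviour budgets are per-trip proportions that sum to one", {
  one <- label_trip(make_track(rep(-22.3, 6), rep(40.3, 6)))
  one$trip_id <- "t1"
  b <- behaviour_budget(one)
  expect_equal(b$mean[b$behaviour == "resting"], 1)
  expect_equal(sum(b$mean), 1, tolerance = 1e-12)

  bundle <- cached_bundle()
  per_age <- bundle$budgets |>
    dplyr::group_by(age_class) |>
    dplyr::summarise(total = sum(mean))
  expect_equal(per_age$total, rep(1, nrow(per_age)), tolerance = 1e-12)

  expect_error(behaviour_budget(one[0, ]), "no labelled fixes")
})

test_that("budget of a free chain matches its stationary distribution", {
  cfg <- default_sim_config()
  P <- cfg$transition
  ev <- eigen(t(P))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)
  names(stat) <- rownames(P)
  set.seed(34)
  crw <- simulate_crw_track(20000, cfg, init_state = "travelling",
                            lat0 = -24, lon0 = 42)
  lab <- label_trip(dplyr::mutate(crw$fixes, trip_id = "t1"))
  props <- table(factor(lab$behaviour, levels = rownames(P))) /
    sum(!is.na(lab$behaviour))
  nb <- 50
  batches <- matrix(seq_len(20000), ncol = nb)
  for (st in rownames(P)) {
    bm <- apply(batches, 2, function(idx) {
      mean(lab$behaviour[idx + 1] == st, na.rm = TRUE)
    })
    se <- stats::sd(bm) / sqrt(nb)
    expect_lt(abs(props[[st]] - stat[[st]]), 3 * se)
  }
})

test_that("the EM fitter recovers delimiters between well-separated clusters", {
  set.seed(35)
  n <- 600
  v <- c(rnorm(n, 3, 0.8), rnorm(n, 3, 0.8), rnorm(n, 40, 5), rnorm(n, 40, 5))
  th <- c(rnorm(n, 0.12, 0.05), rnorm(n, 1.2, 0.3),
          rnorm(n, 0.12, 0.05), rnorm(n, 1.2, 0.3))
  v <- pmax(v, 0.01); th <- pmin(pmax(th, 0.001), pi)
  d <- fit_delimiters(v, th, seed = 1)
  expect_gt(d$v_split_lowturn, 6)
  expect_lt(d$v_split_lowturn, 30)
  expect_gt(d$v_split_highturn, 6)
  expect_lt(d$v_split_highturn, 30)
  expect_gt(d$theta_split_lowspeed, 0.2)
  expect_lt(d$theta_split_lowspeed, 1.0)
  expect_gt(d$theta_split_highspeed, 0.2)
  expect_lt(d$theta_split_highspeed, 1.0)

  d2 <- fit_delimiters(v, th, seed = 1)
  expect_identical(d, d2)

  expect_error(fit_delimiters(v[1:50], th[1:50]), "at least 100")
})
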