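test_that("the colony simulator is deterministic under its seed", {
  cfg <- default_sim_config(n_juveniles = 2, n_adults = 1, n_days = 1)
  a <- simulate_colony(cfg)
  b <- simulate_colony(cfg)
  expect_identical(a$fixes, b$fixes)
  expect_identical(a$truth$states, b$truth$states)
  cfg2 <- cfg
  cfg2$seed <- cfg$seed + 1
  c2 <- simulate_colony(cfg2)
  expect_false(identical(a$fixes$lat, c2$fixes$lat))
})

test_that("an identity transition matrix freezes the chain in its initial state", {
  cfg <- default_sim_config()
  cfg$transition <- diag(4)
  dimnames(cfg$transition) <- dimnames(default_sim_config()$transition)
  set.seed(5)
  crw <- simulate_crw_track(200, cfg, init_state = "resting")
  expect_true(all(crw$states == "resting"))
})

test_that("long-run state frequencies match the chain's stationary distribution", {
  cfg <- default_sim_config()
  P <- cfg$transition
  ev <- eigen(t(P))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)
  names(stat) <- rownames(P)
  set.seed(6)
  n <- 40000
  s <- simulate_state_sequence(n, P)
  freq <- table(factor(s, levels = rownames(P))) / n
  # batch-means standard error (the chain is autocorrelated)
  nb <- 50
  batches <- matrix(seq_len(n), ncol = nb)
  for (st in rownames(P)) {
    bm <- apply(batches, 2, function(idx) mean(s[idx] == st))
    se <- stats::sd(bm) / sqrt(nb)
    expect_lt(abs(freq[[st]] - stat[[st]]), 3 * se)
  }
})

test_that("separable mode stays out of the ambiguous class rectangle", {
  lab <- cached_native_labels()
  # planted follower fixes carry the leader's position plus jitter and are
  # not movement-model draws (truth NA); the box constraint applies to the
  # generated steps
  m <- lab[!is.na(lab$v_kmh) & !is.na(lab$theta_rad) &
             !is.na(lab$true_state), ]
  ambiguous <- m$v_kmh >= 6 & m$v_kmh < 14 &
    m$theta_rad >= 0.30 & m$theta_rad < 0.43
  expect_equal(sum(ambiguous), 0)
})

test_that("default configuration carries the study-site constants", {
  cfg <- default_sim_config()
  expect_equal(cfg$colony$lat, -22.3)
  expect_equal(cfg$colony$lon, 40.3)
  expect_equal(unname(cfg$sampling_s["juvenile"]), 60)
  expect_equal(unname(cfg$sampling_s["adult"]), 120)
})

test_that("infeasible configurations are rejected", {
  cfg <- default_sim_config()
  cfg$speed$resting[c("lo", "hi")] <- c(5, 2)
  expect_error(validate_sim_config(cfg), "empty speed bounds")
  cfg2 <- default_sim_config()
  cfg2$transition[1, ] <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(validate_sim_config(cfg2), "sum to 1")
})

test_that("plant_association with zero jitter copies the leader exactly", {
  cfg <- default_sim_config(n_juveniles = 2, n_adults = 0, n_days = 1,
                            seed = 9)
  cfg$associations <- cfg$associations[0, ]
  sim <- simulate_colony(cfg)
  win <- as.POSIXct(c("2014-02-01 12:00:00", "2014-02-01 13:00:00"),
                    tz = "UTC")
  out <- plant_association(sim$fixes, sim$truth, "J01", "J02",
                           win[1], win[2], jitter_deg = 0)
  a <- out$fixes[out$fixes$bird_id == "J01" & out$fixes$t >= win[1] &
                   out$fixes$t <= win[2], ]
  b <- out$fixes[out$fixes$bird_id == "J02" & out$fixes$t >= win[1] &
                   out$fixes$t <= win[2], ]
  expect_equal(b$lat, a$lat[match(b$t, a$t)], tolerance = 1e-12)
  expect_equal(b$lon, a$lon[match(b$t, a$t)], tolerance = 1e-12)
  expect_true(all(is.na(
    out$truth$states$true_state[out$truth$states$bird_id == "J02" &
                                  out$truth$states$t >= win[1] &
                                  out$truth$states$t <= win[2]])))
})

test_that("planted jitter below the degree rule keeps every in-window pair detectable", {
  bundle <- cached_bundle()
  truth <- bundle$truth
  fixes <- bundle$fixes
  for (i in seq_len(nrow(truth$associations))) {
    w <- truth$associations[i, ]
    a <- fixes[fixes$bird_id == w$bird_a & fixes$t >= w$start &
                 fixes$t <= w$stop, ]
    b <- fixes[fixes$bird_id == w$bird_b & fixes$t >= w$start &
                 fixes$t <= w$stop, ]
    common <- intersect(a$t, b$t)
    expect_true(length(common) > 0)
    ia <- match(common, a$t); ib <- match(common, b$t)
    expect_true(all(abs(a$lat[ia] - b$lat[ib]) < 0.002))
    expect_true(all(abs(a$lon[ia] - b$lon[ib]) < 0.002))
  }
})

test_that("a zero-length window and out-of-coverage windows are handled", {
  cfg <- default_sim_config(n_juveniles = 2, n_adults = 0, n_days = 1,
                            seed = 10)
  cfg$associations <- cfg$associations[0, ]
  sim <- simulate_colony(cfg)
  t1 <- as.POSIXct("2014-02-01 12:00:00", tz = "UTC")
  out <- plant_association(sim$fixes, sim$truth, "J01", "J02", t1, t1)
  expect_identical(out$fixes, sim$fixes)
  expect_error(
    plant_association(sim$fixes, sim$truth, "J01", "J02",
                      t1, t1 + 5 * 86400),
    "coverage")
})
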