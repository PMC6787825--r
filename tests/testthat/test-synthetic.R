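test_that("station simulation is seeded, sized and collinear on demand", {
  sc <- sim_scenario()
  a <- simulate_stations(sc, seed = 4)
  b <- simulate_stations(sc, seed = 4)
  expect_identical(a, b)                       # full determinism under seed
  expect_equal(nrow(a$efforts), 127)           # study design default
  dur <- as.integer(a$efforts$retrieve - a$efforts$deploy) + 1
  expect_true(all(dur >= 20))
  expect_equal(mean(dur), 76.6, tolerance = 0.1 * 76.6)
  # collinear switch produces the designated high-correlation pair
  scc <- sim_scenario(collinear_pair = TRUE)
  hits <- vapply(1:10, function(s) {
    cv <- simulate_stations(scc, seed = s)$covariates
    abs(cor(cv$large_stem_density, cv$stem_total)) > 0.7
  }, TRUE)
  expect_gt(mean(hits), 0.8)
})

test_that("detection simulation respects degenerate rates", {
  sc0 <- sim_scenario(n_stations = 15, species = list(
    ghost = list(psi = c(intercept = qlogis(0.8)),
                 p = c(intercept = qlogis(1e-9)),
                 activity = "nocturnal")))
  st <- simulate_stations(sc0, seed = 2)
  sim <- simulate_detections(sc0, st, seed = 3)
  expect_equal(nrow(sim$records), 0)           # p ~ 0 -> no records
  # psi = p = 1 with 1-day occasions: every active station-day yields a record
  sc1 <- sim_scenario(n_stations = 5, mean_days = 30, sd_days = 1,
                      occasion_length = 1, species = list(
    omni = list(psi = c(intercept = 20), p = c(intercept = 20),
                activity = "diurnal")))
  st1 <- simulate_stations(sc1, seed = 5)
  sim1 <- simulate_detections(sc1, st1, seed = 6)
  expect_equal(nrow(sim1$records), trap_nights(st1$efforts))
})

test_that("realized naive occupancy matches the closed-form identity", {
  # constant model: E[naive occ] = psi * (1 - (1-p)^K); collapse to occasions
  psi <- 0.6; p_occ <- 0.3; K <- 13
  sc <- sim_scenario(n_stations = 127, mean_days = 78, sd_days = 0, species = list(
    sp = list(psi = c(intercept = qlogis(psi)),
              p = c(intercept = qlogis(p_occ)), activity = "nocturnal")))
  naive <- vapply(1:60, function(s) {
    st <- simulate_stations(sc, seed = 100 + s)
    sim <- simulate_detections(sc, st, seed = 200 + s)
    h <- build_history(sim$records, st$efforts, "sp")
    mean(rowSums(h$matrix == 1, na.rm = TRUE) > 0)
  }, 1)
  expect_equal(mean(naive), psi * (1 - (1 - p_occ)^K), tolerance = 0.02)
})

test_that("activity-time simulation matches its mixture and is reproducible", {
  mx <- activity_template("nocturnal")
  a <- simulate_activity_times(mx, 500, seed = 8)
  b <- simulate_activity_times(mx, 500, seed = 8)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a < 2 * pi))
  # large kappa single component: small circular spread around the mean
  tight <- simulate_activity_times(list(w = 1, mu = 1.2, kappa = 200), 400, seed = 9)
  rbar <- sqrt(mean(cos(tight))^2 + mean(sin(tight))^2)
  expect_gt(rbar, 0.99)
  expect_equal(atan2(mean(sin(tight)), mean(cos(tight))), 1.2, tolerance = 0.05)
  # bimodal dusk/dawn mixture: fitted KDE has a two-interval 50% core
  bim <- simulate_activity_times(activity_template("nocturnal_bimodal"), 2000,
                                 seed = 10)
  d <- vm_kde(bim, select_bandwidth(bim))
  expect_equal(nrow(isopleth(d, 0.5)$intervals), 2)
  expect_error(simulate_activity_times(mx, 0), "positive")
})

test_that("two-species generator reproduces its conditional structure", {
  pr <- list(psiA = 0.55, psiBA = 0.2, psiBa = 0.8, pA = 0.4, pB = 0.4,
             rA = 0.4, rBA = 0.4, rBa = 0.4)
  sim <- simulate_two_species_history(4000, 10, pr, seed = 12)
  expect_lt(abs(mean(sim$zA) - pr$psiA), 0.025)
  expect_lt(abs(mean(sim$zB[sim$zA == 1]) - pr$psiBA), 0.025)
  expect_lt(abs(mean(sim$zB[sim$zA == 0]) - pr$psiBa), 0.025)
  expect_equal(sim$phi, sif_occupancy(pr$psiA, pr$psiBA, pr$psiBa))
  # detections only where the latent state allows them
  expect_true(all(rowSums(sim$YA) == 0 | sim$zA == 1))
  expect_true(all(rowSums(sim$YB) == 0 | sim$zB == 1))
})
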