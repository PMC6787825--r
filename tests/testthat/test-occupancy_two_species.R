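base_params <- function(...) {
  p <- list(psiA = 0.55, psiBA = 0.4, psiBa = 0.6, pA = 0.3, pB = 0.4,
            rA = 0.3, rBA = 0.35, rBa = 0.45)
  utils::modifyList(p, list(...))
}

test_that("two-species likelihood reproduces forced single-occasion cases", {
  pr <- base_params()
  # both detected: only the both-present state is consistent
  got <- two_species_loglik(matrix(1L, 1, 1), matrix(1L, 1, 1), pr)
  expect_equal(got, log(pr$psiA * pr$psiBA * pr$rA * pr$rBA))
  # neither detected: all four states contribute
  got0 <- two_species_loglik(matrix(0L, 1, 1), matrix(0L, 1, 1), pr)
  want0 <- pr$psiA * pr$psiBA * (1 - pr$rA) * (1 - pr$rBa) +
    pr$psiA * (1 - pr$psiBA) * (1 - pr$pA) +
    (1 - pr$psiA) * pr$psiBa * (1 - pr$pB) +
    (1 - pr$psiA) * (1 - pr$psiBa)
  expect_equal(got0, log(want0))
  expect_error(two_species_loglik(matrix(1L, 1, 1), matrix(1L, 2, 1), pr),
               "mismatch")
})

test_that("two-species likelihood matches four-state enumeration on a sweep", {
  set.seed(202)
  for (rep in 1:60) {
    n <- sample(1:4, 1); K <- sample(1:4, 1)
    YA <- matrix(rbinom(n * K, 1, 0.4), n, K)
    YB <- matrix(rbinom(n * K, 1, 0.4), n, K)
    if (rep %% 3 == 0) {
      drop <- sample(length(YA), max(1, length(YA) %/% 4))
      YA[drop] <- NA; YB[drop] <- NA
    }
    if (all(rowSums(!is.na(YA)) == 0)) next
    pr <- list(psiA = runif(1, .1, .9), psiBA = runif(1, .1, .9),
               psiBa = runif(1, .1, .9), pA = runif(1, .1, .9),
               pB = runif(1, .1, .9), rA = runif(1, .1, .9),
               rBA = runif(1, .1, .9), rBa = runif(1, .1, .9))
    expect_equal(two_species_loglik(YA, YB, pr), oracle_ts_loglik(YA, YB, pr),
                 tolerance = 1e-10)
  }
})

test_that("under full independence the joint likelihood factorizes", {
  set.seed(77)
  n <- 12; K <- 6
  YA <- matrix(rbinom(n * K, 1, 0.3), n, K)
  YB <- matrix(rbinom(n * K, 1, 0.4), n, K)
  miss <- matrix(runif(n * K) < 0.1, n, K)
  YA[miss] <- NA; YB[miss] <- NA
  # ties: psiBA = psiBa, pB = rBA = rBa, and additionally pA = rA
  pr <- base_params(psiBA = 0.6, psiBa = 0.6, pB = 0.4, rBA = 0.4, rBa = 0.4,
                    pA = 0.3, rA = 0.3)
  joint <- two_species_loglik(YA, YB, pr)
  X <- matrix(1, n, 1)
  single <- occu_loglik(YA, X, X, qlogis(pr$psiA), qlogis(pr$pA)) +
    occu_loglik(YB, X, X, qlogis(pr$psiBa), qlogis(pr$pB))
  expect_equal(joint, single, tolerance = 1e-10)
})

test_that("SIF formulas match hand evaluation and independence limits", {
  # independence tie gives exactly 1 for any psiA
  for (psiA in c(0.2, 0.5, 0.8))
    for (psiB in c(0.3, 0.6))
      expect_identical(sif_occupancy(psiA, psiB, psiB), 1)
  expect_equal(sif_occupancy(0.5, 0.8, 0.2), 1.6)  # 0.4 / (0.5 * 0.5)
  expect_equal(sif_occupancy(0.5, 0, 0.2), 0)      # complete avoidance
  expect_identical(sif_detection(0.4, 0.3, 0.3), 1)
  expect_equal(sif_detection(0.4, 0.2, 0.6),
               0.4 * 0.2 / (0.4 * (0.4 * 0.2 + 0.6 * 0.6)))
  expect_equal(sif_detection(0.4, 0, 0.6), 0)
  expect_error(sif_occupancy(0.5, 0, 0), "denominator")
  # scale consistency: multiplying psiBA and psiBa by c leaves Phi unchanged
  for (cc in c(0.25, 0.5, 1))
    expect_equal(sif_occupancy(0.55, cc * 0.8, cc * 0.2),
                 sif_occupancy(0.55, 0.8, 0.2))
})

test_that("constrained fit forces Phi = 1 with zero standard error", {
  sim <- simulate_two_species_history(60, 8, base_params(), seed = 31)
  fit <- fit_two_species(sim$YA, sim$YB, occ = FALSE, det = "ind")$best
  s <- sif_uncertainty(fit)
  expect_equal(s$phi, 1)
  expect_equal(s$phi_se, 0, tolerance = 1e-6)
  expect_equal(s$delta, 1)
  expect_false(s$occ_interaction)
})

test_that("avoidance is recovered and interpreted from the fitted SIF", {
  pr <- base_params(psiBA = 0.25, psiBa = 0.75, pB = 0.4, rBA = 0.4, rBa = 0.4)
  sim <- simulate_two_species_history(400, 12, pr, seed = 57)
  fit <- fit_two_species(sim$YA, sim$YB, occ = TRUE, det = "ind")$best
  s <- sif_uncertainty(fit)
  expect_lt(s$phi, 1)
  expect_equal(s$phi, sim$phi, tolerance = 0.2)
  expect_equal(s$phi_interpretation, "avoidance")
  # delta-method SE agrees with a parametric bootstrap within 50% (well-
  # conditioned large-n fit; the bootstrap itself is Monte-Carlo noisy)
  fit_nv <- fit
  fit_nv$vcov <- matrix(NA_real_, fit$K, fit$K)
  sb <- sif_uncertainty(fit_nv, n_boot = 80, seed = 3)
  expect_equal(sb$phi_se, s$phi_se, tolerance = 0.5)
})

test_that("model ranking identifies the generating interaction structure", {
  # data simulated under independence: the independence model is supported
  sim <- simulate_two_species_history(
    200, 10, base_params(psiBA = 0.6, psiBa = 0.6, pB = 0.4, rBA = 0.4,
                         rBa = 0.4), seed = 71)
  ms <- fit_two_species(sim$YA, sim$YB)
  ind_row <- grep("psiBA=psiBa, det:ind", ms$table$model)
  expect_lt(ms$table$delta[ind_row], 2.5)
  # the tied model's CI is the point {1}: interpreted as independence
  tied <- ms$fits[[ind_row]]
  s <- sif_uncertainty(tied)
  expect_equal(s$phi_interpretation, "independent")
  expect_equal(s$delta_interpretation, "independent")
})
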