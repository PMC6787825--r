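int_design <- function(n) matrix(1, n, 1)

test_that("occu_loglik reproduces forced single-site cases", {
  # 1 site, 1 occasion, psi = p = 0.5: y = 1 -> 0.25; y = 0 -> 0.75
  X <- int_design(1)
  expect_equal(occu_loglik(matrix(1L, 1, 1), X, X, 0, 0), log(0.25))
  expect_equal(occu_loglik(matrix(0L, 1, 1), X, X, 0, 0), log(0.75))
  expect_error(occu_loglik(matrix(0L, 1, 1), X, X, c(0, 0), 0), "mismatch")
})

test_that("occu_loglik matches latent-state enumeration on a property sweep", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(1:4, 1); K <- sample(1:4, 1)
    Y <- matrix(rbinom(n * K, 1, 0.4), n, K)
    if (rep %% 3 == 0) Y[sample(length(Y), max(1, length(Y) %/% 4))] <- NA
    if (all(rowSums(!is.na(Y)) == 0)) next
    b <- rnorm(1); a <- rnorm(1)
    got <- occu_loglik(Y, int_design(n), int_design(n), b, a)
    want <- oracle_occu_loglik(Y, plogis(b), plogis(a))
    expect_equal(got, want, tolerance = 1e-10)
    # site-covariate case: per-site psi and p
    Xc <- cbind(1, rnorm(n))
    bb <- rnorm(2); aa <- rnorm(2)
    got2 <- occu_loglik(Y, Xc, Xc, bb, aa)
    want2 <- oracle_occu_loglik(Y, plogis(drop(Xc %*% bb)), plogis(drop(Xc %*% aa)))
    expect_equal(got2, want2, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to site and occasion permutations", {
  set.seed(5)
  Y <- matrix(rbinom(40, 1, 0.3), 8, 5)
  X <- int_design(8)
  base <- occu_loglik(Y, X, X, 0.3, -0.6)
  expect_equal(occu_loglik(Y[sample(8), ], X, X, 0.3, -0.6), base)
  expect_equal(occu_loglik(Y[, sample(5)], X, X, 0.3, -0.6), base)
})

test_that("information criteria match their formulas", {
  expect_equal(aicc(-100, 3, 127), 206 + 24 / 123)
  expect_error(aicc(-100, 3, 4), "exceed")
  # chat = 2, hand evaluation with K' = K + 1 = 4
  expect_equal(qaicc(-100, 3, 127, 2), 100 + 8 + 2 * 4 * 5 / (127 - 5))
  # chat = 1: differs from AICc only through the K' = K + 1 correction
  expect_equal(qaicc(-100, 3, 127, 1),
               aicc(-100, 4, 127) + 0)  # same formula with K+1 parameters
  expect_error(qaicc(-100, 3, 127, 0), "positive")
})

test_that("intercept-only ML fit agrees with a brute-force grid search", {
  sim <- simulate_occu_history(25, 8, psi = 0.7, p = 0.35, seed = 21)
  f <- fit_occu(sim$Y)
  # profile the likelihood over a 1000 x 1000 probability grid
  gr <- seq(0.001, 0.999, length.out = 1000)
  d <- rowSums(sim$Y); K <- ncol(sim$Y)
  groups <- table(d)
  ll <- matrix(0, 1000, 1000)  # psi rows, p cols
  for (g in names(groups)) {
    dd <- as.numeric(g)
    cell <- outer(gr, gr, function(psi, p)
      log(psi * p^dd * (1 - p)^(K - dd) + (1 - psi) * (dd == 0)))
    ll <- ll + groups[[g]] * cell
  }
  best <- arrayInd(which.max(ll), dim(ll))
  expect_equal(plogis(f$beta[[1]]), gr[best[1]], tolerance = 1e-3)
  expect_equal(plogis(f$alpha[[1]]), gr[best[2]], tolerance = 1e-3)
  expect_true(f$converged)
  expect_equal(f$aicc, aicc(f$loglik, 2, 25))
})

test_that("monotonicity: a new detection at an all-zero site raises psi-hat", {
  sim <- simulate_occu_history(30, 6, psi = 0.5, p = 0.4, seed = 33)
  Y <- sim$Y
  zero_site <- which(rowSums(Y) == 0)[1]
  f0 <- fit_occu(Y)
  Y2 <- Y; Y2[zero_site, 1] <- 1L
  f1 <- fit_occu(Y2)
  expect_gt(plogis(f1$beta[[1]]), plogis(f0$beta[[1]]))
})

test_that("degenerate all-detection data is handled without crashing", {
  Y <- matrix(1L, 12, 5)
  f <- fit_occu(Y)
  expect_gt(plogis(f$beta[[1]]), 0.95)  # psi-hat at the boundary
  expect_gt(plogis(f$alpha[[1]]), 0.95)
})

test_that("covariate effects are recovered in a seeded simulation", {
  set.seed(61)
  n <- 250; K <- 10
  x <- rnorm(n)
  psi <- plogis(0.3 + 1.0 * x)
  sim <- simulate_occu_history(n, K, psi = psi, p = 0.4)
  covs <- data.frame(x = x)
  f <- fit_occu(sim$Y, covs, occu_spec(psi = "x"))
  expect_true(f$converged)
  expect_equal(f$beta[["psi_x"]], 1.0, tolerance = 0.35)
  se <- sqrt(f$vcov["psi_x", "psi_x"])
  expect_gt(f$beta[["psi_x"]] - 1.96 * se, 0)   # effect detected
})

test_that("ranking and averaging follow the Akaike-weight algebra", {
  sim <- simulate_occu_history(60, 8, psi = 0.6, p = 0.35, seed = 77)
  covs <- data.frame(x = rnorm(60), w = rnorm(60))
  f0 <- fit_occu(sim$Y, covs, occu_spec())
  f1 <- fit_occu(sim$Y, covs, occu_spec(psi = "x"))
  f2 <- fit_occu(sim$Y, covs, occu_spec(psi = "w"))
  ms <- rank_and_average(list(f0, f1, f2))
  expect_equal(ms$table$delta[1], 0)
  expect_equal(sum(ms$table$weight), 1)
  expect_true(all(diff(ms$table$criterion) >= 0))
  # hand-computed conditional average of the intercept
  sel <- ms$table$in_average
  w <- ms$table$weight[sel]
  ests <- vapply(ms$fits[sel], function(f) f$beta[["psi_(Intercept)"]], 1)
  expect_equal(ms$averaged$estimate[ms$averaged$coefficient == "psi_(Intercept)"],
               sum(w * ests) / sum(w))
  # single model -> weight 1 and averaged coefficients equal its own
  ms1 <- rank_and_average(list(f1))
  expect_equal(ms1$table$weight, 1)
  expect_equal(ms1$averaged$estimate[ms1$averaged$coefficient == "psi_x"],
               f1$beta[["psi_x"]])
  # two identical models -> equal weights
  ms2 <- rank_and_average(list(f1, f1))
  expect_equal(ms2$table$weight, c(0.5, 0.5))
})

test_that("Wald CIs for psi achieve near-nominal coverage at the study scale", {
  cover <- vapply(1:500, function(s) {
    sim <- simulate_occu_history(127, 13, psi = 0.6, p = 0.3, seed = 40000 + s)
    f <- fit_occu(sim$Y)
    se <- sqrt(f$vcov[1, 1])
    if (!is.finite(se)) return(NA)
    lo <- plogis(f$beta[[1]] - 1.96 * se)
    hi <- plogis(f$beta[[1]] + 1.96 * se)
    lo <= 0.6 && 0.6 <= hi
  }, TRUE)
  expect_gte(mean(cover, na.rm = TRUE), 0.90)
  expect_lte(mean(cover, na.rm = TRUE), 0.98)
})

test_that("mb_gof returns a usable c-hat on a small correctly specified fit", {
  sim <- simulate_occu_history(80, 8, psi = 0.6, p = 0.35, seed = 99)
  f <- fit_occu(sim$Y)
  expect_warning(g <- mb_gof(f, n_boot = 60, seed = 1), "n_boot")
  expect_gt(g$chat, 0)
  expect_true(g$p_value >= 0 && g$p_value <= 1)
  expect_gte(g$n_boot_ok, 50)
})

test_that("selection workflow recovers an active occupancy covariate", {
  set.seed(303)
  n <- 200; K <- 10
  covs <- data.frame(x = rnorm(n), junk = rnorm(n), tw = rnorm(n))
  psi <- plogis(0.2 + 1.2 * covs$x)
  p <- plogis(-0.4 + 0.5 * covs$tw)
  sim <- simulate_occu_history(n, K, psi = psi, p = p)
  h <- sim$Y
  ms <- selection_workflow(h, covs, detection_candidates = "tw",
                           occupancy_candidates = c("x", "junk"))
  expect_equal(attr(ms, "p_model"), "tw")
  expect_true("x" %in% attr(ms, "significant"))
  expect_match(ms$table$model[1], "x")
  av <- ms$averaged
  row <- av[av$coefficient == "psi_x", ]
  expect_gt(row$lcl, 0)    # averaged CI excludes zero
  # empty candidate set -> null-model set
  ms0 <- selection_workflow(h, covs, detection_candidates = character(),
                            occupancy_candidates = character())
  expect_equal(nrow(ms0$table), 1)
})
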