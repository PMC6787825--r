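hr <- function(h) h / 24 * 2 * pi

test_that("vm_kde normalizes, peaks correctly, and matches a fine-grid oracle", {
  # single observation: the density is the kernel itself, mode at the point
  d1 <- vm_kde(hr(3), kappa = 6)
  expect_equal(d1$grid[which.max(d1$y)], hr(3), tolerance = 2 * pi / 512)
  expect_equal(sum(d1$y) * 2 * pi / 512, 1, tolerance = 1e-6)
  # mixed sample: 512-grid values agree with direct evaluation at those angles
  set.seed(9)
  tt <- c(rvonmises(80, hr(2), 4), rvonmises(60, hr(15), 3))
  d <- vm_kde(tt, kappa = 5)
  direct <- vapply(d$grid, function(th)
    mean(exp(5 * (cos(th - tt) - 1))) / (2 * pi * besselI(5, 0, expon.scaled = TRUE)),
    1)
  expect_lt(max(abs(d$y - direct)), 1e-12)
  expect_equal(sum(d$y) * 2 * pi / 512, 1, tolerance = 1e-6)
  expect_error(vm_kde(numeric(0), 3), "empty")
  expect_error(vm_kde(tt, 0), "positive")
})

test_that("concentration monotonicity: isopleth width shrinks as kappa grows", {
  tt <- rep(hr(1), 50)
  widths <- vapply(c(2, 8, 32, 128), function(k)
    isopleth(vm_kde(tt, k), 0.99)$duration_hours, 1)
  expect_true(all(diff(widths) < 0))
})

test_that("plug-in bandwidth behaves like the Taylor rule", {
  set.seed(15)
  # more data, same distribution -> larger kappa (less smoothing) on average
  k_small <- mean(replicate(20, select_bandwidth(rvonmises(50, hr(2), 4))))
  k_large <- mean(replicate(20, select_bandwidth(rvonmises(800, hr(2), 4))))
  expect_gt(k_large, k_small)
  # near-uniform sample -> heavy smoothing (small kappa)
  k_unif <- select_bandwidth(runif(300, 0, 2 * pi))
  expect_lt(k_unif, 1)
  # within a factor 3 of a leave-one-out cross-validation oracle
  tt <- rvonmises(500, hr(4), 4)
  k_plug <- select_bandwidth(tt)
  k_cv <- oracle_cv_kappa(tt)
  expect_lt(max(k_plug / k_cv, k_cv / k_plug), 3)
  expect_error(select_bandwidth(hr(1)), "at least 2")
  # shared kappa is the arithmetic mean
  a <- rvonmises(100, hr(2), 4); b <- rvonmises(100, hr(14), 4)
  expect_equal(shared_kappa(list(a, b)),
               mean(c(select_bandwidth(a), select_bandwidth(b))))
  expect_equal(shared_kappa(list(a, a)), select_bandwidth(a))
})

test_that("isopleths hit their mass, nest, and match the sort-accumulate oracle", {
  set.seed(23)
  tt <- c(rvonmises(150, hr(20), 5), rvonmises(120, hr(4), 5))  # bimodal
  d <- vm_kde(tt, kappa = 4)
  for (level in c(0.5, 0.95)) {
    iso <- isopleth(d, level)
    expect_equal(iso$mass, level, tolerance = 1e-6)
    # oracle threshold: sort density, accumulate mass on the same grid
    c_or <- oracle_hdr_threshold(d$grid, d$y, level)
    member <- d$y >= iso$threshold
    member_or <- d$y >= c_or
    expect_lte(sum(xor(member, member_or)), 6)  # boundary cells only
  }
  iso50 <- isopleth(d, 0.5); iso95 <- isopleth(d, 0.95)
  expect_gte(iso50$threshold, iso95$threshold)  # 50% set inside 95% set
  expect_equal(nrow(iso50$intervals), 2)        # dusk + dawn core periods
  # unimodal symmetric density: single interval centred on the mode
  du <- vm_kde(rep(hr(13), 30), kappa = 3)
  isou <- isopleth(du, 0.5)
  expect_equal(nrow(isou$intervals), 1)
  mid <- unname((isou$intervals[1, 1] + isou$intervals[1, 2]) / 2) %% (2 * pi)
  expect_equal(radians_to_hours(mid), 13, tolerance = 0.2)
  expect_error(isopleth(d, 1.2), "level")
})

test_that("OVL obeys its identities, bounds and rotation equivariance", {
  set.seed(31)
  tA <- rvonmises(200, hr(2), 3)
  tB <- c(rvonmises(150, hr(9), 2), rvonmises(60, hr(22), 5))
  k <- shared_kappa(list(tA, tB))
  dA <- vm_kde(tA, k); dB <- vm_kde(tB, k)
  o <- ovl(dA, dB)
  expect_true(o >= 0 && o <= 1)
  expect_equal(o, ovl(dB, dA))                        # symmetric
  expect_equal(ovl(dA, dA), 1, tolerance = 1e-6)      # self-overlap
  # algebraic identity: integral min = 1 - 0.5 * integral |fA - fB|
  h <- 2 * pi / 512
  expect_equal(o, 1 - 0.5 * sum(abs(dA$y - dB$y)) * h, tolerance = 1e-12)
  # rotation equivariance (rotate by a grid multiple so the Riemann sums are
  # evaluated at congruent points)
  rot <- 37 * 2 * pi / 512
  dAr <- vm_kde((tA + rot) %% (2 * pi), k)
  dBr <- vm_kde((tB + rot) %% (2 * pi), k)
  expect_equal(ovl(dAr, dBr), o, tolerance = 1e-9)
  # near-disjoint concentrated densities 12 h apart
  dN <- vm_kde(rvonmises(200, hr(2), 50), 30)
  dD <- vm_kde(rvonmises(200, hr(14), 50), 30)
  expect_lt(ovl(dN, dD), 0.01)
})

test_that("conditional OVL truncates to isopleths and hits the 0 / 1 limits", {
  set.seed(47)
  tt <- rvonmises(300, hr(21), 3)
  for (lv in c(0.5, 0.95))
    expect_equal(conditional_ovl(tt, tt, lv), 1, tolerance = 1e-6)
  # strictly day-active vs night-active: disjoint 50% cores -> exactly 0
  night <- rvonmises(300, hr(2), 8)
  day <- rvonmises(300, hr(14), 8)
  expect_identical(conditional_ovl(night, day, 0.5), 0)
  # diffuse densities at 95%: conditional stays close to the plain OVL.
  # Derived bounds of the truncate-renormalize construction: on the
  # intersection of the two isopleth sets min(gA,gB) = min(fA,fB)/level, and
  # each density carries at most (1-level) of its mass outside its own set,
  # so (un - 2(1-level))/level <= conditional <= un/level.
  a <- rvonmises(250, hr(10), 0.8); b <- rvonmises(250, hr(12), 0.8)
  k <- shared_kappa(list(a, b))
  un <- ovl(vm_kde(a, k), vm_kde(b, k))
  cond <- conditional_ovl(a, b, 0.95, kappa = k)
  # 1e-3 slack: un and cond are integrated on different grids (512 vs 8192)
  expect_gte(cond, (un - 0.10) / 0.95 - 1e-3)
  expect_lte(cond, min(1, un / 0.95) + 1e-3)
})

test_that("with/without-dominant comparison partitions by station", {
  set.seed(59)
  ts_seq <- function(st, sp, n, mu, kappa, day0) {
    tod <- rvonmises(n, mu, kappa)
    record_table(rep(st, n), rep(sp, n),
                 as.POSIXct(as.Date(day0), tz = "UTC") +
                   86400 * seq_len(n) + round(tod / (2 * pi) * 86400))
  }
  # dominant at stations S1, S2 only; target everywhere with identical pattern
  recs <- Reduce(rbind_records, list(
    ts_seq("S1", "cat", 6, hr(1), 4, "2013-02-01"),
    ts_seq("S2", "cat", 6, hr(1), 4, "2013-02-01"),
    ts_seq("S1", "genet", 120, hr(22), 3, "2013-02-01"),
    ts_seq("S2", "genet", 120, hr(22), 3, "2013-02-01"),
    ts_seq("S3", "genet", 120, hr(22), 3, "2013-02-01"),
    ts_seq("S4", "genet", 120, hr(22), 3, "2013-02-01")))
  res <- with_without_comparison(recs, "cat", "genet")
  expect_equal(res$n_with, 240)
  expect_equal(res$n_without, 240)
  expect_false(res$low_sample)
  expect_gt(res$ovl_core, 0.75)        # identical generating pattern
  expect_gt(res$ovl_general, 0.85)
  # 6-h phase shift in the "with" stratum depresses core overlap
  recs2 <- Reduce(rbind_records, list(
    ts_seq("S1", "cat", 6, hr(1), 4, "2013-02-01"),
    ts_seq("S1", "genet", 150, hr(4), 6, "2013-02-01"),
    ts_seq("S3", "genet", 150, hr(22), 6, "2013-02-01")))
  res2 <- with_without_comparison(recs2, "cat", "genet")
  expect_lt(res2$ovl_core, res$ovl_core - 0.3)
  # degenerate cases
  expect_error(with_without_comparison(recs, "leopard", "genet"),
               "no stations")
  expect_error(with_without_comparison(recs2[recs2$station == "S1", ],
                                       "cat", "genet"), "one stratum")
})
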