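# Independent oracles used to freeze expected values. These stay deliberately
# naive (explicit loops, direct enumeration) and never share code with R/.

# Single-species occupancy likelihood by enumeration of the latent state.
oracle_occu_loglik <- function(Y, psi, p) {
  n <- nrow(Y)
  psi <- rep(psi, length.out = n)
  p <- rep(p, length.out = n)
  ll <- 0
  for (i in seq_len(n)) {
    y <- Y[i, ]
    act <- !is.na(y)
    if (!any(act)) next
    y <- y[act]
    L1 <- psi[i] * prod(ifelse(y == 1, p[i], 1 - p[i]))
    L0 <- (1 - psi[i]) * as.numeric(all(y == 0))
    ll <- ll + log(L1 + L0)
  }
  ll
}

# Two-species likelihood by enumeration of the four latent states per site,
# applying the per-occasion rBA/rBa rule literally.
oracle_ts_loglik <- function(YA, YB, pr) {
  n <- nrow(YA)
  g <- function(x) rep(x, length.out = n)
  psiA <- g(pr$psiA); psiBA <- g(pr$psiBA); psiBa <- g(pr$psiBa)
  pA <- g(pr$pA); pB <- g(pr$pB); rA <- g(pr$rA)
  rBA <- g(pr$rBA); rBa <- g(pr$rBa)
  bern <- function(y, p) ifelse(y == 1, p, 1 - p)
  ll <- 0
  for (i in seq_len(n)) {
    act <- !is.na(YA[i, ])
    if (!any(act)) next
    yA <- YA[i, act]; yB <- YB[i, act]
    t11 <- psiA[i] * psiBA[i] *
      prod(bern(yA, rA[i])) *
      prod(ifelse(yA == 1, bern(yB, rBA[i]), bern(yB, rBa[i])))
    t10 <- psiA[i] * (1 - psiBA[i]) * prod(bern(yA, pA[i])) *
      as.numeric(all(yB == 0))
    t01 <- (1 - psiA[i]) * psiBa[i] * as.numeric(all(yA == 0)) *
      prod(bern(yB, pB[i]))
    t00 <- (1 - psiA[i]) * (1 - psiBa[i]) *
      as.numeric(all(yA == 0) && all(yB == 0))
    ll <- ll + log(t11 + t10 + t01 + t00)
  }
  ll
}

# Greedy sequential independence filter, written as the literal rule.
oracle_independence <- function(times_sec, window_hours = 1) {
  keep <- logical(length(times_sec))
  last <- -Inf
  for (i in order(times_sec)) {
    if (times_sec[i] - last >= window_hours * 3600) {
      keep[i] <- TRUE
      last <- times_sec[i]
    }
  }
  keep
}

# HDR threshold by sort-and-accumulate on a density grid.
oracle_hdr_threshold <- function(grid, y, level) {
  h <- 2 * pi / length(grid)
  ord <- order(y, decreasing = TRUE)
  cm <- cumsum(y[ord] * h)
  y[ord][which(cm >= level)[1]]
}

# Leave-one-out cross-validated likelihood bandwidth for the von Mises KDE.
oracle_cv_kappa <- function(times, grid = exp(seq(log(0.2), log(200), length.out = 60))) {
  n <- length(times)
  score <- vapply(grid, function(k) {
    D <- exp(k * (cos(outer(times, times, "-")) - 1)) /
      (2 * pi * besselI(k, 0, expon.scaled = TRUE))
    fi <- (colSums(D) - diag(D)) / (n - 1)
    sum(log(fi))
  }, 1)
  grid[which.max(score)]
}

rbind_records <- function(a, b) {
  record_table(c(a$station, b$station), c(a$species, b$species),
               c(a$timestamp, b$timestamp))
}

# Tiny deterministic survey fixture used by several IO tests.
make_fixture_survey <- function() {
  eff <- station_effort(
    c("A", "B", "C"),
    deploy = c("2013-02-01", "2013-02-05", "2013-03-01"),
    retrieve = c("2013-04-17", "2013-04-20", "2013-04-30"),
    gaps = list(data.frame(start = "2013-03-01", end = "2013-03-05"), NULL, NULL))
  rec <- record_table(
    station = c("A", "A", "A", "B", "B", "C"),
    species = c("civet", "civet", "genet", "civet", "civet", "genet"),
    timestamp = c("2013-02-10T00:00", "2013-02-10T00:30", "2013-02-11T13:00",
                  "2013-02-20T22:00", "2013-02-20T23:00", "2013-03-10T02:15"))
  list(efforts = eff, records = rec)
}
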