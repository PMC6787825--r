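# Synthetic camera-trap surveys: stations & effort, station covariates,
# detection records with activity-pattern timestamps, and ground truth.
# All generators are deterministic given a seed (R's default Mersenne-Twister).

#' Von Mises random deviates
#'
#' Best-Fisher (1979) rejection sampler; reproducible under `set.seed()`.
#' @param n sample size.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0; 0 = circular uniform).
#' @return radians in [0, 2*pi).
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be non-negative")
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- stats::runif(1)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      u2 <- stats::runif(1)
      if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) break
    }
    u3 <- stats::runif(1)
    out[i] <- (mu + sign(u3 - 0.5) * acos(f)) %% (2 * pi)
  }
  out
}

#' Draw activity times from a von Mises mixture
#'
#' @param mixture list with numeric vectors `w` (weights summing to 1),
#'   `mu` (mean directions, radians) and `kappa` (concentrations).
#' @param n number of draws (> 0).
#' @param seed optional RNG seed.
#' @return radians in [0, 2*pi).
#' @export
simulate_activity_times <- function(mixture, n, seed = NULL) {
  if (n <= 0) stop("n must be positive")
  stopifnot(length(mixture$w) == length(mixture$mu),
            length(mixture$mu) == length(mixture$kappa))
  if (abs(sum(mixture$w) - 1) > 1e-8) stop("mixture weights must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(length(mixture$w), n, replace = TRUE, prob = mixture$w)
  out <- numeric(n)
  for (j in unique(comp)) {
    ii <- which(comp == j)
    out[ii] <- rvonmises(length(ii), mixture$mu[j], mixture$kappa[j])
  }
  out
}

#' Qualitative diel activity templates
#'
#' Mixture templates for the survey simulator: `"nocturnal"` (unimodal,
#' centred 01:00 — golden-cat-like), `"nocturnal_bimodal"` (dusk and dawn
#' peaks with a mid-night lull — genet-like), `"diurnal"` (unimodal midday —
#' mongoose-like), `"crepuscular"` (dusk/dawn), `"cathemeral"` (nearly
#' uniform).
#' @param name template name.
#' @return mixture list (`w`, `mu`, `kappa`).
#' @export
activity_template <- function(name = c("nocturnal", "nocturnal_bimodal",
                                       "diurnal", "crepuscular", "cathemeral")) {
  name <- match.arg(name)
  hr <- function(h) h / 24 * 2 * pi
  switch(name,
    nocturnal = list(w = 1, mu = hr(1), kappa = 2.5),
    nocturnal_bimodal = list(w = c(0.55, 0.45), mu = hr(c(20, 4)), kappa = c(4, 4)),
    diurnal = list(w = 1, mu = hr(13), kappa = 2.5),
    crepuscular = list(w = c(0.5, 0.5), mu = hr(c(6, 18)), kappa = c(6, 6)),
    cathemeral = list(w = 1, mu = hr(12), kappa = 0.2))
}

#' Simulation scenario for a camera-trap survey
#'
#' Defaults mirror the design of the emulated field study: 127 stations
#' (49 + 43 + 35 across three survey blocks), operational 76.6 (SD 13.8)
#' days (truncated at a 20-day minimum), 6-day occasions, and wet/dry season
#' assignment by calendar date.
#'
#' @param n_stations number of stations (default 127).
#' @param mean_days,sd_days,min_days operational-day distribution
#'   (normal, truncated below at `min_days`).
#' @param occasion_length occasion length in days (default 6).
#' @param species named list; each element is a list with link-scale
#'   coefficients `psi = c(intercept = , <covariate> = ...)`,
#'   `p = c(intercept = , ...)` (per-occasion detection) and `activity`
#'   (mixture list or template name).
#' @param two_species optional list for a dominant/subordinate pair:
#'   `dominant`, `subordinate` (labels), and probabilities `psiA, psiBA,
#'   psiBa, pA, pB, rA, rBA, rBa` (per-occasion scale).
#' @param collinear_pair if TRUE, the covariate table includes `stem_total`
#'   built to correlate with `large_stem_density` at r ~ 0.8, to exercise the
#'   collinearity screen.
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_stations = 127, mean_days = 76.6, sd_days = 13.8,
                         min_days = 20, occasion_length = 6,
                         species = NULL, two_species = NULL,
                         collinear_pair = FALSE) {
  if (is.null(species)) {
    species <- list(
      golden_cat = list(psi = c(intercept = stats::qlogis(0.55),
                                large_stem_density = 0.8),
                        p = c(intercept = stats::qlogis(0.30),
                              trail_width_max = 0.45),
                        activity = "nocturnal"),
      genet = list(psi = c(intercept = stats::qlogis(0.70),
                           shannon_h = 0.7),
                   p = c(intercept = stats::qlogis(0.40)),
                   activity = "nocturnal_bimodal"),
      mongoose = list(psi = c(intercept = stats::qlogis(0.85)),
                      p = c(intercept = stats::qlogis(0.50)),
                      activity = "diurnal"))
  }
  for (nm in names(species)) {
    act <- species[[nm]]$activity
    if (is.character(act)) species[[nm]]$activity <- activity_template(act)
  }
  structure(list(n_stations = n_stations, mean_days = mean_days,
                 sd_days = sd_days, min_days = min_days,
                 occasion_length = occasion_length, species = species,
                 two_species = two_species, collinear_pair = collinear_pair),
            class = "sim_scenario")
}

#' Simulate stations: effort windows and habitat covariates
#'
#' Operational windows are drawn from the scenario's truncated normal; deploy
#' dates are staggered over the survey year, which also sets the station's
#' season (wet: Mar-May & Sep-Nov; dry: Jun-Aug & Dec-Feb). Covariates are
#' drawn from independent normals on realistic scales (stems/ha, metres, mm,
#' proportions) with an optional built-in collinear pair (r ~ 0.8).
#'
#' @param scenario a [sim_scenario()].
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list with `efforts` (a `station_effort`) and `covariates`
#'   (data.frame keyed by station, including `season`).
#' @export
simulate_stations <- function(scenario, seed) {
  set.seed(seed)
  n <- scenario$n_stations
  st <- sprintf("ST%03d", seq_len(n))
  days <- round(stats::rnorm(n, scenario$mean_days, scenario$sd_days))
  while (any(days < scenario$min_days)) {  # truncate by redraw
    ii <- days < scenario$min_days
    days[ii] <- round(stats::rnorm(sum(ii), scenario$mean_days, scenario$sd_days))
  }
  deploy <- as.Date("2013-01-15") + sample.int(300, n, replace = TRUE)
  retrieve <- deploy + days - 1
  efforts <- station_effort(st, deploy, retrieve)
  month <- as.integer(format(deploy, "%m"))
  season <- ifelse(month %in% c(3:5, 9:11), "wet", "dry")
  covariates <- data.frame(
    station = st,
    large_stem_density = pmax(0, stats::rnorm(n, 450, 150)),
    small_stem_density = pmax(0, stats::rnorm(n, 2200, 800)),
    canopy_height_mean = pmax(2, stats::rnorm(n, 22, 6)),
    canopy_height_sd = pmax(0, stats::rnorm(n, 6, 2)),
    shannon_h = pmax(0, stats::rnorm(n, 2.2, 0.5)),
    trail_width_max = pmax(50, stats::rnorm(n, 320, 110)),
    undergrowth_mean = pmin(1, pmax(0, stats::rnorm(n, 0.45, 0.18))),
    season = factor(season, levels = c("dry", "wet")),
    stringsAsFactors = FALSE)
  if (isTRUE(scenario$collinear_pair)) {
    z <- (covariates$large_stem_density - 450) / 150
    covariates$stem_total <- 450 + 150 * (0.8 * z +
                                            sqrt(1 - 0.8^2) * stats::rnorm(n))
  }
  list(efforts = efforts, covariates = covariates)
}

# per-occasion detection probability -> daily probability
.daily_rate <- function(p_occ, occasion_length) 1 - (1 - p_occ)^(1 / occasion_length)

#' Simulate detection records for a scenario
#'
#' Single species: latent occupancy per station from psi(covariates); for
#' each active day a Bernoulli detection at the daily rate implied by the
#' per-occasion p (p = 1 - (1-q)^L); event timestamps get times of day drawn
#' from the species' activity mixture. The optional two-species block draws a
#' four-state latent pair from (psiA, psiBA, psiBa), then detects per
#' occasion: A with pA/rA, B with pB where A is absent and rBA/rBa where both
#' are present according to whether A was detected that occasion.
#'
#' @param scenario a [sim_scenario()].
#' @param stations output of [simulate_stations()].
#' @param seed RNG seed.
#' @return list with `records` (a `record_table`) and `truth` (latent states
#'   `z` per species, generating parameters, and — when a two-species block is
#'   present — the generating `phi` and `delta`).
#' @export
simulate_detections <- function(scenario, stations, seed) {
  set.seed(seed)
  efforts <- stations$efforts
  covs <- standardize_covariates(stations$covariates[-1])
  n <- nrow(efforts)
  L <- scenario$occasion_length
  recs <- list()
  truth <- list(z = list(), params = scenario$species)
  lin <- function(coefs) {
    eta <- rep(coefs[["intercept"]], n)
    for (nm in setdiff(names(coefs), "intercept")) {
      if (!nm %in% names(covs)) stop("scenario references missing covariate: ", nm)
      eta <- eta + coefs[[nm]] * covs[[nm]]
    }
    stats::plogis(eta)
  }
  for (sp in names(scenario$species)) {
    cfg <- scenario$species[[sp]]
    psi <- lin(cfg$psi); p_occ <- lin(cfg$p)
    q <- .daily_rate(p_occ, L)
    z <- stats::rbinom(n, 1, psi)
    truth$z[[sp]] <- z
    for (i in seq_len(n)) {
      if (z[i] == 0) next
      days <- .active_days(efforts, i)
      hit <- stats::runif(length(days)) < q[i]
      nd <- sum(hit)
      if (nd == 0) next
      tod <- simulate_activity_times(cfg$activity, nd)
      recs[[length(recs) + 1]] <- data.frame(
        station = efforts$station[i], species = sp,
        timestamp = as.POSIXct(days[hit], tz = "UTC") + round(tod / (2 * pi) * 86400),
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(scenario$two_species)) {
    ts <- scenario$two_species
    zA <- stats::rbinom(n, 1, ts$psiA)
    zB <- stats::rbinom(n, 1, ifelse(zA == 1, ts$psiBA, ts$psiBa))
    truth$z[[ts$dominant]] <- zA
    truth$z[[ts$subordinate]] <- zB
    truth$phi <- sif_occupancy(ts$psiA, ts$psiBA, ts$psiBa)
    truth$delta <- sif_detection(ts$rA, ts$rBA, ts$rBa)
    actA <- scenario$species[[ts$dominant]]$activity
    actB <- scenario$species[[ts$subordinate]]$activity
    if (is.null(actA)) actA <- activity_template("nocturnal")
    if (is.null(actB)) actB <- activity_template("nocturnal_bimodal")
    for (i in seq_len(n)) {
      days <- .active_days(efforts, i)
      if (length(days) == 0) next
      occ <- (as.integer(days - efforts$deploy[i])) %/% L + 1L
      for (k in unique(occ)) {
        kd <- days[occ == k]
        pick_day <- function() kd[sample.int(length(kd), 1)]
        yA <- if (zA[i] == 1)
          stats::rbinom(1, 1, if (zB[i] == 1) ts$rA else ts$pA) else 0L
        pBk <- if (zB[i] == 1) {
          if (zA[i] == 1) { if (yA == 1) ts$rBA else ts$rBa } else ts$pB
        } else 0
        yB <- stats::rbinom(1, 1, pBk)
        if (yA == 1)
          recs[[length(recs) + 1]] <- data.frame(
            station = efforts$station[i], species = ts$dominant,
            timestamp = as.POSIXct(pick_day(), tz = "UTC") +
              round(simulate_activity_times(actA, 1) / (2 * pi) * 86400),
            stringsAsFactors = FALSE)
        if (yB == 1)
          recs[[length(recs) + 1]] <- data.frame(
            station = efforts$station[i], species = ts$subordinate,
            timestamp = as.POSIXct(pick_day(), tz = "UTC") +
              round(simulate_activity_times(actB, 1) / (2 * pi) * 86400),
            stringsAsFactors = FALSE)
      }
    }
  }
  records <- if (length(recs) > 0) {
    df <- do.call(rbind, recs)
    record_table(df$station, df$species, df$timestamp)
  } else record_table(character(), character(), as.POSIXct(character(), tz = "UTC"))
  list(records = records, truth = truth)
}

#' Simulate a single-species detection history directly
#'
#' Occasion-level generator used by estimator-calibration tests: latent
#' occupancy Bernoulli(psi) per site, detections Bernoulli(z * p) per active
#' occasion.
#' @param n_sites,n_occasions dimensions.
#' @param psi,p scalars or per-site vectors.
#' @param miss optional logical matrix marking missing cells.
#' @param seed optional seed.
#' @return list with `Y` (matrix) and `z` (latent states).
#' @export
simulate_occu_history <- function(n_sites, n_occasions, psi, p, miss = NULL,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  psi <- rep(psi, length.out = n_sites)
  p <- rep(p, length.out = n_sites)
  z <- stats::rbinom(n_sites, 1, psi)
  Y <- matrix(stats::rbinom(n_sites * n_occasions, 1, rep(z * p, n_occasions)),
              n_sites, n_occasions)
  if (!is.null(miss)) Y[miss] <- NA_integer_
  list(Y = Y, z = z)
}

#' Simulate paired two-species detection histories directly
#'
#' Occasion-level generator matching the conditional two-species estimator's
#' assumptions exactly: four-state latent occupancy from (psiA, psiBA,
#' psiBa), detection of A with rA/pA, of B with pB, or rBA/rBa according to
#' whether A was detected on that occasion.
#' @param n_sites,n_occasions dimensions.
#' @param params list with `psiA, psiBA, psiBa, pA, pB, rA, rBA, rBa`.
#' @param seed optional seed.
#' @return list with `YA`, `YB`, latent `zA`, `zB`, and the generating `phi`
#'   and `delta`.
#' @export
simulate_two_species_history <- function(n_sites, n_occasions, params,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(TRUE, n_sites, n_occasions)
  sim <- .ts_simulate(n_sites, n_occasions, params, M)
  list(YA = sim$YA, YB = sim$YB, zA = sim$zA, zB = sim$zB,
       phi = sif_occupancy(params$psiA, params$psiBA, params$psiBa),
       delta = sif_detection(params$rA, params$rBA, params$rBa))
}
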