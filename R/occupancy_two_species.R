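# Conditional two-species occupancy (psiBa/rBa parameterization), constrained
# submodels, AIC ranking, and species interaction factors (Phi, delta).
#
# Species A is the dominant species, B the subordinate. Eight parameters:
#   psiA  occupancy of A
#   psiBA occupancy of B given A present
#   psiBa occupancy of B given A absent
#   pA    detection of A given B absent
#   pB    detection of B given A absent
#   rA    detection of A given both present
#   rBA   detection of B given both present and A detected (that occasion)
#   rBa   detection of B given both present and A not detected

.xlog <- function(n, v) ifelse(n == 0, 0, n * log(v))

#' Two-species occupancy log-likelihood
#'
#' Mixture over the four latent occupancy states per site with weights
#' psiA*psiBA, psiA*(1-psiBA), (1-psiA)*psiBa, (1-psiA)*(1-psiBa). Occasion
#' likelihoods use rA for A when both species are present and pA when A is
#' alone; for B they use pB when B is alone and, when both are present, rBA on
#' occasions where A was detected and rBa where it was not. Latent states
#' inconsistent with the observations contribute zero.
#'
#' @param YA,YB detection matrices (0/1/NA) for the dominant (A) and
#'   subordinate (B) species; must share dimensions and missingness.
#' @param params list with elements `psiA, psiBA, psiBa, pA, pB, rA, rBA,
#'   rBa`, each a scalar or per-site vector of probabilities.
#' @return log-likelihood (scalar).
#' @export
two_species_loglik <- function(YA, YB, params) {
  if (!identical(dim(YA), dim(YB))) stop("mismatched history dimensions")
  MA <- !is.na(YA); MB <- !is.na(YB)
  if (!identical(MA, MB)) stop("histories must share missingness pattern")
  n <- nrow(YA)
  g <- function(x) if (length(x) == 1) rep(x, n) else x
  psiA <- g(params$psiA); psiBA <- g(params$psiBA); psiBa <- g(params$psiBa)
  pA <- g(params$pA); pB <- g(params$pB); rA <- g(params$rA)
  rBA <- g(params$rBA); rBa <- g(params$rBa)
  M <- MA
  A1 <- YA == 1L & M; A0 <- YA == 0L & M
  B1 <- YB == 1L & M; B0 <- YB == 0L & M
  aK <- rowSums(M)
  dA <- rowSums(A1); dB <- rowSums(B1)
  nBA1 <- rowSums(A1 & B1); nBA0 <- rowSums(A1 & B0)
  nBa1 <- rowSums(A0 & B1); nBa0 <- rowSums(A0 & B0)
  lA_r <- .xlog(dA, rA) + .xlog(aK - dA, 1 - rA)
  lB_both <- .xlog(nBA1, rBA) + .xlog(nBA0, 1 - rBA) +
    .xlog(nBa1, rBa) + .xlog(nBa0, 1 - rBa)
  lA_p <- .xlog(dA, pA) + .xlog(aK - dA, 1 - pA)
  lB_p <- .xlog(dB, pB) + .xlog(aK - dB, 1 - pB)
  t11 <- psiA * psiBA * exp(lA_r + lB_both)
  t10 <- psiA * (1 - psiBA) * exp(lA_p) * (dB == 0)
  t01 <- (1 - psiA) * psiBa * exp(lB_p) * (dA == 0)
  t00 <- (1 - psiA) * (1 - psiBa) * (dA == 0 & dB == 0)
  L <- t11 + t10 + t01 + t00
  use <- aK > 0
  sum(log(L[use]))
}

# Build the per-site parameter list from the packed parameter vector.
# occ_free: psiBA differs from psiBa (extra intercept offset).
# det: "ind" (pB = rBA = rBa), "presence" (pB != rBA = rBa),
#      "detection" (pB, rBA, rBa all free).
.ts_unpack <- function(theta, XA, XB, XdA, XdB, occ_free, det) {
  i <- 0
  take <- function(k) { out <- theta[i + seq_len(k)]; i <<- i + k; out }
  bA <- take(ncol(XA))
  bB <- take(ncol(XB))
  gOcc <- if (occ_free) take(1) else 0
  aA <- take(ncol(XdA))
  gA <- take(1)
  aB <- take(ncol(XdB))
  d1 <- d2 <- 0
  if (det == "presence") { d1 <- d2 <- take(1) }
  if (det == "detection") { d1 <- take(1); d2 <- take(1) }
  list(psiA = stats::plogis(drop(XA %*% bA)),
       psiBA = stats::plogis(drop(XB %*% bB) + gOcc),
       psiBa = stats::plogis(drop(XB %*% bB)),
       pA = stats::plogis(drop(XdA %*% aA)),
       rA = stats::plogis(drop(XdA %*% aA) + gA),
       pB = stats::plogis(drop(XdB %*% aB)),
       rBA = stats::plogis(drop(XdB %*% aB) + d1),
       rBa = stats::plogis(drop(XdB %*% aB) + d2))
}

.ts_parnames <- function(XA, XB, XdA, XdB, occ_free, det) {
  nm <- c(paste0("psiA_", colnames(XA)), paste0("psiB_", colnames(XB)))
  if (occ_free) nm <- c(nm, "psiB_presA")
  nm <- c(nm, paste0("pA_", colnames(XdA)), "rA_offset",
          paste0("pB_", colnames(XdB)))
  if (det == "presence") nm <- c(nm, "rB_presA")
  if (det == "detection") nm <- c(nm, "rB_detA", "rB_nodetA")
  nm
}

# Fit one constrained two-species model.
.ts_fit_one <- function(YA, YB, XA, XB, XdA, XdB, occ_free, det, n_restarts = 3) {
  nm <- .ts_parnames(XA, XB, XdA, XdB, occ_free, det)
  npar <- length(nm)
  nll <- function(th) {
    v <- -two_species_loglik(YA, YB, .ts_unpack(th, XA, XB, XdA, XdB, occ_free, det))
    if (!is.finite(v)) 1e10 else v
  }
  best <- NULL
  for (attempt in 0:n_restarts) {
    start <- if (attempt == 0) rep(0, npar) else stats::rnorm(npar, 0, 0.75)
    opt <- tryCatch(stats::optim(start, nll, method = "BFGS",
                                 control = list(maxit = 800, reltol = 1e-10)),
                    error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-8) best <- opt
    if (best$convergence == 0) break
  }
  if (is.null(best)) stop("two-species optimization failed")
  th <- stats::setNames(best$par, nm)
  H <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  if (is.null(vc) || any(!is.finite(vc))) vc <- matrix(NA_real_, npar, npar)
  dimnames(vc) <- list(nm, nm)
  ll <- -best$value
  # parameters at covariate means (columnwise design means)
  param_fun <- function(theta) {
    mA <- matrix(colMeans(XA), 1); mB <- matrix(colMeans(XB), 1)
    mdA <- matrix(colMeans(XdA), 1); mdB <- matrix(colMeans(XdB), 1)
    .ts_unpack(theta, mA, mB, mdA, mdB, occ_free, det)
  }
  boundary <- any(abs(best$par) > 10)
  structure(list(theta = th, loglik = ll, K = npar, aic = -2 * ll + 2 * npar,
                 vcov = vc, converged = best$convergence == 0,
                 boundary = boundary,
                 occ_free = occ_free, det = det,
                 param_fun = param_fun,
                 params_hat = param_fun(best$par),
                 site_params = .ts_unpack(best$par, XA, XB, XdA, XdB, occ_free, det),
                 YA = YA, YB = YB,
                 label = paste0("psiBA", if (occ_free) "!=" else "=", "psiBa, det:", det)),
            class = "two_species_fit")
}

#' Fit the conditional two-species model set
#'
#' Enumerates the biological hypotheses as constrained submodels: occupancy of
#' the subordinate independent of (psiBA = psiBa) or influenced by
#' (psiBA != psiBa) the dominant's presence, crossed with detection of the
#' subordinate independent (pB = rBA = rBa), influenced by the dominant's
#' presence (pB != rBA = rBa), or additionally by its detection
#' (rBA != rBa). When covariates are supplied, each structure is fitted both
#' without and with them (slopes shared between the conditional occupancy /
#' detection legs). Models are ranked by AIC.
#'
#' @param historyA,historyB `detection_history` objects (or 0/1/NA matrices)
#'   for the dominant and subordinate species; same stations and occasions.
#' @param covariates optional standardized covariate data.frame.
#' @param psi_covariates,p_covariates covariate names for the occupancy legs
#'   (both species) and detection legs (both species).
#' @param occ occupancy structures to fit: FALSE (psiBA = psiBa), TRUE
#'   (psiBA != psiBa), or both (default).
#' @param det detection structures to fit (subset of `"ind"`, `"presence"`,
#'   `"detection"`; default all three).
#' @param n_restarts jittered restarts per model.
#' @return object of class `two_species_set`: ranked `fits`, summary `table`
#'   (with `delta` AIC and a `supported` flag for Delta < 2), `best`.
#' @export
fit_two_species <- function(historyA, historyB, covariates = NULL,
                            psi_covariates = character(),
                            p_covariates = character(),
                            occ = c(FALSE, TRUE),
                            det = c("ind", "presence", "detection"),
                            n_restarts = 3) {
  det <- match.arg(det, several.ok = TRUE)
  YA <- if (inherits(historyA, "detection_history")) historyA$matrix else historyA
  YB <- if (inherits(historyB, "detection_history")) historyB$matrix else historyB
  n <- nrow(YA)
  cov_sets <- list(list(psi = character(), p = character()))
  if (length(psi_covariates) + length(p_covariates) > 0)
    cov_sets <- c(cov_sets, list(list(psi = psi_covariates, p = p_covariates)))
  fits <- list()
  for (cs in cov_sets) {
    XA <- .occu_design(covariates, cs$psi, n)
    XB <- XA
    XdA <- .occu_design(covariates, cs$p, n)
    XdB <- XdA
    for (occ_free in occ) for (dt in det) {
      f <- tryCatch(.ts_fit_one(YA, YB, XA, XB, XdA, XdB, occ_free, dt,
                                n_restarts = n_restarts),
                    error = function(e) NULL)
      if (is.null(f)) next
      if (length(cs$psi) + length(cs$p) > 0)
        f$label <- paste0(f$label, " +cov(",
                          paste(unique(c(cs$psi, cs$p)), collapse = ","), ")")
      fits[[length(fits) + 1]] <- f
    }
  }
  conv <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  if (any(!conv)) warning(sum(!conv), " two-species fit(s) did not converge; excluded")
  fits <- fits[conv]
  if (length(fits) == 0) stop("no converged two-species fits")
  aic <- vapply(fits, `[[`, 1, "aic")
  ord <- order(aic)
  fits <- fits[ord]; aic <- aic[ord]
  tab <- data.frame(model = vapply(fits, `[[`, "", "label"),
                    K = vapply(fits, `[[`, 1L, "K"),
                    loglik = vapply(fits, `[[`, 1, "loglik"),
                    AIC = aic, delta = aic - aic[1],
                    supported = (aic - aic[1]) < 2,
                    boundary = vapply(fits, `[[`, TRUE, "boundary"),
                    stringsAsFactors = FALSE)
  structure(list(fits = fits, table = tab, best = fits[[1]]),
            class = "two_species_set")
}

#' @export
print.two_species_set <- function(x, ...) {
  cat("Two-species occupancy model set (AIC ranked)\n")
  tabr <- x$table; tabr[, 3:5] <- round(tabr[, 3:5], 3)
  print(tabr, row.names = FALSE)
  invisible(x)
}

#' Occupancy species interaction factor
#'
#' \deqn{\Phi = \psi_A \psi_{BA} / \{\psi_A [\psi_A \psi_{BA} +
#'   (1-\psi_A)\psi_{Ba}]\}}
#' the ratio of joint occupancy to the product of marginal occupancies.
#' Equals 1 under independence (psiBA = psiBa), < 1 for avoidance, > 1 for
#' attraction.
#'
#' @param psiA,psiBA,psiBa occupancy probabilities (vectorized).
#' @return Phi (>= 0).
#' @export
sif_occupancy <- function(psiA, psiBA, psiBa) {
  tied <- psiBA == psiBa      # exact by algebra: psiA*psiB / (psiA*psiB)
  den <- psiA * (psiA * psiBA + (1 - psiA) * psiBa)
  if (any(den == 0)) stop("SIF denominator is zero")
  out <- ifelse(tied, 1, psiA * psiBA / den)
  if (length(out) == 1) out[[1]] else out
}

#' Detection species interaction factor
#'
#' \deqn{\delta = r_A r_{BA} / \{r_A [r_A r_{BA} + (1-r_A) r_{Ba}]\}}
#' Equals 1 when rBA = rBa (co-detection independent given co-occurrence).
#'
#' @param rA,rBA,rBa detection probabilities (vectorized).
#' @return delta (>= 0).
#' @export
sif_detection <- function(rA, rBA, rBa) {
  tied <- rBA == rBa
  den <- rA * (rA * rBA + (1 - rA) * rBa)
  if (any(den == 0)) stop("SIF denominator is zero")
  out <- ifelse(tied, 1, rA * rBA / den)
  if (length(out) == 1) out[[1]] else out
}

# numeric gradient (central differences)
.numgrad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- rep(0, length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, 1)
}

.sif_interp <- function(value, lcl, ucl) {
  if (!is.finite(lcl) || !is.finite(ucl)) return(NA_character_)
  if (ucl < 1) "avoidance" else if (lcl > 1) "attraction" else "independent"
}

#' Species interaction factors with uncertainty
#'
#' Computes Phi and delta at the fitted parameters (evaluated at covariate
#' means), with standard errors by the delta method through the SIF formulas
#' using the fit covariance, Wald 95% intervals, and the interpretation rule:
#' SIF < 1 with CI excluding 1 = avoidance, > 1 with CI excluding 1 =
#' attraction, otherwise independent. If the Hessian-based covariance is not
#' available, a parametric-bootstrap fallback is used when `n_boot > 0`.
#'
#' @param fit a `two_species_fit`.
#' @param n_boot bootstrap replicates for the fallback SE (default 200).
#' @param seed optional seed for the bootstrap fallback.
#' @return object of class `sif_result` (a one-row data.frame with phi,
#'   delta, SEs, CIs and interpretation flags; `occ_interaction` and
#'   `det_interaction` record whether the model allowed each interaction).
#' @export
sif_uncertainty <- function(fit, n_boot = 200, seed = NULL) {
  phi_of <- function(th) {
    p <- fit$param_fun(th)
    sif_occupancy(p$psiA, p$psiBA, p$psiBa)
  }
  delta_of <- function(th) {
    p <- fit$param_fun(th)
    sif_detection(p$rA, p$rBA, p$rBa)
  }
  th <- unname(fit$theta)
  phi <- phi_of(th); del <- delta_of(th)
  V <- fit$vcov
  if (!any(is.na(V))) {
    gp <- .numgrad(phi_of, th); gd <- .numgrad(delta_of, th)
    phi_se <- sqrt(max(0, drop(t(gp) %*% V %*% gp)))
    del_se <- sqrt(max(0, drop(t(gd) %*% V %*% gd)))
  } else if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    sp <- fit$site_params
    n <- nrow(fit$YA); M <- !is.na(fit$YA)
    g <- function(x) if (length(x) == 1) rep(x, n) else x
    phis <- dels <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      sim <- .ts_simulate(n, ncol(fit$YA), sp, M)
      rf <- tryCatch(.ts_fit_one(sim$YA, sim$YB,
                                 matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
                                 matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
                                 matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
                                 matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
                                 fit$occ_free, fit$det, n_restarts = 1),
                     error = function(e) NULL)
      if (is.null(rf)) next
      p <- rf$params_hat
      phis[b] <- sif_occupancy(p$psiA, p$psiBA, p$psiBa)
      dels[b] <- sif_detection(p$rA, p$rBA, p$rBa)
    }
    phi_se <- stats::sd(phis, na.rm = TRUE)
    del_se <- stats::sd(dels, na.rm = TRUE)
  } else {
    phi_se <- del_se <- NA_real_
  }
  out <- data.frame(
    phi = phi, phi_se = phi_se,
    phi_lcl = phi - 1.96 * phi_se, phi_ucl = phi + 1.96 * phi_se,
    delta = del, delta_se = del_se,
    delta_lcl = del - 1.96 * del_se, delta_ucl = del + 1.96 * del_se,
    occ_interaction = fit$occ_free,
    det_interaction = fit$det != "ind",
    stringsAsFactors = FALSE)
  out$phi_interpretation <- .sif_interp(phi, out$phi_lcl, out$phi_ucl)
  out$delta_interpretation <- .sif_interp(del, out$delta_lcl, out$delta_ucl)
  class(out) <- c("sif_result", "data.frame")
  out
}

# Simulate paired histories from site-level two-species parameters, keeping a
# given missingness mask. Conditional detection of B is applied per occasion
# according to whether A was detected on that occasion.
.ts_simulate <- function(n, K, sp, M) {
  g <- function(x) if (length(x) == 1) rep(x, n) else x
  psiA <- g(sp$psiA); psiBA <- g(sp$psiBA); psiBa <- g(sp$psiBa)
  pA <- g(sp$pA); pB <- g(sp$pB); rA <- g(sp$rA)
  rBA <- g(sp$rBA); rBa <- g(sp$rBa)
  zA <- stats::rbinom(n, 1, psiA)
  zB <- stats::rbinom(n, 1, ifelse(zA == 1, psiBA, psiBa))
  YA <- YB <- matrix(NA_integer_, n, K)
  for (k in seq_len(K)) {
    yA <- stats::rbinom(n, 1, zA * ifelse(zB == 1, rA, pA))
    pBk <- ifelse(zA == 1, ifelse(yA == 1, rBA, rBa), pB)
    yB <- stats::rbinom(n, 1, zB * pBk)
    YA[, k] <- yA; YB[, k] <- yB
  }
  YA[!M] <- NA_integer_; YB[!M] <- NA_integer_
  list(YA = YA, YB = YB, zA = zA, zB = zB)
}
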