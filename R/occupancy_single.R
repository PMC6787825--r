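# Single-season, single-species occupancy: zero-inflated binomial likelihood,
# ML fitting, (Q)AICc, MacKenzie-Bailey GOF / c-hat, model ranking & averaging.

#' Occupancy model specification
#' @param psi character vector of occupancy covariate names (empty = intercept).
#' @param p character vector of detection covariate names (may include season).
#' @return object of class `occu_spec`.
#' @export
occu_spec <- function(psi = character(), p = character()) {
  structure(list(psi = psi, p = p), class = "occu_spec")
}

# Link-scale starting values: intercepts at the naive occupancy and the raw
# detection rate among sites with >= 1 detection; slopes at zero.
.occu_start <- function(Y, npsi, np) {
  d <- rowSums(Y == 1L, na.rm = TRUE)
  a <- rowSums(!is.na(Y))
  naive <- mean(d[a > 0] > 0)
  p_raw <- if (any(d > 0)) sum(d) / max(1, sum(a[d > 0])) else 0.2
  clamp <- function(x) min(max(x, 0.05), 0.95)
  c(stats::qlogis(clamp(naive)), rep(0, npsi - 1),
    stats::qlogis(clamp(p_raw)), rep(0, np - 1))
}

# Design matrix for a covariate subset (intercept-only when empty).
.occu_design <- function(covariates, vars, n) {
  if (length(vars) == 0) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  missing <- setdiff(vars, names(covariates))
  if (length(missing) > 0) stop("unknown covariate(s): ", paste(missing, collapse = ", "))
  stats::model.matrix(~ ., data = covariates[, vars, drop = FALSE])
}

#' Occupancy log-likelihood
#'
#' Zero-inflated binomial likelihood for a detection/non-detection history
#' with imperfect detection, logit links on both occupancy (psi) and
#' detection (p):
#' \deqn{\ell = \sum_i \log\left[\psi_i \prod_{k \in active}
#'   p_i^{y_{ik}} (1-p_i)^{1-y_{ik}} + (1-\psi_i) I\{\text{all } y_{ik}=0\}\right]}
#' Missing occasions contribute nothing; sites with zero active occasions are
#' skipped.
#'
#' @param Y sites x occasions matrix of 0/1/NA.
#' @param Xpsi,Xp design matrices (n_sites rows) for psi and p.
#' @param beta,alpha link-scale coefficient vectors for psi and p.
#' @return log-likelihood (scalar).
#' @export
occu_loglik <- function(Y, Xpsi, Xp, beta, alpha) {
  if (ncol(Xpsi) != length(beta) || ncol(Xp) != length(alpha))
    stop("design/parameter dimension mismatch")
  psi <- stats::plogis(drop(Xpsi %*% beta))
  p <- stats::plogis(drop(Xp %*% alpha))
  M <- !is.na(Y)
  a <- rowSums(M)
  d <- rowSums(Y == 1L & M, na.rm = TRUE)
  xlog <- function(n, v) ifelse(n == 0, 0, n * log(v))   # 0 * log(0) := 0
  logdet <- xlog(d, p) + xlog(a - d, 1 - p)
  L <- psi * exp(logdet) + (1 - psi) * (d == 0)
  use <- a > 0
  sum(log(L[use]))
}

#' Small-sample Akaike information criterion
#'
#' \eqn{AICc = -2\ell + 2K + 2K(K+1)/(n-K-1)} with n the number of sites.
#' @param loglik maximized log-likelihood.
#' @param K number of estimated parameters.
#' @param n effective sample size (number of sites).
#' @return AICc value.
#' @export
aicc <- function(loglik, K, n) {
  if (n <= K + 1) stop("n must exceed K + 1 for the AICc correction")
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Quasi-AICc for overdispersed data
#'
#' \eqn{QAICc = -2\ell/\hat c + 2K' + 2K'(K'+1)/(n-K'-1)} with
#' \eqn{K' = K + 1}: the variance inflation factor c-hat counts as an
#' estimated parameter.
#' @inheritParams aicc
#' @param chat variance inflation factor (> 0).
#' @return QAICc value.
#' @export
qaicc <- function(loglik, K, n, chat) {
  if (chat <= 0) stop("chat must be positive")
  Kp <- K + 1
  if (n <= Kp + 1) stop("n must exceed K + 2 for the QAICc correction")
  -2 * loglik / chat + 2 * Kp + 2 * Kp * (Kp + 1) / (n - Kp - 1)
}

#' Fit a single-species occupancy model by maximum likelihood
#'
#' Quasi-Newton (BFGS) optimization of [occu_loglik()] from zero-initialized
#' link-scale parameters, with up to `n_restarts` jittered restarts on
#' non-convergence. The parameter covariance is the inverse of the observed
#' information (numerically differentiated Hessian) at the optimum.
#'
#' @param history a `detection_history` (or plain 0/1/NA matrix).
#' @param covariates data.frame of station covariates aligned with the
#'   history's stations (standardize first; see [standardize_covariates()]).
#' @param spec an [occu_spec()].
#' @param n_restarts maximum jittered restarts (default 5).
#' @return object of class `occu_fit`: estimates (`beta`, `alpha`), `loglik`,
#'   `K`, `n_sites`, `vcov`, `aicc`, `converged`, plus the data and designs
#'   (needed by [mb_gof()]).
#' @export
fit_occu <- function(history, covariates = NULL, spec = occu_spec(),
                     n_restarts = 5) {
  Y <- if (inherits(history, "detection_history")) history$matrix else history
  n_all <- nrow(Y)
  active <- rowSums(!is.na(Y)) > 0
  if (any(!active)) {
    warning(sum(!active), " site(s) with zero active occasions skipped")
    Y <- Y[active, , drop = FALSE]
    if (!is.null(covariates)) covariates <- covariates[active, , drop = FALSE]
  }
  if (sum(Y == 1L, na.rm = TRUE) < 1) stop("no detections: cannot fit occupancy model")
  n <- nrow(Y)
  Xpsi <- .occu_design(covariates, spec$psi, n)
  Xp <- .occu_design(covariates, spec$p, n)
  npsi <- ncol(Xpsi); np <- ncol(Xp)
  nll <- function(par) {
    v <- -occu_loglik(Y, Xpsi, Xp, par[seq_len(npsi)], par[npsi + seq_len(np)])
    if (!is.finite(v)) 1e10 else v
  }
  # data-driven start (naive occupancy, raw conditional detection rate) plus
  # the zero start: the zero-inflated surface has a spurious psi -> 1 ridge
  # that quasi-Newton can follow from a bad start.
  smart <- .occu_start(Y, npsi, np)
  starts <- list(smart, rep(0, npsi + np))
  for (j in seq_len(n_restarts))
    starts[[2 + j]] <- smart + stats::rnorm(npsi + np, 0, 0.75)
  best <- NULL
  for (attempt in seq_along(starts)) {
    opt <- tryCatch(stats::optim(starts[[attempt]], nll, method = "BFGS",
                                 control = list(maxit = 500, reltol = 1e-10)),
                    error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-8) best <- opt
    if (attempt >= 2 && best$convergence == 0) break
  }
  if (is.null(best)) stop("optimization failed on all restarts")
  par <- best$par
  H <- tryCatch(stats::optimHess(par, nll), error = function(e) NULL)
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  if (is.null(vc) || any(!is.finite(vc)))
    vc <- matrix(NA_real_, length(par), length(par))
  beta <- stats::setNames(par[seq_len(npsi)], paste0("psi_", colnames(Xpsi)))
  alpha <- stats::setNames(par[npsi + seq_len(np)], paste0("p_", colnames(Xp)))
  dimnames(vc) <- list(c(names(beta), names(alpha)), c(names(beta), names(alpha)))
  K <- length(par)
  ll <- -best$value
  structure(list(spec = spec, beta = beta, alpha = alpha, loglik = ll,
                 K = K, n_sites = n, vcov = vc,
                 aicc = aicc(ll, K, n),
                 converged = best$convergence == 0,
                 Y = Y, Xpsi = Xpsi, Xp = Xp,
                 label = paste0("psi(", if (length(spec$psi)) paste(spec$psi, collapse = "+") else ".",
                                ") p(", if (length(spec$p)) paste(spec$p, collapse = "+") else ".", ")")),
            class = "occu_fit")
}

#' @export
print.occu_fit <- function(x, ...) {
  cat("Occupancy fit", x$label, "\n")
  cat("  logLik =", round(x$loglik, 3), " K =", x$K, " AICc =",
      round(x$aicc, 3), " converged:", x$converged, "\n")
  est <- c(x$beta, x$alpha)
  se <- sqrt(diag(x$vcov))
  print(round(cbind(estimate = est, se = se), 4))
  invisible(x)
}

#' Fitted occupancy / detection probabilities
#' @param object an `occu_fit`.
#' @param ... unused.
#' @return list with per-site `psi` and `p` vectors.
#' @export
fitted.occu_fit <- function(object, ...) {
  list(psi = stats::plogis(drop(object$Xpsi %*% object$beta)),
       p = stats::plogis(drop(object$Xp %*% object$alpha)))
}

# Pearson chi-square over detection-history frequencies, sites grouped into
# cohorts by missing-occasion pattern. Observed histories with expected
# frequency >= 2 are individual cells; smaller observed cells are pooled into
# a tail cell (stabilizes the statistic against rare histories); unobserved
# histories contribute their total expected mass (O = 0 implies
# (O-E)^2/E = E). The parametric bootstrap uses the identical statistic, so
# the reference distribution is consistent by construction.
.mb_chisq <- function(Y, psi, p) {
  M <- !is.na(Y)
  pat <- apply(M, 1, paste, collapse = "")
  chi2 <- 0
  for (cohort in unique(pat)) {
    ii <- which(pat == cohort)
    act <- which(M[ii[1], ])
    if (length(act) == 0) next
    hist_key <- apply(Y[ii, act, drop = FALSE], 1, paste, collapse = "")
    d_i <- rowSums(Y[ii, act, drop = FALSE] == 1L)
    obs <- table(hist_key)
    # site-level probability of a history depends only on its detection count
    d_of <- vapply(names(obs), function(h)
      sum(strsplit(h, "")[[1]] == "1"), 1L)
    a <- length(act)
    E <- vapply(d_of, function(d) {
      sum(psi[ii] * p[ii]^d * (1 - p[ii])^(a - d) + (1 - psi[ii]) * (d == 0))
    }, 1)
    O <- as.numeric(obs)
    keep <- E >= 2
    chi2 <- chi2 + sum((O[keep] - E[keep])^2 / E[keep])
    if (any(!keep))
      chi2 <- chi2 + (sum(O[!keep]) - sum(E[!keep]))^2 / sum(E[!keep])
    chi2 <- chi2 + max(0, length(ii) - sum(E))   # unobserved-history mass
  }
  chi2
}

#' MacKenzie-Bailey goodness-of-fit test and c-hat
#'
#' Pearson chi-square over observed vs expected detection-history frequencies
#' (cohorts by missing-data pattern), with the null distribution obtained by
#' parametric bootstrap from the fitted model. The variance inflation factor
#' is \eqn{\hat c = \chi^2_{obs} / \overline{\chi^2_{boot}}}.
#'
#' @param fit an `occu_fit` (typically the global model).
#' @param n_boot bootstrap replicates (default 1000; < 100 warns).
#' @param seed optional RNG seed.
#' @return list with `chi2_obs`, `p_value`, `chat`, `n_boot_ok`,
#'   `chi2_boot`.
#' @export
mb_gof <- function(fit, n_boot = 1000, seed = NULL) {
  if (n_boot < 100) warning("n_boot < 100: bootstrap p-value and c-hat are unstable")
  if (!is.null(seed)) set.seed(seed)
  fv <- fitted.occu_fit(fit)
  chi2_obs <- .mb_chisq(fit$Y, fv$psi, fv$p)
  Y <- fit$Y; M <- !is.na(Y); n <- nrow(Y)
  npsi <- ncol(fit$Xpsi); np <- ncol(fit$Xp)
  par_hat <- unname(c(fit$beta, fit$alpha))
  nll <- function(par, Yb) {
    v <- -occu_loglik(Yb, fit$Xpsi, fit$Xp, par[seq_len(npsi)], par[npsi + seq_len(np)])
    if (!is.finite(v)) 1e10 else v
  }
  boot <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    z <- stats::rbinom(n, 1, fv$psi)
    Yb <- matrix(NA_integer_, n, ncol(Y))
    det <- matrix(stats::rbinom(n * ncol(Y), 1, rep(z * fv$p, ncol(Y))), n, ncol(Y))
    Yb[M] <- det[M]
    if (sum(Yb == 1L, na.rm = TRUE) == 0) next   # degenerate replicate
    opt <- NULL
    for (st in list(par_hat, .occu_start(Yb, npsi, np))) {
      o <- tryCatch(stats::optim(st, nll, Yb = Yb, method = "BFGS",
                                 control = list(maxit = 300, reltol = 1e-9)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(opt) || o$value < opt$value)) opt <- o
    }
    if (is.null(opt)) next
    pb <- stats::plogis(drop(fit$Xp %*% opt$par[npsi + seq_len(np)]))
    psib <- stats::plogis(drop(fit$Xpsi %*% opt$par[seq_len(npsi)]))
    boot[b] <- .mb_chisq(Yb, psib, pb)
  }
  ok <- !is.na(boot)
  if (sum(ok) == 0) stop("all bootstrap replicates failed")
  list(chi2_obs = chi2_obs,
       p_value = mean(boot[ok] >= chi2_obs),
       chat = chi2_obs / mean(boot[ok]),
       n_boot_ok = sum(ok),
       chi2_boot = boot[ok])
}

# Criterion value for one fit under the set's c-hat rule.
.criterion <- function(fit, chat) {
  if (chat > 1) qaicc(fit$loglik, fit$K, fit$n_sites, chat)
  else aicc(fit$loglik, fit$K, fit$n_sites)
}

#' Rank a candidate set and model-average coefficients
#'
#' Models are ranked by AICc, or by QAICc with standard errors inflated by
#' sqrt(c-hat) when c-hat > 1 (overdispersion). Akaike weights
#' \eqn{w_m \propto \exp(-\Delta_m/2)} are renormalized over the models with
#' \eqn{\Delta < } `delta_max`. Coefficients are averaged conditionally on
#' inclusion (natural averaging), with unconditional standard errors
#' combining within-model variance and between-model spread.
#'
#' @param fits list of `occu_fit` objects (non-converged fits are excluded).
#' @param chat variance inflation factor (default 1 = no overdispersion).
#' @param delta_max averaging window on the Delta-(Q)AICc scale (default 6,
#'   strict `<`).
#' @return object of class `model_set`: ranked `table`, `fits`, `chat`,
#'   `criterion` name, and `averaged` coefficient table (estimate, SE,
#'   Wald 95% CI).
#' @export
rank_and_average <- function(fits, chat = 1, delta_max = 6) {
  conv <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  if (any(!conv)) {
    warning(sum(!conv), " non-converged fit(s) excluded from ranking")
    fits <- fits[conv]
  }
  if (length(fits) == 0) stop("no converged fits to rank")
  crit <- vapply(fits, .criterion, 1, chat = chat)
  ord <- order(crit)
  fits <- fits[ord]; crit <- crit[ord]
  delta <- crit - crit[1]
  sel <- delta < delta_max
  w <- numeric(length(fits))
  w[sel] <- exp(-delta[sel] / 2)
  w <- w / sum(w)
  tab <- data.frame(model = vapply(fits, `[[`, "", "label"),
                    K = vapply(fits, `[[`, 1L, "K"),
                    loglik = vapply(fits, `[[`, 1, "loglik"),
                    criterion = crit, delta = delta, weight = w,
                    in_average = sel, stringsAsFactors = FALSE)
  infl <- if (chat > 1) sqrt(chat) else 1
  coefs <- unique(unlist(lapply(fits[sel], function(f) names(c(f$beta, f$alpha)))))
  avg <- do.call(rbind, lapply(coefs, function(cn) {
    est <- se2 <- wt <- numeric()
    for (m in which(sel)) {
      th <- c(fits[[m]]$beta, fits[[m]]$alpha)
      if (cn %in% names(th)) {
        est <- c(est, th[[cn]])
        se2 <- c(se2, (infl^2) * fits[[m]]$vcov[cn, cn])
        wt <- c(wt, w[m])
      }
    }
    wt <- wt / sum(wt)
    ebar <- sum(wt * est)
    se <- sqrt(sum(wt * (se2 + (est - ebar)^2)))
    data.frame(coefficient = cn, estimate = ebar, se = se,
               lcl = ebar - 1.96 * se, ucl = ebar + 1.96 * se,
               stringsAsFactors = FALSE)
  }))
  structure(list(fits = fits, table = tab, chat = chat,
                 criterion = if (chat > 1) "QAICc" else "AICc",
                 delta_max = delta_max, averaged = avg),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat("Model set ranked by", x$criterion,
      if (x$chat > 1) paste0("(c-hat = ", round(x$chat, 3), ")"), "\n")
  tabr <- x$table
  tabr[, 3:6] <- round(tabr[, 3:6], 3)
  print(tabr, row.names = FALSE)
  cat("\nModel-averaged coefficients (Delta <", x$delta_max, "):\n")
  av <- x$averaged; av[, 2:5] <- round(av[, 2:5], 3)
  print(av, row.names = FALSE)
  invisible(x)
}

#' Detection-first covariate selection workflow
#'
#' Stage 1 selects the best detection model by (Q)AICc among intercept-only
#' and each single candidate, holding occupancy at intercept-only. Stage 2
#' tests each occupancy covariate univariately with the stage-1 detection
#' model; covariates whose Wald 95% CI (inflated by sqrt(c-hat) if c-hat > 1)
#' excludes zero are "significant". Stage 3 fits all additive combinations of
#' the significant covariates. The final ranking and averaging covers the
#' null, all stage-2 and all stage-3 models.
#'
#' @param history a `detection_history`.
#' @param covariates standardized station covariate data.frame.
#' @param detection_candidates,occupancy_candidates covariate name vectors.
#' @param chat variance inflation factor (e.g. from [mb_gof()]; default 1).
#' @param delta_max averaging window (default 6).
#' @return a `model_set` (see [rank_and_average()]); the chosen detection
#'   model is attached as attribute `"p_model"`, the significant occupancy
#'   covariates as `"significant"`.
#' @export
selection_workflow <- function(history, covariates, detection_candidates,
                               occupancy_candidates, chat = 1, delta_max = 6) {
  p_specs <- c(list(character()), as.list(detection_candidates))
  p_fits <- lapply(p_specs, function(pc)
    fit_occu(history, covariates, occu_spec(psi = character(), p = pc)))
  p_ok <- vapply(p_fits, function(f) isTRUE(f$converged), TRUE)
  p_fits <- p_fits[p_ok]; p_specs <- p_specs[p_ok]
  p_crit <- vapply(p_fits, .criterion, 1, chat = chat)
  best_p <- p_specs[[which.min(p_crit)]]

  null_fit <- p_fits[[which.min(p_crit)]]
  uni <- list(); signif <- character()
  infl <- if (chat > 1) sqrt(chat) else 1
  for (v in occupancy_candidates) {
    f <- tryCatch(fit_occu(history, covariates, occu_spec(psi = v, p = best_p)),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) next
    uni[[v]] <- f
    cn <- paste0("psi_", v)
    if (cn %in% names(f$beta)) {
      se <- infl * sqrt(f$vcov[cn, cn])
      if (is.finite(se) && abs(f$beta[[cn]]) - 1.96 * se > 0) signif <- c(signif, v)
    }
  }
  combos <- list()
  if (length(signif) >= 2) {
    for (k in 2:length(signif))
      combos <- c(combos, utils::combn(signif, k, simplify = FALSE))
  }
  combo_fits <- lapply(combos, function(cs)
    tryCatch(fit_occu(history, covariates, occu_spec(psi = cs, p = best_p)),
             error = function(e) NULL))
  combo_fits <- Filter(Negate(is.null), combo_fits)
  all_fits <- c(list(null_fit), uni, combo_fits)
  ms <- rank_and_average(all_fits, chat = chat, delta_max = delta_max)
  attr(ms, "p_model") <- best_p
  attr(ms, "significant") <- signif
  ms
}

#' Univariate significance scores across species
#'
#' For each candidate covariate, fits a univariate occupancy model per
#' species and returns the mean |estimate/SE| (Wald z) across species — the
#' aggregation used to decide which member of a collinear pair to retain.
#'
#' @param histories list of `detection_history` objects (one per species).
#' @param covariates standardized covariate data.frame.
#' @param candidates covariate names to score.
#' @param p_covariates detection covariates held fixed (default none).
#' @return named numeric vector of scores.
#' @export
univariate_scores <- function(histories, covariates, candidates,
                              p_covariates = character()) {
  sc <- vapply(candidates, function(v) {
    zs <- vapply(histories, function(h) {
      f <- tryCatch(fit_occu(h, covariates, occu_spec(psi = v, p = p_covariates)),
                    error = function(e) NULL)
      if (is.null(f) || !f$converged) return(NA_real_)
      cn <- paste0("psi_", v)
      se <- sqrt(f$vcov[cn, cn])
      if (!is.finite(se) || se == 0) return(NA_real_)
      abs(f$beta[[cn]] / se)
    }, 1)
    mean(zs, na.rm = TRUE)
  }, 1)
  stats::setNames(sc, candidates)
}
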