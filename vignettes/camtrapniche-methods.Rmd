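---
title: "Models and methods in camtrapniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in camtrapniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

camtrapniche analyses how a community of camera-trapped species partitions
its niche along three axes: space (habitat-driven site occupancy), direct
interaction (conditional co-occurrence with a dominant species), and time
(diel activity). This vignette documents the statistical models, the tunable
parameters and their defaults, what the synthetic-survey generator does and
does not emulate, and the numerical choices that matter. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## From photographs to detection histories

The raw unit is a timestamped photographic event of one species at one
station. Because an animal lingering in front of a camera produces bursts of
near-duplicate photographs, events are thinned to *independent* captures: a
record is kept if and only if it falls at least one hour (configurable) after
the last **retained** record of the same species at the same station — a
greedy forward scan, which is deterministic and idempotent, with "at least"
read inclusively (a gap of exactly 60 minutes keeps the record).

Independent events are collapsed into detection/non-detection occasions of 6
days (default), anchored per station at its deployment date, since stations
deploy on different dates. An occasion is `1` if the species was detected at
least once, `0` if the station was active with no detection, and missing
(`NA`) only if the station was inactive (failure, damage) for the *entire*
occasion: an occasion partially covered by a failure gap still permitted
detection for part of the time, so it stays active. The final partial
occasion is kept if it contains at least one active day. Survey summaries
report events per 100 effective trap nights (active station-days) and naive
occupancy (share of stations with any detection).

Timestamps are local clock time; no time-zone or solar arithmetic is applied
(the emulated study site is near-equatorial, where clock time and sun time
stay in near-constant phase).

## Habitat covariates

Station plots (30 m × 30 m) yield large-stem density (trees with DBH > 10 cm,
scaled by the nominal 900 m² plot area to stems/ha), small-stem density
(sapling counts over 3 m × 3 m subplots), canopy-height mean and SD,
trail-width mean and max, undergrowth covered-proportion mean and SD, and
tree-diversity indices: Shannon \(H = -\sum p_i \ln p_i\), Pielou
\(J = H/\ln S\) (undefined for \(S = 1\)), and Fisher's \(\alpha\) solving
\(S = \alpha \ln(1 + N/\alpha)\) by root finding (the left side is strictly
increasing in \(\alpha\), so the root is unique; \(S = N\) has no finite
solution and errors). Undergrowth density is consumed as an already-measured
proportion; the field photographic protocol that produces it is out of scope.

Collinear covariates are screened before modelling: while any pair has
Pearson \(|r| > 0.70\), the lowest-scoring covariate involved in an offending
pair is dropped (ties break alphabetically, later name dropped). The score is
the mean univariate Wald \(|z|\) of the covariate across the focal species'
occupancy fits — the source protocol keeps "the most significant covariate
across all species" without naming a metric, and this is a reproducible,
deterministic operationalization. Covariates are z-scored before fitting so
additive coefficients are comparable.

## Single-species occupancy

The zero-inflated binomial occupancy model treats true presence \(z_i\) at
site \(i\) as latent: \(z_i \sim \mathrm{Bern}(\psi_i)\), and detection on
active occasion \(k\) as \(y_{ik} \mid z_i \sim \mathrm{Bern}(z_i p_i)\),
with logit links on both \(\psi\) and \(p\) (the standard choice; the source
protocol does not state a link). The site likelihood mixes the occupied
product over active occasions with the unoccupied point mass at an all-zero
history; missing occasions contribute nothing.

**Optimization.** BFGS with two deterministic starts — a data-driven start
(naive occupancy and the raw detection rate among detected sites, clamped to
[0.05, 0.95] on the probability scale) and the zero start — plus up to five
jittered restarts on non-convergence, keeping the best optimum. The
data-driven start matters: the zero-inflated surface has a spurious
\(\psi \to 1\) ridge that quasi-Newton can follow from a cold start while
still reporting formal convergence. Covariance is the inverse observed
information (numeric Hessian); a non-invertible Hessian yields an NA
covariance and the fit is excluded from averaging.

**Ranking.** \(AICc = -2\ell + 2K + 2K(K+1)/(n-K-1)\) with \(n\) = sites.
Overdispersion is assessed on the global model by the MacKenzie–Bailey
parametric bootstrap: the Pearson \(\chi^2\) over observed vs expected
detection-history frequencies (sites cohorted by missing-occasion pattern) is
compared to its bootstrap null, and \(\hat c = \chi^2_{obs} /
\overline{\chi^2_{boot}}\). Observed cells with expected frequency below 2
are pooled into one tail cell; the expected mass of *unobserved* histories is
added as its own term (O = 0 implies \((O-E)^2/E = E\)). Pooling the
unobserved mass *into* the tail cell — a literal reading of one design note —
degenerates the statistic to ~0 whenever every observed history is rare, so
the two are kept separate. When \(\hat c > 1\), ranking switches to QAICc
with \(K' = K + 1\) (\(\hat c\) counts as estimated — the common convention)
and standard errors inflate by \(\sqrt{\hat c}\); \(\hat c \le 1\) leaves
AICc untouched.

**Selection workflow** (detection first): (1) choose the best detection model
among intercept-only and each single candidate, holding \(\psi\) at
intercept-only; (2) test each occupancy covariate univariately with that
detection model, calling it significant when its Wald 95% CI excludes zero;
(3) fit all *additive* combinations of significant covariates (the protocol
says "additively combined", so no interactions). The final set — null,
univariate and combination models — is ranked, and coefficients are averaged
over models with \(\Delta < 6\) (strict), conditionally on inclusion, with
unconditional SEs combining within-model variance and between-model spread
(\(\widehat{var} = \sum w'_m (var_m + (\beta_m - \bar\beta)^2)\)).

## Two-species conditional occupancy

The conditional parameterization puts the dominant species A first:
\(\psi_A\); \(\psi_{BA}, \psi_{Ba}\) (subordinate occupancy given A
present/absent); \(p_A, p_B\) (detection when alone); \(r_A\) (A's detection
when both present); \(r_{BA}, r_{Ba}\) (B's detection when both present,
split per occasion by whether A was detected on that occasion). The site
likelihood mixes the four latent states; states inconsistent with the
observations contribute zero. Under the full independence ties the joint
log-likelihood equals the sum of the two single-species log-likelihoods (a
tested invariant).

The biological hypotheses are fitted as constrained submodels — occupancy
tied (\(\psi_{BA} = \psi_{Ba}\)) or free, crossed with detection independent
(\(p_B = r_{BA} = r_{Ba}\)), presence-affected (\(p_B \ne r_{BA} = r_{Ba}\)),
or detection-affected (all free) — optionally with and without the best
single-species habitat covariates, and ranked by AIC (not AICc, matching the
source protocol for this stage); models with \(\Delta\mathrm{AIC} < 2\) are
flagged as supported.

Species interaction factors:
\[
\Phi = \frac{\psi_A \psi_{BA}}{\psi_A\,[\psi_A \psi_{BA} + (1-\psi_A)\psi_{Ba}]},
\qquad
\delta = \frac{r_A r_{BA}}{r_A\,[r_A r_{BA} + (1-r_A) r_{Ba}]}.
\]
The printed source expressions lack grouping parentheses; this reading is the
joint probability over the product of marginals and reproduces the stated
independence behavior (\(\Phi = \delta = 1\) under ties — computed via an
exact algebraic shortcut, because naive floating point misses exactness by
an ulp). SIF uncertainty comes from the delta method through the SIF formula
using the fit covariance (numeric gradient), with a parametric-bootstrap
fallback when the Hessian is singular. Interpretation follows the CI-vs-1
rule: below 1 with CI excluding 1 = avoidance, above = attraction, otherwise
independent. Models without an occupancy interaction force \(\Phi = 1\) with
SE 0; the pipeline's SIF table blanks \(\Phi\) for such best models, so
report rows without an occupancy SIF are supported.

## Diel activity

Capture times map the 24-h clock to the circle (24 h = \(2\pi\)). The
activity density is a von Mises kernel estimate
\(f(\theta) = n^{-1}\sum_i vM(\theta; t_i, \kappa)\) on a 512-point grid
(sub-3-minute resolution; an 8192-point refinement is used internally and in
tests). The smoothing parameter is the Taylor rule-of-thumb plug-in
\(\kappa = [3 n \hat\kappa^2 I_2(2\hat\kappa) / (4\sqrt\pi\,
I_0(\hat\kappa)^2)]^{2/5}\) with \(\hat\kappa\) the ML von Mises
concentration capped at 3 (the conventional cap for activity data). Scaled
Bessel functions keep everything finite at large \(\kappa\). Within any
multi-species comparison a single shared \(\kappa\) — the arithmetic mean of
the per-sample plug-ins — is used; a density reported alone uses its own.

Activity isopleths are highest-density regions: the smallest set
\(\{\theta : f(\theta) \ge c\}\) with mass equal to the level (0.50 core,
0.95 general). The threshold is found by root solving with linear
interpolation inside boundary grid cells, so the returned mass matches the
level to ~1e-9 — well inside the 1e-3 requirement — and nesting (50% inside
95%) holds by construction of superlevel sets. Intervals wrap across
midnight.

Overlap is \(OVL = \int \min(f_A, f_B)\,d\theta = 1 - TV\), the circular
\(\hat\Delta_1\) statistic. *Conditional* OVL truncates each density to its
own level-isopleth and renormalizes before integrating the minimum — the
documented reading of the source's "conditional overlap", chosen because it
reproduces the printed limiting behaviors (identical samples give 1 at any
level; strictly day-active vs night-active samples give exactly 0 at the 50%
level, since their cores are disjoint). A consequence worth knowing: at level
\(\lambda\), conditional OVL is bounded by \((OVL - 2(1-\lambda))/\lambda\)
from below and \(OVL/\lambda\) from above, so it can sit slightly below the
plain OVL when the exclusion zones misalign — this is structural, not noise.
The with/without-dominant comparison partitions a target species' detections
by whether their station ever recorded the dominant, builds both densities
with a shared \(\kappa\), and reports core and general conditional OVL,
flagging strata with fewer than 10 events.

## The synthetic world

The generator emulates the survey design it is meant to test: 127 stations,
operational days drawn from Normal(76.6, 13.8) truncated below at 20 days
(redrawn, so the realized mean stays near 76.6), 6-day occasions, and wet/dry
season from the deployment month (wet: Mar–May, Sep–Nov). Covariates are
independent normals on field-realistic scales (e.g. ~450 large stems/ha,
canopy ~22 m, trails ~320 mm) with an optional built-in collinear pair
(r = 0.8) to exercise the screen; these scales are stated once here and not
revisited. Single-species detections are generated at daily resolution — the
per-occasion \(p\) converts to a daily rate via \(p = 1-(1-q)^6\) — so the
same records exercise the summary, activity and occupancy layers
consistently; the two-species block generates at occasion granularity to
match the conditional estimator's assumptions exactly. Activity timestamps
come from von Mises mixtures with qualitative templates (nocturnal unimodal,
nocturnal-bimodal with a mid-night lull, diurnal, crepuscular, near-uniform).
Draws use R's Mersenne-Twister via `set.seed`, with the Best–Fisher rejection
sampler for von Mises deviates; everything is reproducible from a single
integer seed.

What the generator does **not** emulate: spatial autocorrelation between
stations (the real design spaced stations 600–800 m and treated them as
independent, as does the estimator), animal movement and trap-shyness,
multi-camera redundancy within a station, seasonal drift in activity, and
misidentification. A green recovery test therefore establishes that the
estimators recover the parameters of their own data-generating model at the
study's scale — not that the field estimates were unbiased.

## Numerical choices and degenerate inputs

- Optimizer: BFGS, relative tolerance 1e-10, ≤ 500 iterations, jittered
  restarts; two-species fits flag |link-scale estimate| > 10 as boundary.
- All-detections-everywhere data pushes \(\hat\psi \to 1\); handled without
  error (estimates sit at the clamp of `plogis`).
- Sites with zero active occasions are skipped with a warning; a species
  absent from the records yields an all-zero history (fitting then errors:
  no detections).
- GOF bootstrap replicates that fail to refit or contain no detections are
  dropped and counted.
- Heterogeneity calibration uses a bimodal site mixture of detection
  probabilities (0.10/0.65): logit-scale Gaussian heterogeneity at moderate
  SD inflates \(\hat c\) only marginally, while the two-group mixture is the
  classic overdispersion scenario and shows the \(\hat c > 1\) direction
  clearly.
- Model-averaging weight renormalization is over the \(\Delta <\) 6 set only;
  a single-model set gets weight 1.

## Known limitations

Single-season models only (no dynamics, no Bayesian fitting); two-species
models assume a fixed dominant and share covariate slopes between the
conditional legs; no bootstrap CIs on OVL (the source reports none);
detection covariates are station-level (an occasion-varying season within a
station is not supported — each station's deployment sits within one
season in the emulated design).
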