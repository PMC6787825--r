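# camtrapniche

Niche-partitioning analysis for camera-trap surveys of small-carnivore
communities — or any detection/non-detection wildlife survey. The package
takes timestamped photographic records plus station effort and habitat
tables, and quantifies how species divide their niche along three axes:

1. **Space** — single-season site-occupancy models with imperfect detection
   (zero-inflated binomial: ψ = probability a station is occupied/used,
   p = per-occasion detection probability, logit links), with a
   detection-first covariate selection workflow, AICc/QAICc ranking,
   MacKenzie–Bailey parametric-bootstrap goodness-of-fit (ĉ), and model
   averaging over the Δ < 6 set.
2. **Interaction** — conditional two-species occupancy (ψBa/rBa
   parameterization; dominant species A, subordinate B) with constrained
   submodels ranked by AIC, and species interaction factors

   Φ = ψA·ψBA / (ψA·[ψA·ψBA + (1−ψA)·ψBa]),  δ = rA·rBA / (rA·[rA·rBA + (1−rA)·rBa])

   where Φ, δ = 1 means independence, < 1 avoidance, > 1 attraction (judged
   by whether the Wald 95% CI excludes 1).
3. **Time** — circular diel activity densities by von Mises kernel smoothing
   (Taylor plug-in bandwidth κ), 50%/95% highest-density activity isopleths,
   and overlap coefficients OVL = ∫ min(f_A, f_B) dθ (the circular Δ̂₁),
   including the *conditional* OVL between isopleth-truncated densities and
   with/without-dominant activity comparisons.

A fully seeded synthetic-survey generator (127 stations operational
76.6 ± 13.8 days by default, covariate-driven occupancy and detection,
two-species interaction scenarios, von Mises activity mixtures) makes every
stage testable without any field data. Supporting utilities cover record
tables, effort tables with failure gaps, a 1-hour temporal independence
filter, 6-day occasion detection histories, Table-style survey summaries, and
station habitat covariates with Shannon H, Pielou J and Fisher's α.

## Worked example

Simulate the default survey world, summarize it, fit the occupancy selection
workflow for one species, and look at activity:

```r
library(camtrapniche)

sc  <- sim_scenario()                       # 127 stations, 3 species
st  <- simulate_stations(sc, seed = 21)
sim <- simulate_detections(sc, st, seed = 22)

recs <- independence_filter(sim$records)    # >= 1 h between retained events
survey_summary(recs, st$efforts)
#>      species n_events trap_nights capture_rate naive_occupancy
#> 1      genet      590        9749     6.051903       0.7322835
#> 2 golden_cat      280        9749     2.872089       0.4566929
#> 3   mongoose      906        9749     9.293261       0.8425197
```

`capture_rate` is events per 100 effective trap nights; `naive_occupancy` is
the share of stations with at least one detection, uncorrected for imperfect
detection — the occupancy model corrects it.

```r
h    <- build_history(recs, st$efforts, "golden_cat")   # 6-day occasions
covs <- standardize_covariates(st$covariates[-1])
ms   <- selection_workflow(h, covs,
          detection_candidates = c("trail_width_max", "undergrowth_mean"),
          occupancy_candidates = c("large_stem_density", "shannon_h",
                                   "canopy_height_mean"))
ms
#> Model set ranked by AICc
#>                                       model K   loglik criterion  delta weight
#>  psi(large_stem_density) p(trail_width_max) 4 -527.883  1064.094  0.000      1
#>                   psi(.) p(trail_width_max) 3 -543.384  1092.964 28.869      0
#>           psi(shannon_h) p(trail_width_max) 4 -543.101  1094.530 30.436      0
#>  psi(canopy_height_mean) p(trail_width_max) 4 -543.350  1095.027 30.933      0
#>
#> Model-averaged coefficients (Delta < 6):
#>             coefficient estimate    se    lcl    ucl
#>         psi_(Intercept)   -0.147 0.211 -0.560  0.266
#>  psi_large_stem_density    1.233 0.267  0.710  1.755
#>           p_(Intercept)   -0.852 0.084 -1.017 -0.686
#>       p_trail_width_max    0.530 0.095  0.343  0.717
```

The generator's true golden-cat effects are a large-stem-density coefficient
of 0.8 on ψ and a max-trail-width coefficient of 0.45 on p: both covariates
are selected, their averaged CIs exclude zero, and both CIs cover the truth.
The two null-effect covariates are not significant and carry no weight.

```r
tt <- time_to_radians(recs$timestamp[recs$species == "genet"])
d  <- vm_kde(tt, select_bandwidth(tt))
isopleth(d, 0.5)
#> 50% activity isopleth: 2 interval(s), 6.74 h total
#>      start_h end_h
#> [1,]    3.02  5.29
#> [2,]   18.01 22.48
```

The genet template is nocturnal-bimodal (dusk and dawn peaks with a mid-night
lull), and the fitted 50% core correctly splits into an evening and a
pre-dawn interval. Two-species models against the (independently generated)
golden cat rank the independence structure first and force Φ = 1 on the tied
fit:

```r
tsf <- fit_two_species(h, build_history(recs, st$efforts, "genet"))
tsf$table[1:3, c("model", "K", "AIC", "delta")]
#>                       model K      AIC    delta
#> 1      psiBA=psiBa, det:ind 5 2918.745 0.000000
#> 2 psiBA=psiBa, det:presence 6 2920.530 1.785178
#> 3     psiBA!=psiBa, det:ind 6 2920.727 1.982107
sif_uncertainty(tsf$best)[, c("phi", "delta", "phi_interpretation")]
#>   phi delta phi_interpretation
#> 1   1     1        independent
```

An end-to-end run (`run_pipeline(pipeline_config(scenario = sc, ...))`)
chains every stage and writes the summary, averaged-coefficient, SIF and
overlap tables as CSV. A command-line front end is installed as
`exec/camtrapniche` (`summarize`, `simulate`, `activity`, `run`).

## Further reading

`vignettes/camtrapniche-methods.Rmd` documents the models and their
assumptions, every tunable default (independence window, occasion length,
correlation and Δ thresholds, grid sizes, bandwidth rule), what the synthetic
world does and does not emulate, numerical choices, and known limitations.
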