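# Station-level vegetation covariates, diversity indices, collinearity screen.

#' Shannon diversity index H
#'
#' \eqn{H = -\sum p_i \ln p_i} over species with positive counts (natural log).
#' @param species_counts non-negative counts, at least one positive.
#' @return H (>= 0; 0 for a single species).
#' @export
shannon_h <- function(species_counts) {
  if (any(species_counts < 0)) stop("counts must be non-negative")
  x <- species_counts[species_counts > 0]
  if (length(x) == 0) stop("all counts are zero")
  p <- x / sum(x)
  -sum(p * log(p))
}

#' Pielou evenness index J
#'
#' \eqn{J = H / \ln S} where S is the number of species present. Undefined
#' (error) for a single species.
#' @inheritParams shannon_h
#' @return J in [0, 1].
#' @export
pielou_j <- function(species_counts) {
  S <- sum(species_counts > 0)
  if (S < 2) stop("Pielou's J is undefined for fewer than 2 species")
  shannon_h(species_counts) / log(S)
}

#' Fisher's alpha
#'
#' Solves \eqn{S = \alpha \ln(1 + N/\alpha)} numerically for the diversity
#' parameter of Fisher's log-series, given S species among N individuals.
#' The left side is strictly increasing in alpha, so the root is unique.
#'
#' @param S number of species (1 <= S < N; S = N has no finite solution).
#' @param N number of individuals.
#' @return alpha, to |S_fit - S| < 1e-9.
#' @export
fishers_alpha <- function(S, N) {
  if (S < 1 || N < 1 || S > N) stop("need 1 <= S <= N")
  if (S == N) stop("S = N: Fisher's alpha has no finite solution")
  f <- function(a) a * log1p(N / a) - S
  lo <- 1e-12
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Station covariates from a habitat-plot tally
#'
#' Aggregates the field tally of one 30 m x 30 m station plot: trees with
#' DBH > 10 cm ("large stems"), sapling counts from 3 m x 3 m subplots
#' ("small stems"), trail widths and undergrowth covered-proportions measured
#' along trails. Densities are scaled to per-hectare using the nominal plot
#' areas; diversity indices are computed from the large-tree species tally.
#'
#' @param trees data.frame with columns `species`, `dbh_cm`, `height_m`
#'   (one row per large stem; all DBH must exceed 10 cm). May have 0 rows.
#' @param saplings integer vector of sapling counts, one per 3 m x 3 m subplot.
#' @param trail_widths_mm numeric vector of trail-width measurements (mm).
#' @param undergrowth numeric vector of covered proportions in [0, 1].
#' @param station_id station label.
#' @param plot_area_m2,sapling_subplot_area_m2 nominal areas (900, 9).
#' @return one-row data.frame of named station covariates.
#' @export
station_covariates <- function(trees, saplings, trail_widths_mm, undergrowth,
                               station_id = NA_character_,
                               plot_area_m2 = 900, sapling_subplot_area_m2 = 9) {
  if (nrow(trees) > 0 && any(trees$dbh_cm <= 10))
    stop("tree records must have DBH > 10 cm")
  if (any(undergrowth < 0 | undergrowth > 1))
    stop("undergrowth proportions must lie in [0, 1]")
  counts <- if (nrow(trees) > 0) as.vector(table(trees$species)) else integer()
  S <- length(counts); N <- sum(counts)
  data.frame(
    station = station_id,
    large_stem_density = nrow(trees) / plot_area_m2 * 1e4,
    small_stem_density = if (length(saplings) > 0)
      sum(saplings) / (length(saplings) * sapling_subplot_area_m2) * 1e4 else 0,
    canopy_height_mean = if (nrow(trees) > 0) mean(trees$height_m) else NA_real_,
    canopy_height_sd = if (nrow(trees) > 1) stats::sd(trees$height_m) else 0,
    trail_width_mean = mean(trail_widths_mm),
    trail_width_max = max(trail_widths_mm),
    undergrowth_mean = mean(undergrowth),
    undergrowth_sd = if (length(undergrowth) > 1) stats::sd(undergrowth) else 0,
    shannon_h = if (S >= 1) shannon_h(counts) else NA_real_,
    pielou_j = if (S >= 2) pielou_j(counts) else NA_real_,
    fishers_alpha = if (S >= 1 && S < N) fishers_alpha(S, N) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Z-score standardization of covariates
#'
#' Centers and scales every numeric column (constant columns are centered
#' only). Standardizing puts additive-model coefficients on a comparable
#' scale before occupancy fitting.
#' @param covariates data.frame of station covariates.
#' @return data.frame with numeric columns standardized.
#' @export
standardize_covariates <- function(covariates) {
  for (nm in names(covariates)) {
    x <- covariates[[nm]]
    if (is.numeric(x)) {
      s <- stats::sd(x)
      covariates[[nm]] <- if (is.na(s) || s == 0) x - mean(x) else (x - mean(x)) / s
    }
  }
  covariates
}

#' Screen collinear covariates
#'
#' Iteratively removes covariates until no pair has Pearson |r| above the
#' threshold. At each step the lowest-scoring covariate involved in any
#' offending pair is dropped (score = e.g. mean |estimate/SE| across species
#' from univariate occupancy fits); ties break alphabetically (later name
#' dropped). Constant covariates, whose correlation is undefined, are dropped
#' up front with a warning. Deterministic given inputs.
#'
#' @param covariate_table data.frame of numeric candidate covariates.
#' @param scores named numeric vector: a significance score per covariate
#'   (higher = retained preferentially).
#' @param threshold correlation threshold (default 0.70).
#' @return character vector of retained covariate names.
#' @export
screen_collinear <- function(covariate_table, scores, threshold = 0.70) {
  vars <- names(covariate_table)
  if (!all(vars %in% names(scores)))
    stop("scores missing for: ",
         paste(setdiff(vars, names(scores)), collapse = ", "))
  const <- vars[vapply(covariate_table, function(x) stats::sd(x) == 0 || is.na(stats::sd(x)), TRUE)]
  if (length(const) > 0) {
    warning("dropping constant covariate(s): ", paste(const, collapse = ", "))
    vars <- setdiff(vars, const)
  }
  repeat {
    if (length(vars) < 2) break
    r <- abs(stats::cor(covariate_table[vars]))
    diag(r) <- 0
    if (max(r) <= threshold) break
    offending <- unique(rownames(which(r > threshold, arr.ind = TRUE)))
    sc <- scores[offending]
    cand <- offending[sc == min(sc)]
    drop <- max(cand)                       # lowest score; later name on tie
    vars <- setdiff(vars, drop)
  }
  vars
}

#' Read a long-form habitat plot CSV
#'
#' Columns: `station,subplot,tree_species,dbh_cm,height_m` (one row per large
#' stem).
#' @param path file path.
#' @return data.frame.
#' @export
read_plot_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
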