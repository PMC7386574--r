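## Replicate-averaged simulation, synthetic observations, the simulator-backed
## pattern cost, trait calibration, and the pattern-subset sensitivity
## experiment.

#' Replicate-averaged simulation
#'
#' Runs `n` independent simulations (seeds derived from the master seed),
#' averages the census values element-wise across replicates before any
#' annual aggregation, and reports the per-census standard deviation across
#' replicates as the spread.
#'
#' @param n number of replicates (>= 1).
#' @param traits,climate,mowing,census_dates,config passed to
#'   [run_simulation()].
#' @param seed master seed; replicate seeds are drawn from it.
#' @return A list with `census` (replicate-mean census data frame), `spread`
#'   (same shape, standard deviations), `n` and `replicate_seeds`.
#' @export
run_replicates <- function(n, traits, climate, mowing = NULL,
                           census_dates = NULL, config = sim_config(),
                           seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n)
  num_cols <- c("agb_g_m2", "cover_pct", "lai", "height_cm")
  runs <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- run_simulation(traits, climate, mowing, census_dates, config,
                          seed = rep_seeds[i])
    runs[[i]] <- sim$census
  }
  mean_cen <- runs[[1]]
  spread <- runs[[1]]
  stack <- function(col) sapply(runs, function(r) r[[col]])
  for (col in num_cols) {
    m <- stack(col)
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    mean_cen[[col]] <- rowMeans(m)
    spread[[col]] <- apply(m, 1, sd)
  }
  list(census = mean_cen, spread = spread, n = n, replicate_seeds = rep_seeds)
}

#' Synthetic observed vegetation patterns from known traits
#'
#' Simulates with the supplied ("true") traits, averages over replicates,
#' aggregates to annual patterns, and multiplies every annual value by
#' lognormal noise of the stated coefficient of variation (mean 1). With
#' `cv = 0` the observations equal the replicate-mean simulation. The truth
#' is returned alongside for parameter-recovery studies.
#'
#' @param traits,climate,mowing,census_dates,config as in [run_simulation()].
#' @param n_replicates replicates averaged into the underlying truth.
#' @param cv lognormal noise coefficient of variation (>= 0).
#' @param seed master seed.
#' @return A list with `patterns` (annual-aggregate data frame with noisy
#'   `mean`/`min`/`max`), `truth` (noise-free aggregate), `census`
#'   (replicate-mean censuses) and `traits`.
#' @export
generate_synthetic_observations <- function(traits, climate, mowing = NULL,
                                            census_dates = NULL,
                                            config = sim_config(),
                                            n_replicates = 16, cv = 0,
                                            seed = NULL) {
  stopifnot(cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  reps <- run_replicates(n_replicates, traits, climate, mowing, census_dates,
                         config)
  truth <- annual_aggregate(reps$census)
  obs <- truth
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    noise <- rlnorm(nrow(obs), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    obs$mean <- obs$mean * noise
    obs$min <- obs$min * noise
    obs$max <- obs$max * noise
  }
  list(patterns = obs, truth = truth, census = reps$census, traits = traits)
}

#' Simulator-backed cost function over vegetation patterns
#'
#' Builds the closure handed to [optimize_params()]: decode the free
#' parameters into the trait set, run `replicates` simulations, average the
#' censuses, aggregate annually, and score against the observed patterns with
#' [multi_pattern_cost()]. Replicate seeds are drawn from the RNG stream at
#' each call, so a single `set.seed` before the optimization makes the whole
#' calibration reproducible.
#'
#' @param base_traits the `species_traits` providing all fixed parameters.
#' @param bounds a `trait_bounds` over the free subset.
#' @param obs_patterns observed annual patterns (long data frame).
#' @param spec a [cost_spec()].
#' @param climate,mowing,census_dates,config simulation inputs.
#' @param replicates simulator runs averaged per cost evaluation.
#' @return `function(x) -> cost` over the encoded free-parameter vector.
#' @export
make_pattern_cost <- function(base_traits, bounds, obs_patterns, spec,
                              climate, mowing = NULL, census_dates = NULL,
                              config = sim_config(), replicates = 3) {
  force(base_traits); force(bounds); force(obs_patterns); force(spec)
  force(climate); force(mowing); force(census_dates); force(config)
  force(replicates)
  function(x) {
    tr <- decode_free_parameters(x, base_traits, bounds)
    num_cols <- c("agb_g_m2", "cover_pct", "lai", "height_cm")
    acc <- NULL
    for (i in seq_len(replicates)) {
      sim <- run_simulation(tr, climate, mowing, census_dates, config)
      if (is.null(acc)) acc <- sim$census
      else for (col in num_cols) acc[[col]] <- acc[[col]] + sim$census[[col]]
    }
    for (col in num_cols) acc[[col]] <- acc[[col]] / replicates
    multi_pattern_cost(spec, annual_aggregate(acc), obs_patterns)
  }
}

#' Calibrate free traits against observed vegetation patterns
#'
#' The package's inverse parameterization: free traits (named by `bounds`)
#' are searched inside their boxes to minimize the multi-pattern cost between
#' replicate-averaged simulations and the observations.
#'
#' @inheritParams make_pattern_cost
#' @param method,iterations,x0,control,seed passed to [optimize_params()].
#' @return A `calibration_result` with an extra `traits` element (the
#'   best-fit trait set).
#' @export
calibrate_traits <- function(base_traits, bounds, obs_patterns, spec,
                             climate, mowing = NULL, census_dates = NULL,
                             config = sim_config(), replicates = 3,
                             method = "dds", iterations = 500, x0 = NULL,
                             control = list(), seed = NULL) {
  fn <- make_pattern_cost(base_traits, bounds, obs_patterns, spec, climate,
                          mowing, census_dates, config, replicates)
  res <- optimize_params(fn, bounds$lower, bounds$upper, method = method,
                         iterations = iterations, x0 = x0, control = control,
                         seed = seed)
  res$traits <- decode_free_parameters(res$par, base_traits, bounds)
  res
}

#' All subsets of the four monoculture attributes
#'
#' Helper enumerating the 15 non-empty subsets of
#' `c("agb_g_m2", "lai", "height_cm", "cover_pct")` used by the pattern-subset
#' sensitivity experiment (4 singles, 6 pairs, 4 triples, 1 full).
#'
#' @param attributes attribute names.
#' @return A list of character vectors.
#' @export
attribute_subsets <- function(attributes = c("agb_g_m2", "lai", "height_cm",
                                             "cover_pct")) {
  out <- list()
  for (k in seq_along(attributes))
    out <- c(out, utils::combn(attributes, k, simplify = FALSE))
  out
}

#' Pattern-subset sensitivity of the inverse parameterization
#'
#' For each candidate subset of vegetation attributes, calibrates the free
#' traits on that subset only, then evaluates the calibrated model's nrmse on
#' all evaluation attributes (calibrated and excluded alike) using a
#' replicate-averaged simulation. This quantifies how much information each
#' attribute (or combination) carries for a robust parameterization.
#'
#' @inheritParams calibrate_traits
#' @param subsets list of character vectors of attributes (each becomes a
#'   MAPE [cost_spec()] for `subject`).
#' @param subject the subject (species or `"community"`) the patterns belong
#'   to.
#' @param eval_attributes attributes scored after calibration.
#' @param eval_replicates replicates of the final evaluation run.
#' @param metric per-pattern calibration metric.
#' @return A data frame with one row per subset: `subset`, `n_attributes`,
#'   `best_cost`, one `nrmse_*` column per evaluation attribute and
#'   `mean_nrmse`.
#' @export
pattern_subset_experiment <- function(base_traits, bounds, obs_patterns,
                                      subsets, subject,
                                      climate, mowing = NULL,
                                      census_dates = NULL,
                                      config = sim_config(),
                                      eval_attributes = c("agb_g_m2", "lai",
                                                          "height_cm",
                                                          "cover_pct"),
                                      replicates = 3, eval_replicates = 8,
                                      method = "dds", iterations = 200,
                                      metric = "mape", seed = NULL) {
  stopifnot(length(subsets) >= 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", length(subsets))
  for (si in seq_along(subsets)) {
    spec <- cost_spec(subsets[[si]], subject = subject, metric = metric)
    fit <- calibrate_traits(base_traits, bounds, obs_patterns, spec, climate,
                            mowing, census_dates, config, replicates,
                            method = method, iterations = iterations)
    ev <- run_replicates(eval_replicates, fit$traits, climate, mowing,
                         census_dates, config)
    agg <- annual_aggregate(ev$census)
    scores <- vapply(eval_attributes, function(attr) {
      sim <- pattern_values(agg, subject, attr, "annual")
      obs <- pattern_values(obs_patterns, subject, attr, "annual")
      n <- min(length(sim), length(obs))
      nrmse(sim[seq_len(n)], obs[seq_len(n)])
    }, numeric(1))
    row <- data.frame(subset = paste(subsets[[si]], collapse = "+"),
                      n_attributes = length(subsets[[si]]),
                      best_cost = fit$value, stringsAsFactors = FALSE)
    for (attr in eval_attributes) row[[paste0("nrmse_", attr)]] <- scores[[attr]]
    row$mean_nrmse <- mean(scores)
    rows[[si]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
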