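## Agreement metrics between simulated and observed annual series, the
## multi-pattern cost used for inverse parameterization, and the
## evaluation-layer helpers (OLS regression, normalization, relative yields).

#' Mean absolute percentage error
#'
#' `(1/N) * sum(|sim - obs| / |obs|)`, dimensionless. Scale-invariant; zero
#' iff the series agree.
#'
#' @param sim,obs equal-length numeric series; `obs` must be non-zero
#'   everywhere.
#' @return The MAPE (a plain number, not percent).
#' @export
mape <- function(sim, obs) {
  stopifnot(length(sim) == length(obs), length(obs) >= 1)
  if (any(obs == 0))
    stop("undefined MAPE: zero observation at position ",
         which(obs == 0)[1])
  mean(abs(sim - obs) / abs(obs))
}

#' Normalized root mean square error
#'
#' RMSE between the series, normalized by the observed mean, in percent:
#' `100 * sqrt(mean((sim - obs)^2)) / mean(obs)`. Values above 100% occur for
#' poor fits.
#'
#' @param sim,obs equal-length numeric series; `mean(obs)` must be non-zero.
#' @return The nrmse in percent.
#' @export
nrmse <- function(sim, obs) {
  stopifnot(length(sim) == length(obs), length(obs) >= 1)
  if (mean(obs) == 0) stop("undefined nrmse: zero-mean observations")
  100 * sqrt(mean((sim - obs)^2)) / mean(obs)
}

#' Cost specification over a set of vegetation patterns
#'
#' Selects which patterns enter the combined cost, the per-pattern metric and
#' the weights. Patterns are matched between simulation and observation by
#' `(subject, attribute)`.
#'
#' @param patterns a data frame with columns `subject` and `attribute` (one
#'   row per selected pattern), or a character vector of attributes combined
#'   with a single `subject`.
#' @param subject used when `patterns` is a character vector.
#' @param metric `"mape"`, `"nrmse"` or `"combined"`. The combined criterion
#'   is `nrmse + 100*|1 - slope| + 100*(1 - R^2)` from the regression of
#'   simulated on observed values.
#' @param weights per-pattern positive weights (default 1).
#' @param granularity `"annual"` compares annual means, `"census"` compares
#'   the raw (typically biannual) census values via min/max pairs.
#' @return An object of class `cost_spec`.
#' @export
cost_spec <- function(patterns, subject = NULL,
                      metric = c("mape", "nrmse", "combined"),
                      weights = NULL, granularity = c("annual", "census")) {
  metric <- match.arg(metric)
  granularity <- match.arg(granularity)
  if (is.character(patterns)) {
    stopifnot(!is.null(subject))
    patterns <- data.frame(subject = subject, attribute = patterns,
                           stringsAsFactors = FALSE)
  }
  stopifnot(nrow(patterns) >= 1)
  if (is.null(weights)) weights <- rep(1, nrow(patterns))
  if (any(weights <= 0)) stop("pattern weights must be positive")
  stopifnot(length(weights) == nrow(patterns))
  structure(list(patterns = patterns, metric = metric, weights = weights,
                 granularity = granularity), class = "cost_spec")
}

pattern_values <- function(df, subject, attribute, granularity) {
  sel <- df$subject == subject & df$attribute == attribute
  if (!any(sel)) return(NULL)
  d <- df[sel, ]
  d <- d[order(d$year), ]
  if (granularity == "census") c(rbind(d$min, d$max)) else d$mean
}

#' Combined cost over selected vegetation patterns
#'
#' Weighted sum of the per-pattern metric between simulated and observed
#' annual series. A single-pattern spec reduces to that pattern's metric.
#'
#' @param spec a [cost_spec()].
#' @param sim_patterns,obs_patterns long pattern data frames with columns
#'   `subject`, `attribute`, `year`, `mean` (and `min`/`max` for census
#'   granularity), e.g. from [annual_aggregate()] or [build_pattern_set()].
#' @return The scalar cost.
#' @export
multi_pattern_cost <- function(spec, sim_patterns, obs_patterns) {
  stopifnot(inherits(spec, "cost_spec"))
  total <- 0
  for (i in seq_len(nrow(spec$patterns))) {
    sub <- spec$patterns$subject[i]
    attr <- spec$patterns$attribute[i]
    sim <- pattern_values(sim_patterns, sub, attr, spec$granularity)
    obs <- pattern_values(obs_patterns, sub, attr, spec$granularity)
    if (is.null(sim) || is.null(obs))
      stop("missing pattern: ", sub, "/", attr)
    n <- min(length(sim), length(obs))
    sim <- sim[seq_len(n)]; obs <- obs[seq_len(n)]
    val <- switch(spec$metric,
      mape = mape(sim, obs),
      nrmse = nrmse(sim, obs),
      combined = {
        r <- regression_eval(sim, obs)
        r$nrmse + 100 * abs(1 - r$slope) + 100 * (1 - r$r_squared)
      })
    total <- total + spec$weights[i] * val
  }
  total
}

#' Ordinary least squares evaluation of simulated against observed values
#'
#' Fits `sim = intercept + slope * obs` by OLS and reports slope, intercept,
#' the coefficient of determination R^2 (squared Pearson correlation for
#' simple OLS) and the nrmse between the raw series.
#'
#' @param sim,obs equal-length series, `N >= 2`, `obs` not constant.
#' @return A list of class `evaluation_result`: `slope`, `intercept`,
#'   `r_squared`, `nrmse`, `n`.
#' @export
regression_eval <- function(sim, obs) {
  stopifnot(length(sim) == length(obs), length(obs) >= 2)
  if (sd(obs) == 0) stop("degenerate regression: constant observations")
  fit <- lm(sim ~ obs)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((sim - mean(sim))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, nrmse = nrmse(sim, obs),
                 n = length(obs)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("slope %.3f, intercept %.3f, R^2 %.3f, nrmse %.1f%% (N = %d)\n",
              x$slope, x$intercept, x$r_squared, x$nrmse, x$n))
  invisible(x)
}

#' Normalize patterns by their joint observed/simulated maximum
#'
#' Per pattern (attribute), both the simulated and observed series are divided
#' by the maximum over both and over all subjects, so the joint maximum maps
#' to 1 and rank order is preserved.
#'
#' @param df a long data frame with columns `attribute`, `sim` and `obs`.
#' @return The data frame with `sim` and `obs` rescaled, plus a `divisor`
#'   column.
#' @export
normalize_by_max <- function(df) {
  stopifnot(all(c("attribute", "sim", "obs") %in% names(df)))
  out <- df
  out$divisor <- NA_real_
  for (attr in unique(df$attribute)) {
    sel <- df$attribute == attr
    mx <- max(df$sim[sel], df$obs[sel])
    if (mx <= 0) stop("all-zero pattern: ", attr)
    out$sim[sel] <- df$sim[sel] / mx
    out$obs[sel] <- df$obs[sel] / mx
    out$divisor[sel] <- mx
  }
  out
}

#' Relative yield of a species in mixture
#'
#' The ratio of an attribute's value in the mixture to its value in the
#' species' monoculture, per year. A value of 1 means the species performs in
#' mixture as in monoculture; 0.5 is the equal-partition expectation in a
#' two-species mixture.
#'
#' @param mixture,monoculture annual-aggregate data frames
#'   ([annual_aggregate()]) holding the same subject and attribute.
#' @param subject species name.
#' @param attribute census attribute name.
#' @return A data frame `subject`, `attribute`, `year`, `relative_yield`.
#' @export
relative_yield <- function(mixture, monoculture, subject, attribute) {
  mx <- pattern_values(mixture, subject, attribute, "annual")
  mo <- pattern_values(monoculture, subject, attribute, "annual")
  if (is.null(mx) || is.null(mo)) stop("missing pattern: ", subject, "/", attribute)
  yrs_mx <- sort(unique(mixture$year[mixture$subject == subject &
                                     mixture$attribute == attribute]))
  yrs_mo <- sort(unique(monoculture$year[monoculture$subject == subject &
                                         monoculture$attribute == attribute]))
  yrs <- intersect(yrs_mx, yrs_mo)
  if (!length(yrs)) stop("no aligned years")
  mx <- mx[match(yrs, yrs_mx)]; mo <- mo[match(yrs, yrs_mo)]
  if (any(mo <= 0)) stop("zero monoculture value in relative yield")
  data.frame(subject = subject, attribute = attribute, year = yrs,
             relative_yield = mx / mo, stringsAsFactors = FALSE)
}
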