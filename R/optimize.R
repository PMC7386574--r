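## Bounded derivative-free optimizers for the inverse parameterization:
## dynamically dimensioned search (DDS), differential evolution (rand/1/bin)
## and simulated annealing with geometric cooling. All three respect box
## bounds, treat non-finite costs as +Inf, and are reproducible under a fixed
## seed.

reflect_bounds <- function(x, lower, upper) {
  # reflect once at each bound; fall back to the bound if still outside
  below <- x < lower
  x[below] <- 2 * lower[below] - x[below]
  above <- x > upper
  x[above] <- 2 * upper[above] - x[above]
  x <- pmin(pmax(x, lower), upper)
  x
}

safe_cost <- function(fn, x) {
  v <- tryCatch(fn(x), error = function(e) Inf)
  if (!is.finite(v)) Inf else v
}

#' Bounded derivative-free optimization
#'
#' Minimizes `fn` over the box `[lower, upper]`.
#'
#' * `"dds"` — dynamically dimensioned search: at iteration `t` of `T`, each
#'   dimension joins the perturbation set with probability `1 - ln(t)/ln(T)`
#'   (at least one is always perturbed); selected components get a Gaussian
#'   step of standard deviation 0.2 (control `r`) times the range, reflected at
#'   the bounds; acceptance is greedy. The search thus narrows from global to
#'   local as the budget is spent.
#' * `"de"` — differential evolution, rand/1/bin, `F = 0.8`, `CR = 0.9`,
#'   population `10 * D` (capped by the budget), candidates clamped to bounds.
#' * `"sa"` — simulated annealing: single-dimension Gaussian proposals
#'   (sd `0.2` range, reflected), Metropolis acceptance under geometric
#'   cooling from the initial cost scale down three decades.
#'
#' @param fn cost function of a numeric vector; non-finite values are treated
#'   as +Inf.
#' @param lower,upper bound vectors (equal length, `lower < upper`).
#' @param method `"dds"`, `"de"` or `"sa"`.
#' @param iterations evaluation budget `T` (candidates beyond the initial
#'   point).
#' @param x0 optional start; default a uniform draw inside the bounds.
#' @param control list of method knobs: `r` (DDS/SA step scale), `F`, `CR`,
#'   `NP` (DE), `t0_scale`, `t_decades` (SA).
#' @param seed optional integer seed.
#' @return An object of class `calibration_result`: `par` (best vector),
#'   `value` (best cost), `trace` (best-so-far cost after each accepted
#'   candidate evaluation), `evaluations`, `method`, `seed`.
#' @export
optimize_params <- function(fn, lower, upper,
                            method = c("dds", "de", "sa"),
                            iterations = 1000, x0 = NULL, control = list(),
                            seed = NULL) {
  method <- match.arg(method)
  stopifnot(length(lower) == length(upper), all(lower < upper),
            iterations >= 1)
  if (!is.null(seed)) set.seed(seed)
  D <- length(lower)
  rng <- upper - lower
  if (is.null(x0)) x0 <- lower + runif(D) * rng
  stopifnot(length(x0) == D, all(x0 >= lower), all(x0 <= upper))

  ctl <- modifyList(list(r = 0.2, F = 0.8, CR = 0.9,
                         NP = min(10 * D, max(4, iterations %/% 2)),
                         t0_scale = 1, t_decades = 3), control)
  evals <- 0L
  best_x <- x0
  best_f <- safe_cost(fn, x0); evals <- evals + 1L
  trace <- best_f

  if (method == "dds") {
    logT <- log(max(iterations, 2))
    for (t in seq_len(iterations)) {
      p <- 1 - log(t) / logT
      sel <- which(runif(D) < p)
      if (!length(sel)) sel <- sample.int(D, 1)
      cand <- best_x
      cand[sel] <- cand[sel] + ctl$r * rng[sel] * rnorm(length(sel))
      cand <- reflect_bounds(cand, lower, upper)
      f <- safe_cost(fn, cand); evals <- evals + 1L
      if (f <= best_f) { best_f <- f; best_x <- cand }
      trace <- c(trace, best_f)
    }
  } else if (method == "de") {
    NP <- max(4L, as.integer(ctl$NP))
    pop <- matrix(lower + runif(NP * D) * rep(rng, each = NP),
                  nrow = NP, byrow = FALSE)
    pop[1, ] <- x0
    fit <- apply(pop, 1, function(x) safe_cost(fn, x))
    evals <- evals + NP - 1L   # x0 already evaluated
    gens <- max(1L, as.integer((iterations - NP + 1) / NP))
    i_best <- which.min(fit)
    if (fit[i_best] <= best_f) { best_f <- fit[i_best]; best_x <- pop[i_best, ] }
    trace <- c(trace, rep(best_f, NP - 1L))
    for (g in seq_len(gens)) {
      for (i in seq_len(NP)) {
        idx <- sample(setdiff(seq_len(NP), i), 3)
        donor <- pop[idx[1], ] + ctl$F * (pop[idx[2], ] - pop[idx[3], ])
        cross <- runif(D) < ctl$CR
        cross[sample.int(D, 1)] <- TRUE
        cand <- ifelse(cross, donor, pop[i, ])
        cand <- pmin(pmax(cand, lower), upper)
        f <- safe_cost(fn, cand); evals <- evals + 1L
        if (f <= fit[i]) { fit[i] <- f; pop[i, ] <- cand }
        if (f <= best_f) { best_f <- f; best_x <- cand }
        trace <- c(trace, best_f)
      }
    }
  } else {  # sa
    cur_x <- best_x; cur_f <- best_f
    t0 <- ctl$t0_scale * max(abs(best_f), 1e-8)
    ratio <- (10^(-ctl$t_decades))^(1 / iterations)
    temp <- t0
    for (t in seq_len(iterations)) {
      j <- sample.int(D, 1)
      cand <- cur_x
      cand[j] <- cand[j] + ctl$r * rng[j] * rnorm(1)
      cand <- reflect_bounds(cand, lower, upper)
      f <- safe_cost(fn, cand); evals <- evals + 1L
      if (f <= cur_f || runif(1) < exp(-(f - cur_f) / temp)) {
        cur_f <- f; cur_x <- cand
      }
      if (f <= best_f) { best_f <- f; best_x <- cand }
      trace <- c(trace, best_f)
      temp <- temp * ratio
    }
  }

  structure(list(par = setNames(best_x, names(lower)), value = best_f,
                 trace = trace, evaluations = evals, method = method,
                 seed = seed),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> ", x$method, ", ", x$evaluations,
      " evaluations, best cost ", format(x$value, digits = 6), "\n", sep = "")
  if (!is.null(names(x$par)))
    for (nm in names(x$par))
      cat("  ", nm, " = ", format(x$par[[nm]], digits = 6), "\n", sep = "")
  invisible(x)
}
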