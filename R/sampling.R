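# Parameter sampling for the probabilistic sensitivity analysis.
# Distribution assignments: Beta(alpha, beta) for probabilities, lognormal
# for risk ratios (median at the point estimate, log-sd from the 95% CI),
# normal truncated at zero for event costs, and Beta-PERT for the barrier
# sheet count. Parameters are sampled independently.

#' Draw from a probability's Beta distribution
#'
#' One or more draws from Beta(alpha, beta). Infinite pseudo-counts denote a
#' fixed probability and return the point estimate exactly.
#'
#' @param p A [probability_param].
#' @param n Number of draws.
#' @return Numeric vector of length `n` in \[0, 1\].
#' @export
sample_probability <- function(p, n = 1) {
  stop_unless(inherits(p, "probability_param"),
              "sample_probability: 'p' must be a probability_param")
  if (is.infinite(p$alpha)) return(rep(p$point, n))
  stop_unless(p$alpha > 0 && p$beta > 0,
              "sample_probability: degenerate Beta (alpha or beta is 0)")
  stats::rbeta(n, p$alpha, p$beta)
}

# log-scale sd implied by a symmetric-on-log 95% CI
.rr_sigma <- function(rr) (log(rr$ci_high) - log(rr$ci_low)) / (2 * stats::qnorm(0.975))

#' Draw from a risk ratio's lognormal distribution
#'
#' Lognormal with median at the point estimate and
#' `sigma = (log(ci_high) - log(ci_low)) / (2 * 1.96)`, i.e. the 95% CI is
#' taken as symmetric on the log scale. A degenerate CI
#' (`ci_low == ci_high == point`) yields the point estimate with probability
#' one.
#'
#' @param rr A [relative_risk].
#' @param n Number of draws.
#' @return Numeric vector of length `n`, all positive.
#' @export
sample_rr <- function(rr, n = 1) {
  stop_unless(inherits(rr, "relative_risk"),
              "sample_rr: 'rr' must be a relative_risk")
  stats::rlnorm(n, log(rr$point), .rr_sigma(rr))
}

#' Draw from a cost's normal distribution, truncated at zero
#'
#' Normal(mean, sd) with negative draws rejected and redrawn, so all
#' returned costs are nonnegative. `sd = 0` returns the mean.
#'
#' @param cost A [cost_param].
#' @param n Number of draws.
#' @return Numeric vector of length `n` in USD, all >= 0.
#' @export
sample_cost <- function(cost, n = 1) {
  stop_unless(inherits(cost, "cost_param"),
              "sample_cost: 'cost' must be a cost_param")
  x <- stats::rnorm(n, cost$mean, cost$sd)
  while (any(bad <- x < 0)) x[bad] <- stats::rnorm(sum(bad), cost$mean, cost$sd)
  x
}

#' Draw a barrier cost from the Beta-PERT sheet count
#'
#' Sheets are drawn from Beta-PERT(minimum, mode, maximum) — a Beta with
#' `shape1 = 1 + 4 (mode - minimum) / (maximum - minimum)` and
#' `shape2 = 1 + 4 (maximum - mode) / (maximum - minimum)`, rescaled to
#' \[minimum, maximum\] — and multiplied by the unit price. A zero-width
#' range gives a constant cost.
#'
#' @param pert A [pert_param].
#' @param n Number of draws.
#' @return Numeric vector of length `n`: barrier cost in USD, bounded by
#'   `minimum * unit_price` and `maximum * unit_price`.
#' @export
sample_barrier_cost <- function(pert, n = 1) {
  stop_unless(inherits(pert, "pert_param"),
              "sample_barrier_cost: 'pert' must be a pert_param")
  width <- pert$maximum - pert$minimum
  if (width == 0) return(rep(pert$minimum * pert$unit_price, n))
  shape1 <- 1 + 4 * (pert$mode - pert$minimum) / width
  shape2 <- 1 + 4 * (pert$maximum - pert$mode) / width
  sheets <- pert$minimum + width * stats::rbeta(n, shape1, shape2)
  sheets * pert$unit_price
}

#' Draw one coherent sampled parameter set
#'
#' Draws every stochastic parameter once from its assigned distribution,
#' using the current RNG state (wrap in [withr::with_seed()] or call
#' `set.seed()` for reproducibility). Within each cohort the sampled
#' no-barrier surgical-ASBO probability is clamped to be no larger than the
#' sampled ASBO probability, and the sampled repeat-surgery probability is
#' the sampled raw rate minus the sampled no-barrier surgical-ASBO
#' probability, floored at zero.
#'
#' @param params A `cea_parameters` object.
#' @return An object of class `sampled_parameters`: a list with `open` and
#'   `lap` elements, each a named list of the 12 plain numeric values
#'   (four probabilities with `p_repeat` precomputed, three risk ratios,
#'   four event costs, `barrier_cost`). The barrier cost draw is shared
#'   between cohorts.
#' @export
draw_parameter_set <- function(params) {
  validate_parameters(params)
  rrs <- lapply(params[.rr_fields], sample_rr)
  costs <- lapply(params[.cost_fields], sample_cost)
  barrier_cost <- sample_barrier_cost(params$barrier_sheets)
  one_cohort <- function(ch) {
    p_adh <- sample_probability(ch$p_adhesions)
    p_asbo <- sample_probability(ch$p_asbo)
    p_surg <- min(sample_probability(ch$p_asbo_surgical), p_asbo)
    p_rep_raw <- sample_probability(ch$p_repeat_raw)
    c(list(p_adhesions = p_adh, p_asbo = p_asbo, p_asbo_surgical = p_surg,
           p_repeat_raw = p_rep_raw,
           p_repeat = max(p_rep_raw - p_surg, 0)),
      rrs, costs, list(barrier_cost = barrier_cost))
  }
  structure(list(open = one_cohort(params$open_cohort),
                 lap = one_cohort(params$lap_cohort)),
            class = "sampled_parameters")
}

# Vectorised sampler: n draws of the 12 value columns for one cohort, in a
# fixed documented order (probabilities, raw repeat rate, risk ratios,
# costs, sheet count). Deterministic given the RNG state; used by run_psa()
# and threshold_ci().
.sample_values <- function(params, cohort, n) {
  ch <- params[[paste0(cohort, "_cohort")]]
  v <- list(
    p_adhesions = sample_probability(ch$p_adhesions, n),
    p_asbo = sample_probability(ch$p_asbo, n),
    p_asbo_surgical = sample_probability(ch$p_asbo_surgical, n),
    p_repeat_raw = sample_probability(ch$p_repeat_raw, n),
    rr_adhesions = sample_rr(params$rr_adhesions, n),
    rr_asbo = sample_rr(params$rr_asbo, n),
    rr_asbo_surgical = sample_rr(params$rr_asbo_surgical, n),
    cost_asbo_operative = sample_cost(params$cost_asbo_operative, n),
    cost_asbo_conservative = sample_cost(params$cost_asbo_conservative, n),
    cost_repeat_no_adhesions = sample_cost(params$cost_repeat_no_adhesions, n),
    cost_repeat_adhesions = sample_cost(params$cost_repeat_adhesions, n),
    barrier_cost = sample_barrier_cost(params$barrier_sheets, n))
  v$p_asbo_surgical <- pmin(v$p_asbo_surgical, v$p_asbo)
  v
}
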