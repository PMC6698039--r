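# Deterministic sensitivity analyses: one-way tornado over every model
# parameter at its 95% interval bounds, and the best-/worst-case risk-ratio
# scenarios.

# 95% interval per parameter class: risk ratios use their reported CIs;
# probabilities the 2.5th/97.5th Beta percentiles; event costs
# mean +/- 1.96 sd floored at 0; the barrier cost the PERT range endpoints.
.param_bounds <- function(params, cohort) {
  ch <- params[[paste0(cohort, "_cohort")]]
  beta_ci <- function(p) {
    if (is.infinite(p$alpha)) return(c(p$point, p$point))
    stats::qbeta(c(0.025, 0.975), p$alpha, p$beta)
  }
  cost_ci <- function(cc) {
    c(max(0, cc$mean - stats::qnorm(0.975) * cc$sd),
      cc$mean + stats::qnorm(0.975) * cc$sd)
  }
  bounds <- list()
  for (nm in .rr_fields)
    bounds[[nm]] <- c(params[[nm]]$ci_low, params[[nm]]$ci_high)
  for (nm in .cohort_fields)
    bounds[[nm]] <- beta_ci(ch[[nm]])
  for (nm in .cost_fields)
    bounds[[nm]] <- cost_ci(params[[nm]])
  bounds$barrier_cost <- c(params$barrier_sheets$minimum,
                           params$barrier_sheets$maximum) *
    params$barrier_sheets$unit_price
  bounds
}

#' One-way (tornado) deterministic sensitivity analysis
#'
#' Each of the twelve model parameters (three risk ratios, four cohort
#' probabilities, four event costs, barrier cost) is set in turn to the
#' lower and upper bound of its 95% interval, holding every other parameter
#' at its base-case value, and the incremental cost (barrier minus no
#' barrier) is re-evaluated. Bounds per class: risk ratios use their
#' reported 95% CIs; probabilities the 2.5th/97.5th percentiles of their
#' Beta distribution; event costs mean +/- 1.96 SD (floored at 0); the
#' barrier cost the PERT range endpoints.
#'
#' @param params A `cea_parameters` object.
#' @param cohort `"open"` or `"lap"`.
#' @param use Point convention for the held-fixed values, see
#'   [arm_probabilities()].
#' @return A tibble with one row per parameter, sorted by `swing`
#'   (absolute difference of the incremental cost across the two bounds)
#'   in decreasing order: columns `parameter`, `low_input`, `high_input`,
#'   `outcome_at_low`, `outcome_at_high`, `swing`, plus the unranked
#'   incremental-effect columns `effect_at_low`, `effect_at_high`.
#' @export
#' @examples
#' tor <- one_way_tornado(default_parameters(), "open")
#' head(tor[, c("parameter", "swing")])
one_way_tornado <- function(params, cohort = c("open", "lap"),
                            use = c("mean", "point")) {
  cohort <- match.arg(cohort)
  use <- match.arg(use)
  validate_parameters(params)
  base <- .fixed_values(params, cohort, use)
  bounds <- .param_bounds(params, cohort)
  eval_at <- function(nm, value) {
    v <- base
    v[[nm]] <- value
    .evaluate_values(v)
  }
  rows <- lapply(names(bounds), function(nm) {
    lo <- eval_at(nm, bounds[[nm]][1])
    hi <- eval_at(nm, bounds[[nm]][2])
    tibble::tibble(parameter = nm,
                   low_input = bounds[[nm]][1], high_input = bounds[[nm]][2],
                   outcome_at_low = lo$delta_cost,
                   outcome_at_high = hi$delta_cost,
                   swing = abs(hi$delta_cost - lo$delta_cost),
                   effect_at_low = lo$delta_effect,
                   effect_at_high = hi$delta_effect)
  })
  out <- do.call(rbind, rows)
  out[order(-out$swing), ]
}

#' Best-/worst-case scenario evaluation
#'
#' Re-evaluates the two strategies with all three risk ratios set jointly to
#' one end of their 95% CIs: `"worst"` uses the upper limits (0.61, 1.32,
#' 0.88 with the default parameters), `"best"` the lower limits (0.43, 0.35,
#' 0.28). All other inputs stay at base case; `"baseline"` reproduces
#' [base_case()] exactly.
#'
#' @param params A `cea_parameters` object.
#' @param cohort `"open"` or `"lap"`.
#' @param which `"best"`, `"worst"`, or `"baseline"`.
#' @param use Point convention, see [arm_probabilities()].
#' @return An object of class `scenario_result`: a [base_case()]-shaped list
#'   with an extra `scenario` label.
#' @export
scenario <- function(params, cohort = c("open", "lap"),
                     which = c("best", "worst", "baseline"),
                     use = c("mean", "point")) {
  cohort <- match.arg(cohort)
  which <- match.arg(which)
  use <- match.arg(use)
  validate_parameters(params)
  if (which != "baseline") {
    pick <- if (which == "worst") "ci_high" else "ci_low"
    for (nm in .rr_fields) {
      b <- params[[nm]][[pick]]
      params[[nm]] <- relative_risk(b, min(params[[nm]]$ci_low, b),
                                    max(params[[nm]]$ci_high, b))
    }
  }
  out <- base_case(params, cohort, use = use)
  out$scenario <- which
  class(out) <- c("scenario_result", class(out))
  out
}

#' Write a tornado table as CSV
#'
#' Column layout
#' `parameter,low_input,high_input,outcome_at_low,outcome_at_high,swing`
#' (plus the effect columns), sorted by swing descending.
#'
#' @param tornado A [one_way_tornado()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tornado <- function(tornado, path) {
  utils::write.csv(tornado, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
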