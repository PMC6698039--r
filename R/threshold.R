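# Break-even (threshold) analyses. The expected incremental cost is affine
# both in the barrier price (slope +1) and in the shared repeat-surgery
# probability, so both thresholds have closed forms; a bisection solver is
# kept in the test suite as an independent oracle.

# Coerce params / sampled_parameters to a plain value list for `cohort`.
.values_for <- function(params, cohort, use = "mean") {
  if (inherits(params, "sampled_parameters")) return(params[[cohort]])
  if (inherits(params, "cea_parameters"))
    return(.fixed_values(params, cohort, use))
  stop_unless(is.list(params) && all(c("p_adhesions", "barrier_cost") %in%
                                       names(params)),
              "expected a cea_parameters, sampled_parameters, or value list")
  params
}

#' Break-even barrier price
#'
#' The barrier price at which the two strategies' expected costs are equal.
#' The incremental cost rises one-for-one with the price, so the threshold
#' is the current price plus the current saving,
#' `barrier_cost - delta_cost`, floored at zero. At any higher price the
#' barrier strategy no longer reduces costs.
#'
#' @param params A `cea_parameters` object, a [draw_parameter_set()] result,
#'   or a plain value list (as in the PSA draw columns).
#' @param cohort `"open"` or `"lap"`.
#' @param use Point convention when `params` is a `cea_parameters`.
#' @return Threshold price in USD.
#' @export
#' @examples
#' barrier_price_threshold(default_parameters(), "open")  # ~ $737
barrier_price_threshold <- function(params, cohort = c("open", "lap"),
                                    use = c("mean", "point")) {
  cohort <- match.arg(cohort)
  use <- match.arg(use)
  v <- .values_for(params, cohort, use)
  out <- .evaluate_values(v)
  max(v$barrier_cost - out$delta_cost, 0)
}

# Decompose delta_cost(r) = A + r * B in the shared repeat probability r:
# B is the per-unit repeat-surgery cost difference between arms (driven by
# the adhesion-probability reduction), A the price-plus-ASBO-pathway part.
.reop_affine <- function(v) {
  out <- .evaluate_values(v)
  B <- (out$p_adh_barrier - out$p_adh_no_barrier) *
    (v$cost_repeat_adhesions - v$cost_repeat_no_adhesions)
  A <- out$delta_cost - out$p_repeat * B
  list(A = A, B = B)
}

#' Break-even repeat-surgery probability
#'
#' The repeat-surgery probability (applied jointly to both arms, after
#' subtraction of ASBO re-operations) at which the incremental cost is
#' zero: below it the barrier strategy no longer reduces costs. Solved in
#' closed form from the affinity of the incremental cost in the repeat
#' probability, and clamped to \[0, 1\].
#'
#' The returned value is the largest repeat-surgery rate in \[0, 1\] at
#' which the barrier strategy does not reduce costs: 0 when the barrier
#' saves at every rate, 1 when it saves at none (e.g. when a sampled
#' parameter set reverses the repeat-surgery cost ordering so that the
#' incremental cost never crosses zero). When the incremental cost does not
#' decrease with the repeat rate (affine slope >= 0) the result carries
#' `attr(, "no_crossing") = TRUE`.
#'
#' @inheritParams barrier_price_threshold
#' @return Threshold probability in \[0, 1\].
#' @export
#' @examples
#' reoperation_rate_threshold(default_parameters(), "open")  # ~ 0.154
reoperation_rate_threshold <- function(params, cohort = c("open", "lap"),
                                       use = c("mean", "point")) {
  cohort <- match.arg(cohort)
  use <- match.arg(use)
  v <- .values_for(params, cohort, use)
  ab <- .reop_affine(v)
  r <- .reop_solve(ab$A, ab$B)
  if (ab$B >= 0) attr(r, "no_crossing") <- TRUE
  r
}

# Largest r in [0, 1] with A + r B > 0 treated as "not saving"; returns the
# zero crossing when it lies inside the unit interval, otherwise the
# boundary on the non-saving side (vectorised).
.reop_solve <- function(A, B) {
  always_saves <- A <= 0 & A + B <= 0
  never_saves <- A >= 0 & A + B >= 0
  crossing <- ifelse(B != 0, -A / B, 0)
  ifelse(always_saves, 0, ifelse(never_saves, 1, pmin(pmax(crossing, 0), 1)))
}

#' Threshold with a PSA percentile confidence interval
#'
#' Recomputes the chosen threshold on every draw of the Monte Carlo
#' parameter stream (same sampler and seed contract as [run_psa()]) and
#' summarizes the per-draw thresholds with a 95% percentile interval. The
#' point estimate is the base-case threshold on the unsampled parameters.
#'
#' @param params A `cea_parameters` object.
#' @param cohort `"open"` or `"lap"`.
#' @param kind `"barrier_price"` or `"reoperation_rate"`.
#' @param n_samples Number of Monte Carlo draws (>= 100; default 5000).
#' @param seed Integer RNG seed (default 20190816).
#' @param use Point convention for the base-case point estimate.
#' @return An object of class `threshold_result`: list with `kind`,
#'   `cohort`, `point`, `ci_low`, `ci_high`, `n_samples`, `seed`.
#' @export
threshold_ci <- function(params, cohort = c("open", "lap"),
                         kind = c("barrier_price", "reoperation_rate"),
                         n_samples = 5000, seed = 20190816,
                         use = c("mean", "point")) {
  cohort <- match.arg(cohort)
  kind <- match.arg(kind)
  use <- match.arg(use)
  stop_unless(is_number(n_samples) && n_samples >= 100,
              "threshold_ci: 'n_samples' must be >= 100")
  validate_parameters(params)
  v <- withr::with_seed(seed, .sample_values(params, cohort, n_samples))
  if (kind == "barrier_price") {
    out <- .evaluate_values(v)
    per_draw <- pmax(v$barrier_cost - out$delta_cost, 0)
    point <- barrier_price_threshold(params, cohort, use)
  } else {
    ab <- .reop_affine(v)
    per_draw <- .reop_solve(ab$A, ab$B)
    point <- as.numeric(reoperation_rate_threshold(params, cohort, use))
  }
  ci <- percentile_ci(per_draw, 0.95)
  structure(list(kind = kind, cohort = cohort, point = point,
                 ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
                 n_samples = as.integer(n_samples), seed = seed),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  fmt <- if (x$kind == "barrier_price") {
    function(v) sprintf("$%.0f", v)
  } else {
    function(v) sprintf("%.1f%%", 100 * v)
  }
  lbl <- if (x$kind == "barrier_price") "break-even barrier price"
         else "break-even repeat-surgery rate"
  cat(sprintf("%s cohort %s: %s (95%% CI %s-%s; %d draws, seed %d)\n",
              x$cohort, lbl, fmt(x$point), fmt(x$ci_low), fmt(x$ci_high),
              x$n_samples, as.integer(x$seed)))
  invisible(x)
}
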