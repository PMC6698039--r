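# Probabilistic sensitivity analysis: Monte Carlo over the parameter
# distributions, percentile confidence intervals, probability of cost
# saving, and cost-effectiveness-plane export.

#' Run the Monte Carlo probabilistic sensitivity analysis
#'
#' Draws `n_samples` coherent parameter sets (see [draw_parameter_set()] for
#' the distribution assignments and clamping rules) and evaluates both
#' strategies on each draw. The whole stream is a pure function of `seed`:
#' two runs with the same arguments are identical, and the caller's RNG
#' state is left untouched.
#'
#' @param params A `cea_parameters` object.
#' @param cohort `"open"` or `"lap"`.
#' @param n_samples Number of Monte Carlo draws (default 5000).
#' @param seed Integer RNG seed (default 20190816).
#' @return An object of class `psa_result`: list with `cohort`,
#'   `n_samples`, `seed`, and `draws`, a tibble with one row per draw
#'   holding the sampled parameter values (columns as in
#'   [draw_parameter_set()]) and the per-draw outcomes (`cost_no_barrier`,
#'   `cost_barrier`, `delta_cost`, `delta_effect`, both arms' event
#'   probabilities, `p_repeat`).
#' @export
#' @examples
#' psa <- run_psa(default_parameters(), "open", n_samples = 200, seed = 1)
#' probability_cost_saving(psa)
run_psa <- function(params, cohort = c("open", "lap"), n_samples = 5000,
                    seed = 20190816) {
  cohort <- match.arg(cohort)
  stop_unless(is_number(n_samples) && n_samples >= 1,
              "run_psa: 'n_samples' must be >= 1")
  validate_parameters(params)
  v <- withr::with_seed(seed, .sample_values(params, cohort, n_samples))
  draws <- tibble::as_tibble(c(list(iteration = seq_len(n_samples)), v))
  draws <- tibble::as_tibble(cbind(draws, .evaluate_values(v)))
  structure(list(cohort = cohort, n_samples = as.integer(n_samples),
                 seed = seed, draws = draws),
            class = "psa_result")
}

#' Probability that the barrier strategy reduces costs
#'
#' The fraction of PSA draws with negative incremental cost (barrier minus
#' no barrier). This is the probability the barrier strategy is cost saving,
#' i.e. the cost-effectiveness acceptability at a willingness to pay of
#' zero.
#'
#' @param psa A [run_psa()] result.
#' @return A fraction in \[0, 1\].
#' @export
probability_cost_saving <- function(psa) {
  stop_unless(inherits(psa, "psa_result"),
              "probability_cost_saving: 'psa' must be a psa_result")
  mean(psa$draws$delta_cost < 0)
}

#' Percentile confidence interval
#'
#' Empirical percentile interval of a sample: the `100 * (1 - level) / 2`
#' and `100 * (1 + level) / 2` percentiles under the linear-interpolation
#' quantile definition (`stats::quantile(type = 7)`).
#'
#' @param values Nonempty numeric vector (NAs are an error).
#' @param level Coverage level in (0, 1); default 0.95.
#' @return Named numeric vector `c(low, high)`.
#' @export
#' @examples
#' percentile_ci(1:100)  # c(3.475, 97.525)
percentile_ci <- function(values, level = 0.95) {
  stop_unless(is.numeric(values) && length(values) > 0,
              "percentile_ci: 'values' must be a nonempty numeric vector")
  stop_unless(!anyNA(values), "percentile_ci: 'values' must not contain NA")
  stop_unless(is_number(level) && level > 0 && level < 1,
              "percentile_ci: 'level' must be in (0, 1)")
  q <- stats::quantile(values, c((1 - level) / 2, (1 + level) / 2),
                       type = 7, names = FALSE)
  c(low = q[1], high = q[2])
}

#' Export the cost-effectiveness plane
#'
#' One row per PSA draw with the incremental effect (x-axis: adhesion
#' incidence prevented) and incremental cost (y-axis, USD), plus the
#' per-arm costs. Written as CSV with header
#' `iteration,delta_effect,delta_cost,cost_no_barrier,cost_barrier`; the
#' file is byte-stable for a fixed seed.
#'
#' @param psa A [run_psa()] result.
#' @param path Optional CSV output path.
#' @return The export tibble, invisibly if `path` is given.
#' @export
export_ce_plane <- function(psa, path = NULL) {
  stop_unless(inherits(psa, "psa_result"),
              "export_ce_plane: 'psa' must be a psa_result")
  tab <- psa$draws[, c("iteration", "delta_effect", "delta_cost",
                       "cost_no_barrier", "cost_barrier")]
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Summarize a probabilistic sensitivity analysis
#'
#' Means and 95% percentile intervals of the per-arm costs, the incremental
#' cost and effect, and the probability of cost saving.
#'
#' @param object A [run_psa()] result.
#' @param level Interval coverage (default 0.95).
#' @param ... Unused.
#' @return A list with `cohort`, `n_samples`, `seed`,
#'   `probability_cost_saving`, and per-quantity `mean`/`ci_low`/`ci_high`
#'   entries.
#' @export
summary.psa_result <- function(object, level = 0.95, ...) {
  d <- object$draws
  stat <- function(x) {
    ci <- percentile_ci(x, level)
    list(mean = mean(x), ci_low = unname(ci["low"]), ci_high = unname(ci["high"]))
  }
  out <- list(cohort = object$cohort, n_samples = object$n_samples,
              seed = object$seed, level = level,
              probability_cost_saving = probability_cost_saving(object),
              cost_no_barrier = stat(d$cost_no_barrier),
              cost_barrier = stat(d$cost_barrier),
              delta_cost = stat(d$delta_cost),
              delta_effect = stat(d$delta_effect))
  class(out) <- "psa_summary"
  out
}

#' @export
print.psa_summary <- function(x, ...) {
  cat(sprintf("PSA summary, %s cohort (%d draws, seed %d)\n",
              x$cohort, x$n_samples, as.integer(x$seed)))
  line <- function(lbl, s, fmt = "$%.0f")
    cat(sprintf("  %-16s %s (95%% CI %s-%s)\n", lbl,
                sprintf(fmt, s$mean), sprintf(fmt, s$ci_low),
                sprintf(fmt, s$ci_high)))
  line("No barrier", x$cost_no_barrier)
  line("Barrier", x$cost_barrier)
  line("Incr. cost", x$delta_cost)
  line("Incr. effect", x$delta_effect, fmt = "%.3f")
  cat(sprintf("  P(barrier saves costs) = %.1f%%\n",
              100 * x$probability_cost_saving))
  invisible(x)
}

#' @export
print.psa_result <- function(x, ...) {
  print(summary(x))
  invisible(x)
}
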