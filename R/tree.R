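# Decision-tree evaluation: two strategies (no barrier / barrier) for one
# surgical cohort over a 4-year horizon. The tree treats the cohort's event
# probabilities as unconditional per-patient marginals; the ASBO pathway
# (operative vs conservative management) and the repeat-surgery pathway
# (reoperation with vs without adhesions present) contribute additively, and
# the repeat-surgery cost is mixed by the arm's adhesion probability:
#
#   E[cost] = barrier_cost
#           + p_asbo_surgical * C_op + (p_asbo - p_asbo_surgical) * C_cons
#           + p_repeat * [p_adhesions * C_rep_adh + (1 - p_adhesions) * C_rep_noadh]
#
# with p_repeat = p_repeat_raw - p_asbo_surgical(no barrier) shared by both
# arms, so ASBO re-operations are not counted twice.

#' Per-arm event probabilities
#'
#' Computes the event probabilities for one strategy arm. Without risk
#' ratios (`rrs = NULL`) this is the no-barrier arm at the cohort's point
#' estimates. With `rrs`, each probability is multiplied by its risk ratio
#' (adhesions, ASBO, surgically treated ASBO respectively); the surgical-ASBO
#' probability is then clamped to be no larger than the ASBO probability.
#' Both arms share the repeat-surgery probability
#' `p_repeat = p_repeat_raw - p_asbo_surgical(no barrier)`, which removes
#' ASBO re-operations already counted on the ASBO pathway.
#'
#' @param cohort A [cohort_parameters] object.
#' @param rrs `NULL` for the no-barrier arm, or a named list/`cea_parameters`
#'   slice with `rr_adhesions`, `rr_asbo`, `rr_asbo_surgical`
#'   ([relative_risk] objects) for the barrier arm.
#' @param use `"mean"` (default) evaluates at the exact Beta means
#'   `alpha/(alpha+beta)` — the convention under which every event
#'   percentage rounds to its published value; `"point"` uses the rounded
#'   published point estimates instead. The raw repeat-surgery rate always
#'   enters at its headline point estimate.
#' @return An object of class `arm_probabilities` with fields
#'   `p_adhesions`, `p_asbo`, `p_asbo_surgical`, `p_repeat`.
#' @export
#' @examples
#' params <- default_parameters()
#' arm_probabilities(params$open_cohort)           # no-barrier arm
#' arm_probabilities(params$open_cohort, params)   # barrier arm
arm_probabilities <- function(cohort, rrs = NULL, use = c("mean", "point")) {
  use <- match.arg(use)
  stop_unless(inherits(cohort, "cohort_parameters"),
              "arm_probabilities: 'cohort' must be a cohort_parameters object")
  pt <- function(p) {
    if (use == "mean" && is.finite(p$alpha)) p$alpha / (p$alpha + p$beta)
    else p$point
  }
  p_adh <- pt(cohort$p_adhesions)
  p_asbo <- pt(cohort$p_asbo)
  p_surg <- pt(cohort$p_asbo_surgical)
  p_repeat <- max(cohort$p_repeat_raw$point - p_surg, 0)
  if (!is.null(rrs)) {
    clamp1 <- function(x, what) {
      if (x > 1) {
        warning(sprintf("arm_probabilities: %s exceeds 1 after applying its risk ratio; clamped", what))
        1
      } else x
    }
    p_adh <- clamp1(p_adh * rrs$rr_adhesions$point, "p_adhesions")
    p_asbo <- clamp1(p_asbo * rrs$rr_asbo$point, "p_asbo")
    p_surg <- min(clamp1(p_surg * rrs$rr_asbo_surgical$point, "p_asbo_surgical"),
                  p_asbo)
  }
  structure(list(p_adhesions = p_adh, p_asbo = p_asbo,
                 p_asbo_surgical = p_surg, p_repeat = p_repeat),
            class = "arm_probabilities")
}

#' Expected four-year per-patient cost of one strategy arm
#'
#' Evaluates the decision tree for one arm: the barrier acquisition cost (0
#' for the no-barrier arm) plus the expected ASBO treatment cost and the
#' expected repeat-surgery cost, the latter mixed over adhesion status at
#' reoperation.
#'
#' @param arm An [arm_probabilities] object.
#' @param costs A named list with `cost_asbo_operative`,
#'   `cost_asbo_conservative`, `cost_repeat_no_adhesions`,
#'   `cost_repeat_adhesions` — either [cost_param] objects (means are used)
#'   or bare numbers in USD. A full `cea_parameters` object works.
#' @param barrier_cost Barrier acquisition cost in USD (default 0).
#' @return An object of class `strategy_outcome` with fields
#'   `expected_cost`, `p_adhesions`, `p_asbo`, `p_asbo_surgical`,
#'   `barrier_cost_included`.
#' @export
expected_cost <- function(arm, costs, barrier_cost = 0) {
  stop_unless(inherits(arm, "arm_probabilities"),
              "expected_cost: 'arm' must be an arm_probabilities object")
  cost_of <- function(nm) {
    x <- costs[[nm]]
    stop_unless(!is.null(x), sprintf("expected_cost: missing cost '%s'", nm))
    v <- if (inherits(x, "cost_param")) x$mean else x
    stop_unless(is_number(v) && v >= 0,
                sprintf("expected_cost: cost '%s' must be a nonnegative number", nm))
    v
  }
  stop_unless(is_number(barrier_cost) && barrier_cost >= 0,
              "expected_cost: 'barrier_cost' must be a nonnegative number")
  total <- barrier_cost +
    arm$p_asbo_surgical * cost_of("cost_asbo_operative") +
    (arm$p_asbo - arm$p_asbo_surgical) * cost_of("cost_asbo_conservative") +
    arm$p_repeat * (arm$p_adhesions * cost_of("cost_repeat_adhesions") +
                    (1 - arm$p_adhesions) * cost_of("cost_repeat_no_adhesions"))
  stop_unless(total >= 0, "expected_cost: negative expected cost")
  structure(list(expected_cost = total,
                 p_adhesions = arm$p_adhesions,
                 p_asbo = arm$p_asbo,
                 p_asbo_surgical = arm$p_asbo_surgical,
                 barrier_cost_included = barrier_cost),
            class = "strategy_outcome")
}

#' Incremental comparison of the two strategies
#'
#' Computes the incremental cost (barrier minus no barrier), the incremental
#' effect (adhesion incidence prevented: no-barrier minus barrier adhesion
#' probability), and classifies the result: `"dominant"` (more effective and
#' cheaper), `"icer"` (more effective and more expensive; `icer` holds
#' delta_cost / delta_effect in USD per patient with adhesions prevented),
#' `"dominated"` (no more effective and more expensive), or `"equal"`.
#'
#' @param no_barrier,barrier [strategy_outcome] objects from the same cohort
#'   and parameter set.
#' @return An object of class `comparison_result` with fields `delta_cost`,
#'   `delta_effect`, `status`, `icer` (`NA` unless `status == "icer"`).
#' @export
compare_strategies <- function(no_barrier, barrier) {
  stop_unless(inherits(no_barrier, "strategy_outcome") &&
                inherits(barrier, "strategy_outcome"),
              "compare_strategies: inputs must be strategy_outcome objects")
  delta_cost <- barrier$expected_cost - no_barrier$expected_cost
  delta_effect <- no_barrier$p_adhesions - barrier$p_adhesions
  icer <- NA_real_
  if (delta_effect > 0 && delta_cost > 0) {
    status <- "icer"
    icer <- delta_cost / delta_effect
  } else if (delta_effect >= 0 && delta_cost <= 0 &&
             (delta_effect > 0 || delta_cost < 0)) {
    status <- "dominant"
  } else if (delta_effect == 0 && delta_cost == 0) {
    status <- "equal"
  } else if (delta_effect <= 0 && delta_cost >= 0) {
    status <- "dominated"
  } else {
    # less effective and cheaper: a trade-off exists but the barrier cannot
    # be recommended on effectiveness; report the cost per adhesion forgone
    status <- "icer"
    icer <- delta_cost / delta_effect
  }
  structure(list(delta_cost = delta_cost, delta_effect = delta_effect,
                 status = status, icer = icer),
            class = "comparison_result")
}

#' Deterministic base-case evaluation for one cohort
#'
#' Evaluates both strategies at the parameter point estimates and compares
#' them. The barrier acquisition cost defaults to the Beta-PERT mean sheet
#' count times the unit price.
#'
#' @param params A `cea_parameters` object.
#' @param cohort `"open"` or `"lap"`.
#' @param use Point convention, see [arm_probabilities()].
#' @param barrier_cost Barrier cost in USD; default `pert_mean(params$barrier_sheets)`.
#' @return An object of class `strategy_comparison`: a list with
#'   `cohort`, `no_barrier`, `barrier` ([strategy_outcome]s) and
#'   `comparison` ([compare_strategies()] result).
#' @export
#' @examples
#' bc <- base_case(default_parameters(), "lap")
#' bc$comparison$icer
base_case <- function(params, cohort = c("open", "lap"),
                      use = c("mean", "point"),
                      barrier_cost = pert_mean(params$barrier_sheets)) {
  cohort <- match.arg(cohort)
  use <- match.arg(use)
  validate_parameters(params)
  ch <- params[[paste0(cohort, "_cohort")]]
  nb <- expected_cost(arm_probabilities(ch, use = use), params, 0)
  ba <- expected_cost(arm_probabilities(ch, params, use = use), params,
                      barrier_cost)
  structure(list(cohort = cohort,
                 no_barrier = nb, barrier = ba,
                 comparison = compare_strategies(nb, ba)),
            class = "strategy_comparison")
}

#' Base-case barrier cost from the Beta-PERT sheet count
#'
#' The classic PERT mean sheet count, `(minimum + 4 * mode + maximum) / 6`,
#' multiplied by the unit price.
#'
#' @param pert A [pert_param].
#' @return The base-case barrier cost in USD.
#' @export
pert_mean <- function(pert) {
  stop_unless(inherits(pert, "pert_param"), "pert_mean: need a pert_param")
  (pert$minimum + 4 * pert$mode + pert$maximum) / 6 * pert$unit_price
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat(sprintf("Base-case evaluation, %s cohort\n", x$cohort))
  row <- function(lbl, o)
    cat(sprintf("  %-10s $%7.0f  adhesions %5.1f%%  ASBO %4.1f%%\n", lbl,
                o$expected_cost, 100 * o$p_adhesions, 100 * o$p_asbo))
  row("No barrier", x$no_barrier)
  row("Barrier", x$barrier)
  cmp <- x$comparison
  verdict <- switch(cmp$status,
                    icer = sprintf("ICER $%.0f per patient with adhesions prevented",
                                   cmp$icer),
                    dominant = "Dominant (more effective, less costly)",
                    dominated = "Dominated",
                    equal = "Equal")
  cat(sprintf("  Incremental cost $%+.0f, effect %+0.3f: %s\n",
              cmp$delta_cost, cmp$delta_effect, verdict))
  invisible(x)
}

# --- shared vectorised core -------------------------------------------------

# Collapse a cea_parameters object to one set of plain numeric values for a
# cohort. Used by the DSA and threshold modules; the PSA sampler produces
# the same column layout.
.fixed_values <- function(params, cohort, use = "mean") {
  ch <- params[[paste0(cohort, "_cohort")]]
  pt <- function(p) {
    if (use == "mean" && is.finite(p$alpha)) p$alpha / (p$alpha + p$beta)
    else p$point
  }
  list(p_adhesions = pt(ch$p_adhesions),
       p_asbo = pt(ch$p_asbo),
       p_asbo_surgical = pt(ch$p_asbo_surgical),
       p_repeat_raw = ch$p_repeat_raw$point,
       rr_adhesions = params$rr_adhesions$point,
       rr_asbo = params$rr_asbo$point,
       rr_asbo_surgical = params$rr_asbo_surgical$point,
       cost_asbo_operative = params$cost_asbo_operative$mean,
       cost_asbo_conservative = params$cost_asbo_conservative$mean,
       cost_repeat_no_adhesions = params$cost_repeat_no_adhesions$mean,
       cost_repeat_adhesions = params$cost_repeat_adhesions$mean,
       barrier_cost = pert_mean(params$barrier_sheets))
}

# Vectorised two-arm tree evaluation over parallel vectors of parameter
# values (a list/data frame with the 12 .fixed_values columns). Returns a
# tibble of per-set outcomes; identical arithmetic to the scalar functions.
.evaluate_values <- function(v) {
  p_surg_nb <- pmin(v$p_asbo_surgical, v$p_asbo)
  p_repeat <- pmax(v$p_repeat_raw - p_surg_nb, 0)
  p_adh_b <- pmin(v$p_adhesions * v$rr_adhesions, 1)
  p_asbo_b <- pmin(v$p_asbo * v$rr_asbo, 1)
  p_surg_b <- pmin(pmin(p_surg_nb * v$rr_asbo_surgical, 1), p_asbo_b)
  mix_nb <- v$p_adhesions * v$cost_repeat_adhesions +
    (1 - v$p_adhesions) * v$cost_repeat_no_adhesions
  mix_b <- p_adh_b * v$cost_repeat_adhesions +
    (1 - p_adh_b) * v$cost_repeat_no_adhesions
  cost_nb <- p_surg_nb * v$cost_asbo_operative +
    (v$p_asbo - p_surg_nb) * v$cost_asbo_conservative +
    p_repeat * mix_nb
  cost_b <- v$barrier_cost + p_surg_b * v$cost_asbo_operative +
    (p_asbo_b - p_surg_b) * v$cost_asbo_conservative +
    p_repeat * mix_b
  tibble::tibble(
    cost_no_barrier = cost_nb, cost_barrier = cost_b,
    delta_cost = cost_b - cost_nb,
    delta_effect = v$p_adhesions - p_adh_b,
    p_adh_no_barrier = v$p_adhesions, p_adh_barrier = p_adh_b,
    p_asbo_no_barrier = v$p_asbo, p_asbo_barrier = p_asbo_b,
    p_asbo_surgical_no_barrier = p_surg_nb, p_asbo_surgical_barrier = p_surg_b,
    p_repeat = p_repeat)
}
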