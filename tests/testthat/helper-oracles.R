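# Shared fixtures and independent oracles for the test suite.

# Arm built directly from bare probabilities (bypasses cohort construction).
make_arm <- function(p_adh, p_asbo, p_surg, p_repeat) {
  structure(list(p_adhesions = p_adh, p_asbo = p_asbo,
                 p_asbo_surgical = p_surg, p_repeat = p_repeat),
            class = "arm_probabilities")
}

# Random valid (arm, costs, barrier) tuple for property tests.
random_tuple <- function() {
  p_asbo <- stats::runif(1, 0.01, 0.4)
  list(arm = make_arm(p_adh = stats::runif(1),
                      p_asbo = p_asbo,
                      p_surg = stats::runif(1, 0, p_asbo),
                      p_repeat = stats::runif(1, 0, 0.5)),
       costs = list(cost_asbo_operative = stats::runif(1, 5000, 25000),
                    cost_asbo_conservative = stats::runif(1, 500, 5000),
                    cost_repeat_no_adhesions = stats::runif(1, 5000, 20000),
                    cost_repeat_adhesions = stats::runif(1, 5000, 25000)),
       barrier = stats::runif(1, 0, 1200))
}

# Patient-level microsimulation oracle: independent Bernoulli pathways
# (ASBO with nested operative management, repeat surgery with independent
# adhesion status at reoperation), averaged over n_patients.
microsim_cost <- function(arm, costs, barrier_cost, n_patients = 1e6) {
  asbo <- stats::rbinom(n_patients, 1, arm$p_asbo)
  surg_frac <- if (arm$p_asbo > 0) arm$p_asbo_surgical / arm$p_asbo else 0
  surg <- asbo * stats::rbinom(n_patients, 1, surg_frac)
  rep_surg <- stats::rbinom(n_patients, 1, arm$p_repeat)
  adh <- stats::rbinom(n_patients, 1, arm$p_adhesions)
  cost <- barrier_cost +
    surg * costs$cost_asbo_operative +
    (asbo - surg) * costs$cost_asbo_conservative +
    rep_surg * ifelse(adh == 1, costs$cost_repeat_adhesions,
                      costs$cost_repeat_no_adhesions)
  list(mean = mean(cost), se = stats::sd(cost) / sqrt(n_patients))
}

# Fully degenerate parameter set: fixed probabilities (infinite
# pseudo-counts), zero-variance costs and risk ratios, point-mass PERT.
# Every PSA draw equals the deterministic base case exactly.
degenerate_parameters <- function() {
  fix <- function(pt) probability_param(pt, Inf, Inf)
  fix_rr <- function(pt) relative_risk(pt, pt, pt)
  model_parameters(
    open_cohort = cohort_parameters(
      p_adhesions = fix(0.889), p_asbo = fix(0.0856),
      p_asbo_surgical = fix(0.032), p_repeat_raw = fix(0.24)),
    lap_cohort = cohort_parameters(
      p_adhesions = fix(0.623), p_asbo = fix(0.0663),
      p_asbo_surgical = fix(0.031), p_repeat_raw = fix(0.24)),
    rr_adhesions = fix_rr(0.51), rr_asbo = fix_rr(0.68),
    rr_asbo_surgical = fix_rr(0.49),
    cost_asbo_operative = cost_param(18366, 0),
    cost_asbo_conservative = cost_param(2565, 0),
    cost_repeat_no_adhesions = cost_param(14063, 0),
    cost_repeat_adhesions = cost_param(18579, 0),
    barrier_sheets = pert_param(3.3, 3.3, 3.3, unit_price = 629.68 / 3.3))
}

# Bisection oracle for break-even solving on a plain value list: the
# incremental cost re-evaluated through the full tree, root-found with
# uniroot (no reuse of the closed forms under test).
bisect_price_threshold <- function(v, lower = 0, upper = 1e5) {
  g <- function(price) {
    v2 <- v
    v2$barrier_cost <- price
    barriercea:::.evaluate_values(v2)$delta_cost
  }
  if (g(lower) > 0) return(0)
  stats::uniroot(g, c(lower, upper), tol = 1e-9)$root
}

# Assumes the usual case of an effective barrier (repeat-surgery savings
# decrease the incremental cost as the rate rises), which holds for every
# draw from the default parameter distributions.
bisect_reop_threshold <- function(v) {
  # vary the shared repeat probability by shifting the raw rate; the tree
  # computes p_repeat = p_repeat_raw - p_asbo_surgical internally
  g <- function(r) {
    v2 <- v
    v2$p_repeat_raw <- r + min(v$p_asbo_surgical, v$p_asbo)
    barriercea:::.evaluate_values(v2)$delta_cost
  }
  g0 <- g(0)
  g1 <- g(1)
  if (g0 <= 0 && g1 <= 0) return(0)  # cost saving at any repeat rate
  if (g0 >= 0 && g1 >= 0) return(1)  # never cost saving
  stats::uniroot(g, c(0, 1), tol = 1e-9)$root
}
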