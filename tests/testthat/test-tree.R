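params <- default_parameters()

test_that("arm probabilities apply risk ratios and share the repeat rate", {
  nb <- arm_probabilities(params$open_cohort, use = "point")
  expect_equal(nb$p_adhesions, 0.889)
  expect_equal(nb$p_repeat, 0.24 - 0.032)
  ba <- arm_probabilities(params$open_cohort, params, use = "point")
  expect_equal(ba$p_adhesions, 0.889 * 0.51)
  expect_equal(ba$p_asbo, 0.0856 * 0.68)
  expect_equal(ba$p_asbo_surgical, 0.032 * 0.49)
  expect_equal(ba$p_repeat, nb$p_repeat)  # shared between arms
  lap <- arm_probabilities(params$lap_cohort, params, use = "point")
  expect_equal(lap$p_asbo, 0.0663 * 0.68)

  # identity risk ratios leave the arm unchanged
  id <- params
  for (nm in c("rr_adhesions", "rr_asbo", "rr_asbo_surgical"))
    id[[nm]] <- relative_risk(1, 1, 1)
  expect_equal(unclass(arm_probabilities(params$open_cohort, id)),
               unclass(arm_probabilities(params$open_cohort)))

  # mean convention uses exact Beta means
  nb_m <- arm_probabilities(params$open_cohort, use = "mean")
  expect_equal(nb_m$p_adhesions, 80 / 90)
  expect_equal(nb_m$p_repeat, 0.24 - 74 / 2326)

  # probabilities pushed past 1 are clamped with a warning
  big <- params
  big$rr_asbo <- relative_risk(16, 16, 16)
  expect_warning(ba_big <- arm_probabilities(params$open_cohort, big),
                 "clamped")
  expect_equal(ba_big$p_asbo, 1)
})

test_that("expected cost matches hand-expanded tree arithmetic", {
  # hand expansion: 0.05*10000 + (0.1-0.05)*1000 + 0.2*(0.5*8000 + 0.5*5000)
  arm <- make_arm(0.5, 0.1, 0.05, 0.2)
  costs <- list(cost_asbo_operative = 10000, cost_asbo_conservative = 1000,
                cost_repeat_no_adhesions = 5000, cost_repeat_adhesions = 8000)
  out <- expected_cost(arm, costs, barrier_cost = 0)
  expect_equal(out$expected_cost, 1850)

  # empty tree: only the barrier cost remains
  empty <- make_arm(0, 0, 0, 0)
  expect_equal(expected_cost(empty, costs, 630)$expected_cost, 630)
  expect_equal(expected_cost(empty, costs, 630)$barrier_cost_included, 630)

  # cost_param objects and bare numbers are interchangeable
  expect_equal(expected_cost(arm, lapply(costs, cost_param, sd = 1), 0),
               out)
  expect_error(expected_cost(arm, costs[-1], 0), "cost_asbo_operative")
})

test_that("expected cost is affine in every cost input and the barrier price", {
  withr::with_seed(101, {
    for (i in 1:20) {
      tp <- random_tuple()
      base <- expected_cost(tp$arm, tp$costs, tp$barrier)$expected_cost
      # doubling all event costs with no barrier cost doubles the total
      doubled <- expected_cost(tp$arm, lapply(tp$costs, `*`, 2), 0)$expected_cost
      no_barrier <- expected_cost(tp$arm, tp$costs, 0)$expected_cost
      expect_equal(doubled, 2 * no_barrier, tolerance = 1e-12)
      # unit slope in the barrier price
      expect_equal(expected_cost(tp$arm, tp$costs, tp$barrier + 100)$expected_cost,
                   base + 100, tolerance = 1e-12)
      # affine in each single cost: f(c + d) - f(c) is linear in d
      for (nm in names(tp$costs)) {
        bump <- function(d) {
          cc <- tp$costs
          cc[[nm]] <- cc[[nm]] + d
          expected_cost(tp$arm, cc, tp$barrier)$expected_cost
        }
        expect_equal(bump(200) - base, 2 * (bump(100) - base),
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("lowering any risk ratio never raises the barrier arm's cost", {
  rr_grid <- seq(0.2, 1, by = 0.2)
  for (nm in c("rr_adhesions", "rr_asbo", "rr_asbo_surgical")) {
    costs_prev <- Inf
    for (r in rev(rr_grid)) {  # decreasing r
      q <- params
      q[[nm]] <- relative_risk(r, r, r)
      ba <- expected_cost(arm_probabilities(q$open_cohort, q), q, 629.68)
      expect_lte(ba$expected_cost, costs_prev + 1e-9)
      costs_prev <- ba$expected_cost
    }
  }
})

test_that("expected cost agrees with a patient-level microsimulation", {
  withr::with_seed(2024, {
    for (i in 1:25) {
      tp <- random_tuple()
      analytic <- expected_cost(tp$arm, tp$costs, tp$barrier)$expected_cost
      sim <- microsim_cost(tp$arm, tp$costs, tp$barrier, n_patients = 1e6)
      expect_lt(abs(analytic - sim$mean), 3 * sim$se)
    }
  })
})

test_that("comparison classifies dominance, ICER, dominated, and equality", {
  costs <- list(cost_asbo_operative = 10000, cost_asbo_conservative = 1000,
                cost_repeat_no_adhesions = 5000, cost_repeat_adhesions = 8000)
  mk <- function(p_adh, barrier)
    expected_cost(make_arm(p_adh, 0.1, 0.05, 0.2), costs, barrier)
  nb <- mk(0.8, 0)

  dom <- compare_strategies(nb, mk(0.4, 0))   # cheaper and more effective
  expect_equal(dom$status, "dominant")
  expect_true(is.na(dom$icer))

  ic <- compare_strategies(nb, mk(0.4, 500))  # more effective, more costly
  expect_equal(ic$status, "icer")
  expect_equal(ic$icer, ic$delta_cost / 0.4)
  expect_gt(ic$delta_cost, 0)

  dominated <- compare_strategies(nb, mk(0.9, 500))
  expect_equal(dominated$status, "dominated")

  eq <- compare_strategies(nb, mk(0.8, 0))
  expect_equal(eq$status, "equal")
  expect_equal(eq$delta_cost, 0)

  # equal effect, different cost: classified by cost sign, no ICER
  cheaper <- compare_strategies(mk(0.8, 500), mk(0.8, 0))
  expect_equal(cheaper$status, "dominant")
  expect_true(is.na(cheaper$icer))
})

test_that("base case reproduces itself through the exported pieces", {
  bc <- base_case(params, "open")
  nb <- expected_cost(arm_probabilities(params$open_cohort), params, 0)
  ba <- expected_cost(arm_probabilities(params$open_cohort, params), params,
                      pert_mean(params$barrier_sheets))
  expect_equal(bc$no_barrier, nb)
  expect_equal(bc$barrier, ba)
  expect_equal(bc$comparison, compare_strategies(nb, ba))
})
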