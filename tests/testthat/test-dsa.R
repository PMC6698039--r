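params <- default_parameters()

test_that("tornado entries equal direct single-substitution recomputation", {
  for (co in c("open", "lap")) {
    tor <- one_way_tornado(params, co)
    expect_equal(nrow(tor), 12)  # 3 RRs + 4 probabilities + 4 costs + price
    expect_true(all(diff(tor$swing) <= 1e-9))  # sorted descending
    base <- barriercea:::.fixed_values(params, co, "mean")
    for (i in seq_len(nrow(tor))) {
      for (side in c("low", "high")) {
        v <- base
        v[[tor$parameter[i]]] <- tor[[paste0(side, "_input")]][i]
        direct <- barriercea:::.evaluate_values(v)
        expect_equal(tor[[paste0("outcome_at_", side)]][i],
                     direct$delta_cost, tolerance = 1e-12)
        expect_equal(tor[[paste0("effect_at_", side)]][i],
                     direct$delta_effect, tolerance = 1e-12)
      }
    }
  }
})

test_that("tornado bounds follow each parameter's assigned distribution", {
  tor <- one_way_tornado(params, "open")
  row <- function(nm) tor[tor$parameter == nm, ]
  # risk ratios: the reported CI
  expect_equal(unlist(row("rr_adhesions")[, c("low_input", "high_input")]),
               c(low_input = 0.43, high_input = 0.61))
  # probabilities: Beta quantiles
  expect_equal(unname(unlist(row("p_adhesions")[, c("low_input", "high_input")])),
               stats::qbeta(c(0.025, 0.975), 80, 10))
  # costs: mean +/- 1.96 sd
  expect_equal(row("cost_asbo_operative")$high_input,
               18366 + stats::qnorm(0.975) * 2831)
  # barrier price: PERT endpoints
  expect_equal(unname(unlist(row("barrier_cost")[, c("low_input", "high_input")])),
               c(2, 4) * 629.68 / 3.3)
})

test_that("barrier cost has the largest swing among the reported figure's bars", {
  for (co in c("open", "lap")) {
    tor <- one_way_tornado(params, co)
    shown <- tor[tor$parameter %in% c("rr_adhesions", "rr_asbo",
                                      "rr_asbo_surgical", "barrier_cost"), ]
    expect_equal(shown$parameter[which.max(shown$swing)], "barrier_cost")
  }
})

test_that("risk-ratio tornado bars bracket the baseline incremental cost", {
  for (co in c("open", "lap")) {
    tor <- one_way_tornado(params, co)
    baseline <- base_case(params, co)$comparison$delta_cost
    for (nm in c("rr_adhesions", "rr_asbo", "rr_asbo_surgical")) {
      entry <- tor[tor$parameter == nm, ]
      expect_lte(min(entry$outcome_at_low, entry$outcome_at_high),
                 baseline + 1e-9)
      expect_gte(max(entry$outcome_at_low, entry$outcome_at_high),
                 baseline - 1e-9)
    }
  }
})

test_that("a degenerate interval yields zero swing", {
  dp <- degenerate_parameters()
  tor <- one_way_tornado(dp, "open")
  # fixed probabilities, point CIs, zero-sd costs, point PERT: no variation
  expect_true(all(tor$swing < 1e-9))
})

test_that("scenarios reproduce the published best/worst cells", {
  worst <- scenario(params, "open", "worst")
  expect_equal(round(100 * worst$barrier$p_adhesions, 1), 54.2)
  expect_equal(round(100 * worst$barrier$p_asbo, 1), 11.3)
  expect_equal(worst$comparison$status, "icer")
  expect_lt(abs(worst$barrier$expected_cost - 4789) / 4789, 0.005)
  expect_lt(abs(worst$comparison$icer - 908) / 908, 0.03)

  best <- scenario(params, "open", "best")
  expect_equal(best$comparison$status, "dominant")
  expect_equal(round(100 * best$barrier$p_adhesions, 1), 38.2)
  expect_equal(round(100 * best$barrier$p_asbo, 1), 3.0)
  expect_lt(abs(best$barrier$expected_cost - 4129) / 4129, 0.005)

  lap_worst <- scenario(params, "lap", "worst")
  expect_equal(round(100 * lap_worst$barrier$p_adhesions, 1), 38.0)
  expect_equal(round(100 * lap_worst$barrier$p_asbo, 1), 8.7)
  lap_best <- scenario(params, "lap", "best")
  expect_equal(round(100 * lap_best$barrier$p_adhesions, 1), 26.8)
  expect_equal(round(100 * lap_best$barrier$p_asbo, 1), 2.3)
  expect_equal(lap_best$comparison$status, "dominant")
})

test_that("scenarios bracket the baseline and the identity scenario matches it", {
  for (co in c("open", "lap")) {
    bl <- scenario(params, co, "baseline")
    bc <- base_case(params, co)
    expect_equal(bl$comparison, bc$comparison)
    expect_equal(bl$no_barrier, bc$no_barrier)
    worst <- scenario(params, co, "worst")$comparison$delta_cost
    best <- scenario(params, co, "best")$comparison$delta_cost
    expect_gte(worst, bc$comparison$delta_cost)
    expect_lte(best, bc$comparison$delta_cost)
    # the no-barrier arm is untouched by the risk-ratio scenarios
    expect_equal(scenario(params, co, "worst")$no_barrier, bc$no_barrier)
  }
})
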