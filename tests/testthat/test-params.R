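test_that("built-in parameter set matches the published evidence tables", {
  p <- default_parameters()
  expect_equal(p$lap_cohort$p_adhesions$point, 0.623)
  expect_equal(p$lap_cohort$p_adhesions$alpha, 38)
  expect_equal(p$lap_cohort$p_adhesions$beta, 23)
  expect_equal(p$open_cohort$p_asbo$point, 0.0856)
  expect_equal(p$open_cohort$p_asbo$alpha, 199)
  expect_equal(p$open_cohort$p_repeat_raw$point, 0.24)
  expect_equal(p$rr_adhesions$point, 0.51)
  expect_equal(p$rr_asbo$ci_high, 1.32)
  expect_equal(p$cost_asbo_operative$mean, 18366)
  expect_equal(p$cost_asbo_operative$sd, 2831)
  expect_equal(p$cost_repeat_adhesions$mean, 18579)
  # unit price reconstructs the published $629.68 for 3.3 sheets
  expect_equal(3.3 * p$barrier_sheets$unit_price, 629.68)
  # every probability point is the rounded Beta mean
  for (co in c("open_cohort", "lap_cohort")) {
    for (f in c("p_adhesions", "p_asbo", "p_asbo_surgical", "p_repeat_raw")) {
      pp <- p[[co]][[f]]
      expect_lt(abs(pp$point - pp$alpha / (pp$alpha + pp$beta)), 0.01)
    }
  }
  # PERT endpoints times unit price reproduce the published $382-$763 range
  range <- c(p$barrier_sheets$minimum, p$barrier_sheets$maximum) *
    p$barrier_sheets$unit_price
  expect_lt(abs(range[1] - 382), 1)
  expect_lt(abs(range[2] - 763), 1)
  # PERT mean is 3.3 sheets
  expect_equal(pert_mean(p$barrier_sheets), 629.68, tolerance = 1e-9)
})

test_that("constructors reject invariant violations with named errors", {
  expect_error(probability_param(0.6, 10, 10), "within 0.01")
  expect_error(probability_param(1.2, 12, 0), "point")
  expect_error(probability_param(0.5, 0, 0), "alpha \\+ beta")
  expect_error(relative_risk(0.5, 0.6, 0.7), "ci_low <= point")
  expect_error(relative_risk(0.5, -0.1, 0.7), "positive")
  expect_error(cost_param(-5, 10), "mean")
  expect_error(cost_param(5, -10), "sd")
  expect_error(pert_param(4, 3, 2, 100), "minimum <= mode <= maximum")
  expect_error(pert_param(2, 3, 4, 0), "unit_price")
  p <- default_parameters()
  expect_error(
    cohort_parameters(p_adhesions = p$open_cohort$p_adhesions,
                      p_asbo = p$open_cohort$p_asbo_surgical,
                      p_asbo_surgical = p$open_cohort$p_asbo,
                      p_repeat_raw = p$open_cohort$p_repeat_raw),
    "p_asbo_surgical")
  # ordered-cost invariants
  bad <- p
  bad$cost_asbo_conservative <- cost_param(20000, 299)
  expect_error(validate_parameters(bad), "cost_asbo_operative")
  bad <- p
  bad$cost_repeat_no_adhesions <- cost_param(19000, 812)
  expect_error(validate_parameters(bad), "cost_repeat_adhesions")
})

test_that("parameter files round-trip and invalid documents are rejected", {
  p <- default_parameters()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, f)
  expect_equal(load_parameters(f), p, tolerance = 1e-9)

  # the shipped file reproduces the built-in set exactly
  shipped <- system.file("extdata", "default_parameters.yaml",
                         package = "barriercea")
  expect_true(nzchar(shipped))
  expect_equal(load_parameters(shipped), p, tolerance = 1e-9)

  # missing field
  doc <- yaml::read_yaml(f)
  doc$rr_asbo <- NULL
  f2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, f2)
  expect_error(load_parameters(f2), "rr_asbo")

  # surgical-ASBO probability exceeding the ASBO probability
  doc <- yaml::read_yaml(f)
  doc$open_cohort$p_asbo_surgical <- list(point = 0.2, alpha = 20, beta = 80)
  yaml::write_yaml(doc, f2)
  expect_error(load_parameters(f2), "p_asbo_surgical")

  # CI bound above the point estimate
  doc <- yaml::read_yaml(f)
  doc$rr_adhesions$ci_low <- 0.55
  yaml::write_yaml(doc, f2)
  expect_error(load_parameters(f2), "ci_low")
})

test_that("perturbed parameter sets are deterministic, valid, and collapse at scale 0", {
  expect_equal(perturbed_parameters(42, 0.3), perturbed_parameters(42, 0.3))
  expect_false(isTRUE(all.equal(perturbed_parameters(42, 0.3),
                                perturbed_parameters(43, 0.3))))
  expect_equal(perturbed_parameters(7, 0), default_parameters())
  expect_error(perturbed_parameters(1, 0.9), "scale")
  for (seed in 1:100) {
    q <- perturbed_parameters(seed, 0.5)
    expect_silent(validate_parameters(q))
  }
  # perturbed sets survive the file round-trip / loader validation
  f <- withr::local_tempfile(fileext = ".yaml")
  for (seed in c(3, 11, 27)) {
    q <- perturbed_parameters(seed, 0.4)
    write_parameters(q, f)
    expect_equal(load_parameters(f), q, tolerance = 1e-8)
  }
})
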