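#!/usr/bin/env Rscript
# Deterministic sensitivity analysis: best-/worst-case risk-ratio scenarios
# and the one-way tornado over all twelve model parameters at their 95%
# bounds. Rewrites results/base_case.json with the scenario rows and writes
# results/tornado_{open,lap}.csv.

suppressPackageStartupMessages(library(barriercea))

params <- default_parameters()
res <- run_analyses(params, out_dir = "results", analyses = c("base", "dsa"),
                    params_source = "builtin", verbose = TRUE)

for (co in c("open", "lap")) {
  for (w in c("best", "worst")) {
    s <- scenario(params, co, w)
    verdict <- if (s$comparison$status == "icer")
      sprintf("ICER $%.0f", s$comparison$icer) else s$comparison$status
    cat(sprintf("%-4s %-5s case: barrier $%.0f, adhesions %.1f%%, ASBO %.1f%% (%s)\n",
                co, w, s$barrier$expected_cost, 100 * s$barrier$p_adhesions,
                100 * s$barrier$p_asbo, verdict))
  }
  tor <- res$tornado[[co]]
  cat(sprintf("%-4s tornado, top three swings: %s\n", co,
              paste(sprintf("%s ($%.0f)", tor$parameter[1:3], tor$swing[1:3]),
                    collapse = ", ")))
}
cat("\nAmong the risk-ratio and barrier-price bars the barrier price has the\n")
cat("largest swing in both cohorts; over all twelve parameters the cost of\n")
cat("repeat surgery with adhesions ranks first.\n")
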