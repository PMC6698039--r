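#!/usr/bin/env Rscript
# Base-case evaluation: expected 4-year per-patient costs and event
# percentages for colorectal surgery with and without an adhesion barrier,
# in the open and laparoscopic cohorts. Writes results/base_case.json.

suppressPackageStartupMessages(library(barriercea))

params <- default_parameters()
run_analyses(params, out_dir = "results", analyses = "base",
             params_source = "builtin", verbose = TRUE)

for (co in c("open", "lap")) print(base_case(params, co))

lap <- base_case(params, "lap")
cat(sprintf(paste0(
  "\nIn the open cohort the barrier strategy dominates (saves $%.0f per\n",
  "patient while halving adhesion incidence). In the laparoscopic cohort\n",
  "it costs $%.0f more per patient, i.e. $%.0f per patient in whom\n",
  "adhesion formation is prevented.\n"),
  -base_case(params, "open")$comparison$delta_cost,
  lap$comparison$delta_cost, lap$comparison$icer))
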