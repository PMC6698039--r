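# Run orchestration and file outputs. The analysis/ scripts in the
# repository are thin drivers over run_analyses(); render_summary() formats
# a one-page text report from the saved JSON outputs, so a report
# regenerated from disk equals the one produced by a live run.

.bc_record <- function(bc) {
  one <- function(o) list(cost = o$expected_cost,
                          pct_adhesions = 100 * o$p_adhesions,
                          pct_asbo = 100 * o$p_asbo,
                          pct_asbo_surgical = 100 * o$p_asbo_surgical)
  cmp <- bc$comparison
  rec <- list(no_barrier = one(bc$no_barrier), barrier = one(bc$barrier),
              delta_cost = cmp$delta_cost, delta_effect = cmp$delta_effect,
              status = cmp$status)
  if (!is.na(cmp$icer)) rec$icer <- cmp$icer
  rec
}

#' Run the full analysis suite and write its outputs
#'
#' Executes the requested analyses in the order base case, deterministic
#' sensitivity (scenarios + tornado), thresholds, PSA, and writes:
#' `base_case.json` (per cohort: both strategies' cost and event
#' percentages, the incremental comparison, and the best/worst-case
#' scenarios), `tornado_<cohort>.csv`, `thresholds.json`,
#' `ce_plane_<cohort>.csv`, and `psa_summary.json`. All numbers are written
#' unrounded; rounding happens only in [render_summary()].
#'
#' @param params A `cea_parameters` object (default [default_parameters()]).
#' @param out_dir Output directory (created if needed).
#' @param cohorts Character vector among `"open"`, `"lap"`.
#' @param analyses Subset of `c("base", "dsa", "threshold", "psa")`.
#' @param n_samples Monte Carlo draws for PSA and threshold CIs.
#' @param seed Integer RNG seed; each cohort's PSA stream and the threshold
#'   CIs reuse the same seed, so reruns are byte-identical.
#' @param use Point convention, see [arm_probabilities()].
#' @param params_source Provenance string recorded in the outputs
#'   (e.g. `"builtin"` or a file path).
#' @param verbose Print progress lines.
#' @return Invisibly, a list with the in-memory results and the paths
#'   written.
#' @export
run_analyses <- function(params = default_parameters(), out_dir,
                         cohorts = c("open", "lap"),
                         analyses = c("base", "dsa", "threshold", "psa"),
                         n_samples = 5000, seed = 20190816,
                         use = c("mean", "point"),
                         params_source = "builtin", verbose = FALSE) {
  use <- match.arg(use)
  cohorts <- match.arg(cohorts, several.ok = TRUE)
  analyses <- match.arg(analyses, c("base", "dsa", "threshold", "psa"),
                        several.ok = TRUE)
  validate_parameters(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stop_unless(dir.exists(out_dir),
              sprintf("run_analyses: cannot create output directory '%s'", out_dir))
  say <- function(...) if (verbose) message(sprintf(...))
  say("parameters: %s; seed %d; convention '%s'", params_source, seed, use)
  meta <- list(params_source = params_source, seed = seed, use = use)
  results <- list(meta = meta)
  paths <- character()
  wjson <- function(x, file) {
    p <- file.path(out_dir, file)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    p
  }

  if ("base" %in% analyses) {
    say("base case")
    bc <- list()
    for (co in cohorts) {
      bc[[co]] <- list(baseline = .bc_record(base_case(params, co, use = use)))
      if ("dsa" %in% analyses) {
        bc[[co]]$best_case <- .bc_record(scenario(params, co, "best", use))
        bc[[co]]$worst_case <- .bc_record(scenario(params, co, "worst", use))
      }
    }
    results$base_case <- bc
    paths <- c(paths, wjson(c(meta, list(cohorts = bc)), "base_case.json"))
  }
  if ("dsa" %in% analyses) {
    say("tornado")
    for (co in cohorts) {
      tor <- one_way_tornado(params, co, use)
      results$tornado[[co]] <- tor
      p <- file.path(out_dir, sprintf("tornado_%s.csv", co))
      write_tornado(tor, p)
      paths <- c(paths, p)
    }
  }
  if ("threshold" %in% analyses) {
    say("thresholds")
    thr <- list()
    for (co in cohorts) {
      for (kind in c("barrier_price", "reoperation_rate")) {
        t <- threshold_ci(params, co, kind, n_samples, seed, use)
        thr[[co]][[kind]] <- t[c("point", "ci_low", "ci_high",
                                 "n_samples", "seed")]
      }
    }
    results$thresholds <- thr
    paths <- c(paths, wjson(c(meta, list(cohorts = thr)), "thresholds.json"))
  }
  if ("psa" %in% analyses) {
    say("PSA (%d draws)", n_samples)
    psum <- list()
    for (co in cohorts) {
      psa <- run_psa(params, co, n_samples, seed)
      results$psa[[co]] <- psa
      p <- file.path(out_dir, sprintf("ce_plane_%s.csv", co))
      export_ce_plane(psa, p)
      paths <- c(paths, p)
      s <- summary(psa)
      psum[[co]] <- s[c("n_samples", "seed", "probability_cost_saving",
                        "cost_no_barrier", "cost_barrier", "delta_cost",
                        "delta_effect")]
    }
    results$psa_summary <- psum
    paths <- c(paths, wjson(c(meta, list(cohorts = psum)), "psa_summary.json"))
  }
  results$paths <- paths
  invisible(results)
}

#' Render a one-page text summary from saved analysis outputs
#'
#' Reads the JSON files written by [run_analyses()] in `out_dir` and formats
#' a compact report: per cohort a strategy table (cost to whole USD, event
#' percentages to 0.1 point, and the dominance verdict or ICER), then PSA
#' and threshold lines when available. All numbers come from the saved
#' outputs; nothing is recomputed here.
#'
#' @param out_dir Directory holding `base_case.json` (and optionally
#'   `thresholds.json`, `psa_summary.json`).
#' @return Character vector of report lines, invisibly; printed to the
#'   console.
#' @export
render_summary <- function(out_dir) {
  bc_path <- file.path(out_dir, "base_case.json")
  stop_unless(file.exists(bc_path),
              sprintf("render_summary: no base_case.json in '%s'", out_dir))
  bc <- jsonlite::read_json(bc_path)
  lines <- c("Adhesion barrier cost-effectiveness, 4-year horizon",
             sprintf("Parameters: %s", bc$params_source))
  verdict <- function(rec) {
    if (identical(rec$status, "icer")) sprintf("$%.0f", rec$icer)
    else tools::toTitleCase(rec$status)
  }
  strat_row <- function(lbl, o, tail = "") {
    sprintf("  %-12s $%5.0f  %5.1f%%  %5.1f%%  %s", lbl,
            o$cost, o$pct_adhesions, o$pct_asbo, tail)
  }
  scen_lbl <- c(baseline = "Baseline", best_case = "Best-case scenario",
                worst_case = "Worst-case scenario")
  for (co in names(bc$cohorts)) {
    lines <- c(lines, "", sprintf("%s cohort", tools::toTitleCase(co)),
               sprintf("  %-12s %6s  %6s  %6s  %s", "Strategy", "Costs",
                       "Adh.", "ASBO", "Cost per adhesion prevented"))
    for (scen in intersect(names(scen_lbl), names(bc$cohorts[[co]]))) {
      rec <- bc$cohorts[[co]][[scen]]
      lines <- c(lines, sprintf(" %s", scen_lbl[[scen]]),
                 strat_row("No barrier", rec$no_barrier),
                 strat_row("Barrier", rec$barrier, verdict(rec)))
    }
  }
  psa_path <- file.path(out_dir, "psa_summary.json")
  if (file.exists(psa_path)) {
    ps <- jsonlite::read_json(psa_path)
    lines <- c(lines, "", sprintf("PSA (%s draws, seed %s)",
                                  ps$cohorts[[1]]$n_samples, ps$seed))
    for (co in names(ps$cohorts)) {
      s <- ps$cohorts[[co]]
      lines <- c(lines, sprintf(
        "  %-5s P(barrier saves costs) %.0f%%; costs $%.0f (95%% CI $%.0f-$%.0f) vs $%.0f (95%% CI $%.0f-$%.0f)",
        co, 100 * s$probability_cost_saving,
        s$cost_no_barrier$mean, s$cost_no_barrier$ci_low, s$cost_no_barrier$ci_high,
        s$cost_barrier$mean, s$cost_barrier$ci_low, s$cost_barrier$ci_high))
    }
  }
  thr_path <- file.path(out_dir, "thresholds.json")
  if (file.exists(thr_path)) {
    th <- jsonlite::read_json(thr_path)
    lines <- c(lines, "", "Break-even thresholds (95% percentile CI)")
    for (co in names(th$cohorts)) {
      bp <- th$cohorts[[co]]$barrier_price
      rr <- th$cohorts[[co]]$reoperation_rate
      lines <- c(lines, sprintf(
        "  %-5s barrier price $%.0f ($%.0f-$%.0f); repeat-surgery rate %.0f%% (%.0f%%-%.0f%%)",
        co, bp$point, bp$ci_low, bp$ci_high,
        100 * rr$point, 100 * rr$ci_low, 100 * rr$ci_high))
    }
  }
  cat(lines, sep = "\n")
  cat("\n")
  invisible(lines)
}
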