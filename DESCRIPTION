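Package: barriercea
Title: Cost-Effectiveness Modelling of Adhesion Barriers in Colorectal Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-tree cost-effectiveness model comparing colorectal
    surgery with and without an intraperitoneal adhesion barrier, for open
    and laparoscopic cohorts over a four-year horizon. Provides a built-in
    evidence-based parameter set (event probabilities with Beta
    pseudo-counts, barrier risk ratios with 95 percent confidence intervals,
    event costs, and a Beta-PERT distributed barrier cost), deterministic
    base-case evaluation with incremental cost-effectiveness ratios and
    dominance classification, Monte Carlo probabilistic sensitivity analysis
    with percentile confidence intervals and cost-effectiveness-plane
    export, one-way (tornado) and best/worst-case deterministic sensitivity
    analyses, and break-even threshold analyses for the barrier price and
    the repeat-surgery rate.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
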