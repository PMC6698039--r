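---
title: "Methods: a decision-tree cost-effectiveness model of adhesion barriers in colorectal surgery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a decision-tree cost-effectiveness model of adhesion barriers in colorectal surgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barriercea)
```

## The clinical question and the model

Most patients develop peritoneal adhesions after colorectal surgery.
Adhesions cause two costly downstream problems over the following years:
adhesive small bowel obstruction (ASBO), managed either operatively or
conservatively, and adhesiolysis at repeat abdominal surgery, which makes
the reoperation longer, riskier and more expensive. A hyaluronate
carboxymethylcellulose (HA/CMC) film placed at the end of the index
operation roughly halves adhesion incidence, but it costs money up front
and is rarely used. `barriercea` implements a two-strategy decision-tree
model that asks whether that up-front cost pays for itself within four
years, separately for open and laparoscopic cohorts.

For one strategy arm the expected four-year direct healthcare cost per
patient is

$$
E[C] \;=\; C_{barrier}
\;+\; p_{surg}\,C_{op} \;+\; (p_{asbo}-p_{surg})\,C_{cons}
\;+\; p_{rep}\,\bigl[p_{adh}\,C_{rep,adh} + (1-p_{adh})\,C_{rep,noadh}\bigr],
$$

where $p_{adh}$, $p_{asbo}$ and $p_{surg}$ are the per-patient
probabilities of adhesions, of ASBO within four years, and of surgically
treated ASBO (unconditional, so $p_{surg} \le p_{asbo}$), and
$C_{barrier}$ is zero in the no-barrier arm. The event probabilities are
treated as unconditional marginals; the ASBO pathway and the
repeat-surgery pathway contribute additively, and the repeat-surgery cost
is mixed by the arm's adhesion probability. In the barrier arm each
probability is multiplied by its risk ratio (`rr_adhesions`, `rr_asbo`,
`rr_asbo_surgical`), with $p_{surg}$ clamped to stay below $p_{asbo}$.

Both arms share the repeat-surgery probability
$p_{rep} = p_{rep,raw} - p_{surg}^{\,no\,barrier}$: the raw four-year
repeat-abdominal-surgery rate (24%) includes re-operations for ASBO, which
the ASBO pathway already prices, so they are subtracted once, using the
no-barrier surgical-ASBO probability in both arms (the underlying evidence
reports a single repeat-surgery rate per cohort, not one per strategy).
Effects are plain probabilities — the headline effect is the absolute
reduction in adhesion incidence — and no discounting is applied over the
four-year horizon.

The incremental comparison is barrier minus no-barrier for cost and
no-barrier minus barrier for the adhesion probability, so "north-west"
on the cost-effectiveness plane means dominant. When the barrier is more
effective and more expensive the ICER $\Delta C / \Delta E$ is reported in
USD per patient in whom adhesion formation is prevented; when it is more
effective and cheaper the strategy is dominant and no ICER is reported.

## Parameters

`default_parameters()` carries the built-in evidence base; the same values
ship as a YAML file (`inst/extdata/default_parameters.yaml`) for editing.
Each probability stores a point estimate plus Beta pseudo-counts
($\alpha$ patients with the event, $\beta$ without), each risk ratio a
point estimate with its 95% CI, each cost a mean and SD in USD, and the
barrier cost a Beta-PERT sheet count on [2, 4] sheets times a unit price
of \$190.81 (so 3.3 sheets cost \$629.68, the base case). The PERT mode
defaults to 3.45, the value at which the classic PERT mean
$(min + 4\,mode + max)/6$ equals the reported average consumption of 3.3
films per patient; the mode is configurable. All monetary values are USD;
the EUR conversion rate behind the source costs (1 EUR = 1.1264 USD) is
recorded here as provenance only and no currency engine is provided.

Two evaluation conventions are exposed because the published inputs are
rounded Beta means and the original spreadsheet's convention is not
recoverable. `use = "mean"` (the default) evaluates at the exact Beta
means $\alpha/(\alpha+\beta)$; `use = "point"` uses the rounded points.
The mean convention is the default because it is the only one under which
every published percentage cell rounds to its printed decimal and the
break-even prices reproduce to within \$0.20; the two conventions differ
by at most a few dollars in any cost. The raw repeat-surgery rate enters
at its headline value of 0.24 in both conventions, matching how the
published per-cohort repeat rates (0.208, 0.209) were derived.

A degenerate (zero-variance) probability is encoded with infinite
pseudo-counts, `probability_param(p, Inf, Inf)`: the sampler then returns
the point exactly. This representation exists because a Beta with a zero
pseudo-count is rejected as ill-defined, yet the zero-variance limit of
the whole model must be expressible for testing and for fixing individual
parameters.

## Probabilistic sensitivity analysis

`run_psa()` draws 5000 parameter sets by default, one coherent set per
iteration, all parameters independent (no correlation structure is
specified by the evidence): probabilities from Beta($\alpha$, $\beta$);
risk ratios from a lognormal with median at the point estimate and
$\sigma = \log(CI_{high}/CI_{low})/(2 \times 1.96)$, i.e. the 95% CI taken
as symmetric on the log scale; costs from Normal(mean, SD) with negative
draws rejected and redrawn (the evidence does not say how negative draws
were handled; rejection keeps the distribution shape above zero with
negligible mean shift at these SD/mean ratios); and the sheet count from
Beta-PERT with the classic shape constant $\lambda = 4$. Within each
draw the sampled surgical-ASBO probability is clamped below the sampled
ASBO probability and the repeat rate is the sampled raw rate minus the
sampled no-barrier surgical-ASBO rate, floored at zero — the same
construction as the base case, applied per draw.

The whole stream is a pure function of one integer seed (default
20190816, recorded in every output), and exports are byte-stable under a
fixed seed. Interval summaries use the percentile method: empirical
quantiles under the linear-interpolation definition
(`stats::quantile(type = 7)`), so `percentile_ci(1:100)` is
(3.475, 97.525). The probability that the barrier strategy reduces costs
is the fraction of draws with negative incremental cost — the
cost-effectiveness acceptability at a willingness to pay of zero; no
acceptability curve over a willingness-to-pay grid is computed because
the underlying analysis reports none.

## Deterministic sensitivity

`one_way_tornado()` moves each of the twelve parameters to the ends of
its 95% interval, everything else held at base case, and records the
incremental cost at both ends. The interval of each parameter follows its
assigned distribution: reported CIs for the risk ratios, Beta 2.5th/97.5th
percentiles for probabilities, mean ± 1.96 SD (floored at zero) for costs,
and the PERT range endpoints (\$382-\$763) for the barrier cost. Entries
are ranked by the absolute swing in incremental cost; incremental-effect
swings are exported alongside but not ranked. Over the twelve bars the
repeat-surgery-with-adhesions cost has the largest swing in both cohorts
(about \$612 in the open cohort); among the bars the published tornado
figure clearly shows — the three risk ratios and the barrier price — the
barrier price ranks first (about \$382), which is the sense in which the
barrier price "has the largest effect".

`scenario()` evaluates the best and worst cases by setting all three risk
ratios jointly to the lower or upper ends of their CIs, everything else at
base case. The worst-case laparoscopic ICER evaluates to about \$1630
here; the source reports both \$1663 (table) and \$1633 (text) for this
cell, and the reconstruction supports the text value.

## Threshold analysis

The incremental cost is affine in the barrier price (slope exactly 1) and
in the shared repeat-surgery probability, so both break-even points have
closed forms. The price threshold is the current price plus the current
per-patient saving. The repeat-rate threshold solves
$A + rB = 0$, where $B$ is the per-unit-of-rate repeat-surgery cost
difference between arms and $A$ the price-plus-ASBO-pathway remainder;
the result is the largest rate at which the barrier does not save money,
clamped to [0, 1]. Draws in which the sampled repeat-surgery costs invert
(reoperation with adhesions sampled cheaper than without, roughly 1% of
draws) make $B$ non-negative, so the barrier never saves at any rate and
the threshold sits at the 100% boundary — which is why the upper
percentile bound of the laparoscopic repeat-rate threshold reaches 100%.
Threshold CIs recompute the threshold on every draw of the same Monte
Carlo stream and take percentile bounds; a bisection root-finder over the
full tree evaluation is kept in the test suite as an independent oracle
for the closed forms.

## Numerical and testing choices

Problem sizes in the test suite are chosen to keep sampling error well
below the assertion tolerances: distribution moment checks use $10^5$
draws; the analytic expected cost is checked against a patient-level
microsimulation ($10^6$ simulated patients per parameter tuple, 25 random
tuples, agreement within 3 standard errors); the closed-form thresholds
are checked against bisection on 50 sampled parameter sets to within
\$0.01 or 0.01 in rate; PSA reproduction checks use the full 5000 draws.
Validation is strict and named: a parameter file missing a field, a
surgical-ASBO probability above the ASBO probability, or a CI bound on
the wrong side of its point estimate all fail loudly at load time, and no
field has a silent default.

`perturbed_parameters(seed, scale)` generates alternative parameter sets
with the same statistical structure as the defaults — each point displaced
a fraction `scale` of the way towards one draw from its own distribution,
with pseudo-counts, CIs and orderings rebuilt so every invariant still
holds. It emulates sampling variation in the evidence base, not new
evidence: source heterogeneity, correlated parameters, or structurally
different trees are outside what passing property tests on these sets can
demonstrate.

## Known limitations

* The model reproduces the published base-case costs to within about
  \$5-12 (0.1-0.3%), not exactly; the original spreadsheet's rounding
  conventions are unrecoverable, and all tolerances in the tests absorb
  this residual.
* The published open-cohort repeat-rate threshold of 16% reconstructs to
  15.4% here (the laparoscopic 24% reproduces as 23.6%). The \$12-scale
  internal discrepancy above is enough to explain the gap; the
  reconstruction is kept as computed.
* The published PSA interval for the open no-barrier cost
  (\$3074-\$6284) is wider on the left than this implementation produces
  (about \$3450) under the stated parameter distributions; the upper
  endpoint agrees within 10%. The extra published spread cannot be traced
  to any stated distributional assumption.
* Female infertility and chronic visceral pain, severity/extent grading
  of adhesions, time horizons beyond four years, QALY weighting, and
  correlation between parameters are all out of scope, mirroring the
  boundaries of the underlying evidence synthesis.
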