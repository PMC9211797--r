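---
title: "MPT models of recognition memory: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MPT models of recognition memory: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mptmem)
```

## The statistical model

A multinomial processing tree (MPT) model describes, for each item-type
condition (a *tree*), the probabilities of the observable response
categories as sums over latent processing paths (*branches*).  Each branch
probability is a product of first-order terms $\theta$ or $1-\theta$, so for
tree $j$ and category $c$

$$p_{jc}(\theta) \;=\; \sum_{b \in \mathcal{B}_{jc}} \;
  \prod_{s} \theta_s^{a_{bs}} (1-\theta_s)^{b_{bs}},$$

with $a_{bs}, b_{bs}$ the number of direct and complement occurrences of
parameter $s$ on branch $b$.  Observed counts $n_{jc}$ are modelled as
independent multinomials per tree (product-multinomial likelihood).  The
restriction to first-order products matches the EQN file convention and
covers both built-in models; exponents, order constraints and nonlinear
parameter functions are out of scope.

Two concrete models are shipped, each with one set of trees per animacy
status (suffix `_a` animate, `_i` inanimate):

* the **four-states model** of remember–know–guess judgments
  (parameters $r, f, d, g_r, g_f, g_g$ per animacy set; old-word and
  new-word trees share the guessing parameters, as the tree diagrams
  specify), and
* the **two-high-threshold process-dissociation model**
  (parameters $r, f, d, g_i, g_e$; four binomial trees per animacy set from
  crossing inclusion/exclusion instructions with Phase-1 old words / new
  words).  Phase-2 words are excluded from the analysis by design, matching
  standard practice for the process-dissociation procedure.

The unrestricted process-dissociation model has 10 parameters on 8
independent data cells and is not identifiable; `identifiability_check()`
verifies this numerically (maximal Jacobian rank 8).  The identifying
restriction $r = d$ within each animacy set — the variant found to perform
best in published validation studies — yields a saturated model and is part
of the built-in base restriction set.

## Hypothesis tests and sensitivity

Substantive hypotheses are equality restrictions.  The analysis ladder for
both experiments first equates all guessing parameters across animacy (the
*base model*), then tests one memory parameter at a time by adding its
equate and referring $\Delta G^2 = G^2_{restricted} - G^2_{base}$ to a
central $\chi^2$ with degrees of freedom equal to the number of free
parameters lost.  Effect sizes use Cohen's convention $w = \sqrt{\Delta
G^2/N}$ with $N$ the total number of analyzed responses (17,600 in the
first design, 16,952 in the second); the noncentrality of the test is
$\lambda = N w^2$.  `minimal_detectable_w()` inverts the noncentral
$\chi^2$ power function by root-finding ($\lambda^* \approx 12.995$ for
df 1, $\alpha = .05$, power .95).  Tests are reported unadjusted for
multiple comparisons, mirroring the source analyses; the printed report
flags this.

## Data reconstruction

No raw data accompany the published study; the aggregate tables are,
however, fully determined by the printed mean judgment proportions and the
design counts.  Because every participant contributes the same number of
items per tree (40 in the first experiment; 26 analyzed items per tree in
the second), the mean of per-participant proportions equals the pooled
proportion, and pooled counts are proportion × total with totals
4,400 = 110 × 40 per tree (Experiment 1) and 2,106 = 81 × 26 /
2,132 = 82 × 26 per inclusion/exclusion tree (Experiment 2).
`reconstruct_counts()` renormalizes each printed row (rounded rows can sum
to .99–1.01), multiplies by the total, and integerizes by largest-remainder
rounding with ties broken by category order — deterministic,
total-preserving, and with at most one count of distortion per cell.

The printed proportions are rounded to two decimals, which bounds how
exactly refits can reproduce the published estimates.  Most parameters
reproduce to within ±.01; the inanimate detection parameter $d_i$ is the
most sensitive quantity because it is recovered from
$d = (P(\text{new}\mid\text{new item}) - Q)/(1 - Q)$ with $Q$ the
guess-new path probability, so a ±.005 input perturbation can move it by
about ±.015.  $G^2$-type statistics are quadratic in the cell perturbations
and are therefore checked qualitatively (same significance pattern), not to
two decimals.

## Estimation

`fit_mpt()` offers two interchangeable backends, and the test suite asserts
they agree to 1e-4 on all fixtures:

* **EM**: the classical MPT expectation-maximization update.  The E-step
  distributes each cell count over its branches proportionally to the
  branch probabilities; the M-step is the closed-form update
  $\theta_s \leftarrow E[\#\text{direct}] / E[\#\text{occurrences}]$.
  Convergence is declared when the log-likelihood improves by less than
  1e-10 between iterations.
* **quasi-Newton**: BFGS on the negative log-likelihood after a logit
  transform of each free parameter, with the analytic gradient.

Both use a midpoint start plus `n_starts` random starts (default 10) under
an explicit seed (default 20220621); EM runs every start briefly and
polishes only the best.  Parameters are clamped to $[10^{-8}, 1-10^{-8}]$
during optimization.  Estimates within 1e-6 of a bound are reported as
boundary estimates with `NA` standard errors, since the information matrix
is undefined there.  Standard errors elsewhere are square roots of the
diagonal of the inverse *observed* Fisher information in the reduced space
(finite differences of the analytic gradient); whether the original
analysis tool used observed or expected information is not documented, so
agreement with published standard errors is only asserted to ±.005.
$G^2$ uses the $0\log 0 = 0$ convention; a zero expected cell with a
positive observed count yields an infinite $G^2$ and a flagged fit.

## What the simulator does and does not emulate

`sample_frequencies()` draws pooled multinomial counts per tree at stated
parameter values — exactly the homogeneity assumption the analysis model
makes.  It deliberately omits participant-level heterogeneity, word-level
covariates, and response times: adding them would change the estimand, and
passing recovery tests would then say nothing about this estimator.
Consequently, the simulation results validate the machinery under the
model's own assumptions; they cannot show robustness to heterogeneous
participants, which would require hierarchical (e.g. beta-MPT) extensions
that are out of scope.

For power validation, the population effect size of a scenario is defined
by the standard noncentrality construction: the restricted model is fitted
to the exact expected counts (an "infinite-N" fit; `population_w()`), and
the resulting per-observation $\Delta G^2$ converts to
$w = \sqrt{\Delta G^2/N}$.

## Problem sizes and numerical choices

The shipped studies use sizes chosen to keep Monte-Carlo error small while
the full suite stays comfortably interactive: 200 replicates for the
bias check and 300–500 for coverage and power comparisons at the design's
own totals (4,400 per tree), with 3-standard-error Monte-Carlo bands for
rate comparisons.  Structural completeness (per-tree probabilities sum
to 1) is checked numerically at random parameter points with tolerance
1e-9 rather than symbolically, avoiding a computer-algebra dependency;
local identifiability is the numerical Jacobian rank at random interior
points.  Replicate streams derive from `(seed, rep_index)` so individual
replicates are reproducible in isolation.

```{r quick-example, eval = FALSE}
report <- run_analysis("exp1")
print(report)
analysis_to_json(report, "exp1_report.json")
```

## Known limitations

* Estimation is aggregate-level only; no hierarchical, Bayesian, or
  bootstrap inference.
* Reproduction of the published numbers is bounded by the two-decimal
  rounding of the source proportions (see above); the significance pattern
  and all guessing/detection estimates but $d_i$ reproduce within ±.01.
* EQN serialization does not represent fixed-value restrictions (the format
  has no constant terms); export the unrestricted model and re-apply
  restrictions on the other side.
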