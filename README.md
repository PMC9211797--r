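# mptmem

Multinomial processing tree (MPT) models of recognition memory: maximum
likelihood estimation, restriction-based hypothesis tests, and power /
sensitivity analysis — built around the question of whether animacy (the
memory advantage of words denoting living beings) enhances recollection,
familiarity, or mere guessing.

## The models

An MPT model expresses the probability of each observable response category
as a sum over latent processing branches, each branch a product of
parameters θ ∈ [0, 1] and complements 1 − θ.  Two classical recognition
models are built in, each duplicated over an animacy factor (animate /
inanimate word sets):

* **Four-states model** (remember–know–guess paradigm).  Old words are
  recollected with probability *r*, or else feel familiar with conditional
  probability *f*; otherwise a guessing chain produces "detailed
  recollection" (*g*<sub>r</sub>), "feeling of familiarity"
  ((1 − *g*<sub>r</sub>)·*g*<sub>f</sub>), "guessing", or "new" judgments.
  New words are detected as new with probability *d*, otherwise enter the
  same guessing chain.
* **Two-high-threshold process-dissociation model**.  Phase-1 words and new
  words are tested under inclusion and exclusion instructions; recollection
  lets participants *exclude* Phase-1 words, whereas familiarity prompts
  false "old" responses, which is what separates the two processes.
  Guessing "old" has separate rates under inclusion (*g*<sub>i</sub>) and
  exclusion (*g*<sub>e</sub>); new words are detected with probability *d*,
  and the validated identifying restriction *r* = *d* is applied per animacy
  set.

Fitting maximizes the product-multinomial likelihood
ℓ(θ) = Σ<sub>jc</sub> n<sub>jc</sub> log p<sub>jc</sub>(θ) (EM and
logit-space quasi-Newton backends).  Goodness of fit is
G² = 2 Σ n<sub>jc</sub> log(n<sub>jc</sub>/n̂<sub>jc</sub>); substantive
hypotheses are equality restrictions tested by ΔG² against the nested base
model, with effect size w = √(ΔG²/N) and noncentral-χ² power analysis
(λ = N·w²).

Aggregate frequency tables for both experiments are reconstructed from the
published mean judgment proportions (largest-remainder rounding at the known
per-tree totals: 4,400 per tree in Experiment 1; 2,106 / 2,132 in
Experiment 2), so the whole analysis reruns from a clean checkout with no
downloads.

## Worked example

```r
library(mptmem)
report <- run_analysis("exp1")
print(report)
```

```
=== Model-based analysis: exp1 ===
Base model fit: G2(3) = 3.00, p = .392
Parameter estimates (full space):
  r_a    0.50 (SE = 0.01)
  f_a    0.27 (SE = 0.02)
  d_a    0.72 (SE = 0.01)
  gr_a   0.08 (SE = 0.01)
  gf_a   0.27 (SE = 0.01)
  gg_a   0.25 (SE = 0.01)
  r_i    0.45 (SE = 0.01)
  f_i    0.28 (SE = 0.02)
  d_i    0.63 (SE = 0.02)
  gr_i   0.08 (SE = 0.01)
  gf_i   0.27 (SE = 0.01)
  gg_i   0.25 (SE = 0.01)
Hypothesis tests (extra restriction vs base model):
  recollection  Delta G2(1) = 17.48, p < .001, w = 0.03
  familiarity   Delta G2(1) = 0.01, p = .917, w = 0.00
  detection     Delta G2(1) = 26.25, p < .001, w = 0.04
Sensitivity: w = 0.03 detectable with power 0.95 at alpha = 0.05 (N = 17600, df = 1, lambda = 12.995)
Note: tests are reported unadjusted for multiple comparisons.
```

Reading: the base model (guessing equated across animacy, `_a`/`_i`
suffixes for animate/inanimate) fits the data, G²(3) = 3.00, *p* = .39.
Equating recollection across animacy significantly worsens the fit
(*p* < .001) — animate words are recollected more often — as does equating
new-word detection, while familiarity shows no animacy effect.  The design
could have detected effects as small as w = 0.03 with 95% power.
`run_analysis("exp2")` gives the corresponding process-dissociation
analysis, which reproduces the same qualitative pattern from
performance-based (rather than introspective) data.

Everything is scriptable from a shell as well:

```sh
inst/cli/mptmem reproduce exp1 --out report.json
inst/cli/mptmem power --N 17600 --df 1 --alpha 0.05 --power 0.95
inst/cli/mptmem fit --model inst/extdata/four_states.eqn \
    --data inst/extdata/exp1_counts.csv --restrict "gr_a=gr_i;gf_a=gf_i;gg_a=gg_i"
```

Models are read and written in the EQN format used across the MPT software
ecosystem (`read_eqn()` / `write_eqn()`), and the built-in models and
frequency tables are shipped as plain text under `inst/extdata/` so external
MPT tools can replicate the fits on identical inputs.  A multinomial
simulator (`sample_frequencies()`, `recovery_study()`, `empirical_power()`)
validates the estimator and the analytic power machinery.

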