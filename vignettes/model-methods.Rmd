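---
title: "Model and methods: screening plus minimal contact psychotherapy for sub-threshold depression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcpcea)
```

## The decision problem

Sub-threshold (minor) depression — depressive symptoms below the
diagnostic threshold for major depressive disorder — carries an
elevated risk of progressing to a major depressive episode (MDE).
The modelled strategy screens adult general-practice attenders
opportunistically, confirms eligibility in a diagnostic interview, and
offers those with sub-threshold depression minimal contact
psychotherapy (MCP): a cognitive-behavioural self-help manual with
brief telephone support.  The comparator is care as usual.  The
package quantifies whether the up-front screening and treatment costs
are justified by averted depression burden (DALYs) and cost offsets,
from a health-care and a societal perspective.

## Cohort model

`run_cohort()` simulates a closed cohort, all starting in
sub-threshold depression, in four-week cycles (13/year) over 65
cycles (five years — one year of intervention effect plus the
two-year span of each probability curve, with room for the
consequences to play out).

States and transitions:

* `SUB` → `MDE_1` with the per-cycle incidence probability; `SUB` is
  otherwise absorbing (no remission from sub-threshold depression,
  and no mortality — the trial evidence did not include it, which
  makes the model's health gains conservative).
* `MDE_k` → `REC_1` with recovery probability `r(k)` falling with
  episode duration `k`; otherwise `MDE_(k+1)`.
* `REC_j` → `MDE_1` with relapse probability `s(j)` falling with time
  since recovery `j` (relapse and recurrence are pooled as one
  process); otherwise `REC_(j+1)`.  Recovered persons carry
  sub-threshold costs and disability.

Duration dependence makes the process semi-Markov; tunnel expansion
(one state per cycle already spent in episode/recovery) restores the
Markov property exactly, so the cohort recursion is a plain
vector-matrix product.  `microsim_cohort()` implements the same rules
at the individual level and is used in the tests as an independent
convergence oracle (200,000 persons agree with the cohort engine to
within 0.01 occupancy at every cycle).

### Numerical conventions

* **Cycle length** is 1/13 year (the per-cycle costs were derived by
  dividing yearly costs by 13), not 28/365 year.
* **Annual → cycle probabilities** use the constant-hazard transform
  `1 − (1 − P)^(1/13)` (`annual_to_cycle_prob()`), applied to point
  estimates and to every PSA draw alike.
* **Tail rule**: both curves span 26 cycles; beyond the span the last
  per-cycle probability is held (`hold_last`).  The source states the
  two-year span but not the continuation; holding the last hazard is
  the conservative choice, and `zero` is available as a config switch.
* **First-cycle convention**: a person entering `MDE_1` at cycle *t*
  can first recover at *t*+1 with `r(1)`; no same-cycle double
  transitions.
* **State membership is counted at cycle start**; time lived during
  cycle *t* is attributed to the state occupied at its start.  A
  half-cycle correction (trapezoid end-weights) is implemented but off
  by default (`options$half_cycle_correction`), since the source model
  does not describe one.
* **Discounting** uses exact fractional-year exponents
  `(1 + rate)^(−cycle/13)` — smooth and order-independent — at 4%/year
  for costs and 1.5%/year for effects.  One-off screening and
  intervention costs fall at *t* = 0 and are undiscounted.

## Parameters

All inputs live in one `mcp_params` object (`default_params()`), and
can be round-tripped through plain-text YAML + curve CSVs
(`save_params()` / `load_params()`, 17-significant-digit decimals, so
the round trip is bit-exact).  The important ones:

| parameter | default | unit | note |
|---|---|---|---|
| one-year incidence, usual care | 21/111 | prob/year | control-arm trial counts; 1.6%/cycle |
| one-year incidence, MCP | 14/109 | prob/year | 1.1%/cycle; effect lasts 13 cycles |
| effect duration | 13 | cycles | after one year both arms behave identically |
| sub-threshold costs | 132 / 439 | €/cycle | health-care / societal, usual care |
| sub-threshold costs, MCP year | 139 / 384 | €/cycle | intervention scenario, cycles 0–12 |
| MDE costs | 268 / 615 | €/cycle | both scenarios |
| recovered costs | = sub-threshold usual care | €/cycle | both scenarios |
| disability weights | 0.46 / 0.097 | — | MDE / sub-threshold (recovered = sub-threshold) |
| unit costs | 5, 119, 423 | € | screen step 1, diagnostic interview, MCP |
| cascade | 7.2M × .725 × .266 × .357 × .595 | persons | GP attenders → treated |
| discounting | 4 / 1.5 | %/year | costs / effects |

Societal cost figures include health-care costs, so the societal
perspective uses the societal column alone (never a sum of the two).

### PSA distributions

Each uncertain input carries a `dist_spec`: beta for fractions and
probabilities, gamma for costs.  Design choices worth recording:

* **Gamma costs are rebuilt by method of moments** from the printed
  point estimate and 95% interval (`moments_to_gamma()`: mean = point,
  sd = half-width/1.96), because several printed shape/scale pairs are
  mutually inconsistent with their printed means under any reading
  (e.g. a (33, 258) pair printed beside a mean of 439, where the
  published price-indexing step is unquantified).  The printed pairs
  are retained in each spec's `provenance` string.
* **Incidence specs are parameterised on the one-year scale** (beta on
  trial counts, point = mean = events/n), and every draw is converted
  with the constant-hazard transform afterwards.  Storing the printed
  per-cycle values as the point estimates instead would break the
  identity between the collapsed PSA and the deterministic run.  The
  printed per-cycle values (0.016, 0.011) are kept as
  `printed_cycle_*` fields and enforced as consistency checks by
  `validate_params()`; the annual 95% beta quantiles transform to the
  printed per-cycle intervals.
* **Sub-threshold disability weight**: the documentation value is
  0.097, but the PSA samples a quality-of-life beta(106, 11) and uses
  dw = 1 − QoL (0.094 at the point estimate).  The two published
  numbers disagree by 0.003; the package keeps both, using 0.097 as
  the `weights$dw_sub` default for direct DALY accounting and the QoL
  route inside `deterministic_run()`/`run_psa()` so the deterministic
  pipeline is exactly the PSA's degenerate limit.  The MDE weight 0.46
  has no published distribution and stays fixed.
* **Cascade fractions are sampled** (their distributions are
  published), with the screened-to-interview step sampled as the
  collapsed beta(364, 3463) fraction; the same drawn fractions feed
  both the counts and the one-off costs within a draw, so each PSA
  iteration is an internally consistent world.  All draws are
  independent across parameters (only marginals are published).
* **Degenerate specs** (zero spread) are first-class: `collapse_spec()`
  turns the whole PSA into the deterministic run, which the tests
  assert to bit precision.
* **Seed policy**: one master seed generates a sub-seed per run;
  `psa_draw()` replays any single run.  Draws that would leave the
  parameter domain are rejected and redrawn with a logged count — a
  safeguard that cannot trigger with the base beta/gamma families but
  protects user-supplied specs.
* **Boundary conventions**: on the cost-effectiveness plane, ΔC = 0
  counts as "not additional cost" (south side) and ΔE = 0 as "no
  gain" (west side); the CEAC uses the net-monetary-benefit indicator
  `λΔE − ΔC ≥ 0`, which handles negative-ΔE draws correctly.

## Synthetic inputs, and what the tests do and do not show

Two inputs were never published as numbers:

* **Recovery and relapse curves** exist only as figures.
  `gen_curve()` generates monotone stand-ins; the defaults —
  recovery `0.25·exp(−0.10(k−1))` (median episode length three to
  four cycles, consistent with short median depressive episodes) and
  relapse `0.04·exp(−0.08(j−1))` — are labelled SYNTHETIC in the
  fixture bundle and were chosen once for qualitative plausibility.
  They are configuration, not constants.
* **Trial event counts** are regenerated by `gen_trial_counts()`
  (binomial arms, hazard-ratio effect), and `fit_incidence_beta()`
  recovers the incidence beta from them; a property test checks the
  generating probability is recovered within its binomial 95% band at
  n = 111.

Consequently the published aggregate magnitudes (≈€16M incremental
health-care costs, ≈−€390M societal, ≈12,000 DALYs averted, the
€1,400/DALY ICER, the quadrant percentages and the ≈80% acceptability
at €20,000/DALY) are **not reproduced** under the synthetic curves:
with short synthetic episodes the averted burden per prevented episode
is far smaller, so the health-care ICER lands an order of magnitude
higher, while the qualitative conclusions (positive mean DALYs
averted; societal perspective cost saving on average; all four plane
quadrants populated) do hold and are asserted.  What the test suite
certifies is the machinery: exact transform arithmetic, cascade
accounting, conservation to 1e-9, agreement with the independent
microsimulation, ICER invariance to the screened fraction (scaling it
moves numerator and denominator identically), PSA/deterministic
coherence, CEAC definition and monotonicity, and parameter recovery.
A related known gap: no combination of the published unit costs and
cascade fractions reproduces the published €54M/€42M
screening/intervention cost split; the package reports its own
internally consistent totals (≈€85M and ≈€125M at point estimates).

Raising the sub-threshold disability weight to 0.19 (the weight of
mild major depression) shrinks DALYs averted and raises the
health-care ICER — the direction is asserted in the tests; whether the
ICER stays under €2,000/DALY is curve-dependent and is only logged.

## Problem sizes

The shipped configuration runs the full analysis at its native scale:
5000 PSA runs over the 65-cycle horizon complete in well under a
minute on one CPU, and the microsimulation oracle uses 200,000
individuals in the acceptance checks (50,000 in the quicker unit
test).  `scripts/acceptance.R` re-runs everything at full scale from
a single seed.

## Limitations

Beyond the synthetic curves: no mortality, no age structure, no
dependence of relapse risk on episode history, a single-trial
effectiveness estimate whose one-year effect duration is an
assumption, cross-sectionally constant incidence, and no modelling of
repeat screening.  These mirror the scope of the source analysis; the
package's contribution is a transparent, property-tested
implementation, not a re-estimation of the evidence base.
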