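# mcpcea

A Markov cohort model for the health-economic evaluation of
opportunistic screening in primary care combined with **minimal
contact psychotherapy (MCP)** — a guided self-help format of the
'Coping with Depression' course — for adults with **sub-threshold
(minor) depression**, aimed at preventing major depressive episodes.
It is written for health economists and epidemiological modellers who
want a tested, fully scriptable implementation of this class of
screen-and-treat decision model.

## The model

A closed cohort of persons with sub-threshold depression is simulated
over a five-year horizon in four-week cycles (13 cycles/year, 65
cycles).  Three clinical states are modelled, with duration-dependent
hazards expressed through tunnel states:

- **SUB** — sub-threshold depression.  Each cycle a person develops a
  major depressive episode with probability *p*, obtained from the
  one-year trial incidence *P* by the constant-hazard transform
  *p* = 1 − (1 − *P*)^(1/13).  Base case: *P* = 21/111 under usual
  care (*p* ≈ 1.6%) and *P* = 14/109 under MCP (*p* ≈ 1.1%), the MCP
  effect lasting one year.  There is no remission from sub-threshold
  depression.
- **MDE_k** — major depressive episode, *k*-th cycle of the episode
  (*k* = 1…26).  Recovery probability *r(k)* declines with episode
  duration.
- **REC_j** — recovered, *j*-th cycle since recovery (*j* = 1…26).
  Relapse probability *s(j)* declines with time since recovery.

Both curves span two years; beyond the span the last value is held.
There is no mortality, so occupancy is conserved exactly.

Health effects are **DALYs** (time in state × disability weight: 0.46
for major depression, 0.097 for sub-threshold and recovered),
discounted at 1.5%/year.  Costs carry per-cycle state prices from the
health-care and societal perspectives (the societal figures include
health-care costs), discounted at 4%/year, plus one-off screening
(€5 + €119 steps) and intervention (€423) costs applied to the
screening cascade: 7.2 million GP attenders × 72.5% screened × 26.6%
screen-positive × 35.7% interviewed × 59.5% included ≈ 0.3 million
treated.  The **ICER** is the ratio of mean incremental costs to mean
incremental DALYs averted; a probabilistic sensitivity analysis
(default 5000 runs over beta/gamma input distributions) yields
cost-effectiveness planes and acceptability curves (net-monetary-
benefit rule, NMB = λ·ΔE − ΔC).

The recovery and relapse curves were published only as figures, so the
package ships clearly-labelled synthetic exponential-decay stand-ins
(`gen_curve()`); absolute cost/DALY magnitudes therefore depend on the
curves you supply, while the transform, cascade, accounting and PSA
machinery are exact.  An individual-level microsimulation
(`microsim_cohort()`) serves as an independent oracle for the cohort
engine.

## Worked example

```r
library(mcpcea)
params <- default_params()         # base case + synthetic curves
cascade_counts(params)
#> <cascade_counts> (millions of persons)
#>   screened:        5.220
#>   positive:        1.389
#>   interviewed:     0.496
#>   treated:         0.295

deterministic_run(params)
#> <mcp_result> deterministic run, target population scale
#>   screened / treated (millions):  5.22 / 0.30
#>   screening costs:                    85.2 M euro
#>   intervention costs:                124.8 M euro
#>   other health-care expenditure:       7.8 M euro
#> <incremental_result> intervention vs reference
#>   incremental health-care costs:      217.9 M euro
#>   incremental societal costs:          -6.7 M euro
#>   DALYs averted:                       3611
#>   ICER (health care):            60,000 per DALY averted
#>   ICER (societal):               cost saving

psa <- run_psa(params, n_runs = 5000, seed = 1)
psa_summary(psa)
#> <psa_summary> 5000 runs
#>   incremental health-care costs:    220.4 M euro (-81/503)
#>   incremental societal costs:        -5.0 M euro (-1205/1332)
#>   DALYs averted:                     3495 (-2226/8396)
#>   ICER (health care):            63,000 per DALY averted
#>   ICER (societal):               cost saving
#>   CE plane, health care:  NE 83%  SE 7%  SW 1%  NW 9%
#>   CE plane, societal:     NE 43%  SE 47%  SW 5%  NW 5%
```

Reading: 1.4 million persons screen positive and 0.3 million (4% of
the target population) receive MCP.  Under the synthetic default
curves the intervention averts ~3,500 DALYs; from the societal
perspective it is cost saving on average (productivity-loss savings
exceed the €210M delivery cost), while from the health-care
perspective it costs ~€63,000 per DALY averted.  With empirically
estimated recovery/relapse curves (longer episodes, higher relapse)
averted DALYs and cost offsets are substantially larger.

Parameter sets live in plain-text YAML + curve CSVs
(`inst/extdata/basecase/`; see `load_params()`, `save_params()`,
`write_fixture_bundle()`), and a thin command line is provided:

```sh
inst/cli/mcpcea run --params inst/extdata/basecase/basecase.yaml --out results/
inst/cli/mcpcea validate --params inst/extdata/basecase/basecase.yaml
```

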