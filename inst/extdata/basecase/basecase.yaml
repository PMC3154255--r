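grid:
  cycles_per_year: 13
  horizon_cycles: 65
transitions:
  p_inc_year_ref: 0.1891891891891892
  p_inc_year_int: 0.12844036697247707
  printed_cycle_ref: 0.016
  printed_cycle_int: 0.011
  effect_duration_cycles: 13
curves:
  recovery:
    file: recovery_curve.csv
    tail_rule: hold_last
  relapse:
    file: relapse_curve.csv
    tail_rule: hold_last
costs:
  sub_ref_hc: 132.0
  sub_ref_soc: 439.0
  sub_int_hc: 139.0
  sub_int_soc: 384.0
  mde_hc: 268.0
  mde_soc: 615.0
  screen_step1: 5.0
  screen_step2: 119.0
  intervention: 423.0
weights:
  dw_sub: 0.097
  dw_mde: 0.46000000000000002
  dw_rec: 0.097
discounts:
  rate_costs: 0.04
  rate_effects: 0.015
cascade:
  n_target: 7200000.0
  f_participate_screen: 0.72499999999999998
  f_screen_positive: 0.26600000000000001
  f_interview_participate: 0.35699999999999998
  f_not_excluded: 0.59499999999999997
  f_screened_to_interview: ~
options:
  half_cycle_correction: no
psa:
  f_participate_screen:
    family: beta
    shape_a: 3826.0
    shape_b: 1452.0
    point_estimate: 0.72489579386131109
    ci_low: 0.71299999999999997
    ci_high: 0.73699999999999999
    provenance: screening uptake; printed 0.725 (0.713-0.737)
    degenerate: no
  f_screened_to_interview:
    family: beta
    shape_a: 364.0
    shape_b: 3463.0
    point_estimate: 0.09511366605696368
    ci_low: 0.08599999999999999
    ci_high: 0.105
    provenance: screened reaching diagnostic interview; printed 0.095 (0.086-0.105)
    degenerate: no
  f_not_excluded:
    family: beta
    shape_a: 217.0
    shape_b: 148.0
    point_estimate: 0.59452054794520548
    ci_low: 0.54400000000000004
    ci_high: 0.64500000000000002
    provenance: interviewed entering intervention; printed 0.595 (0.544-0.645)
    degenerate: no
  p_inc_year_ref:
    family: beta
    shape_a: 21.0
    shape_b: 90.0
    point_estimate: 0.1891891891891892
    ci_low: 0.12223341204535497
    ci_high: 0.26674033109906659
    provenance: one-year incidence, control arm counts 21/111; printed per-cycle 0.016
      (0.010-0.023)
    degenerate: no
  p_inc_year_int:
    family: beta
    shape_a: 14.0
    shape_b: 95.0
    point_estimate: 0.12844036697247707
    ci_low: 0.07271860420300265
    ci_high: 0.19703873370177682
    provenance: one-year incidence under MCP, counts 14/109; printed per-cycle 0.011
      (0.006-0.017)
    degenerate: no
  cost_sub_ref_hc:
    family: gamma
    shape_a: 14.91112461572733139
    shape_b: 8.85245099895245779
    point_estimate: 132.0
    ci_low: 73.0
    ci_high: 207.0
    provenance: health-care cost/cycle, sub-threshold, usual care; printed gamma(15,
      108)
    degenerate: no
  cost_sub_int_hc:
    family: gamma
    shape_a: 30.91359999999999886
    shape_b: 4.4964028776978413
    point_estimate: 139.0
    ci_low: 94.0
    ci_high: 192.0
    provenance: health-care cost/cycle, sub-threshold under MCP (year 1); printed
      gamma(31, 55)
    degenerate: no
  cost_sub_ref_soc:
    family: gamma
    shape_a: 13.2928216317150234
    shape_b: 33.02534346452076619
    point_estimate: 439.0
    ci_low: 219.0
    ci_high: 691.0
    provenance: societal cost/cycle, sub-threshold, usual care; printed gamma(33,
      258)
    degenerate: no
  cost_sub_int_soc:
    family: gamma
    shape_a: 7.38269714970871416
    shape_b: 52.01351108045259508
    point_estimate: 384.0
    ci_low: 138.0
    ci_high: 692.0
    provenance: societal cost/cycle, sub-threshold under MCP (year 1); printed gamma(16,
      433)
    degenerate: no
  cost_mde_hc:
    family: gamma
    shape_a: 15.25236403034783805
    shape_b: 17.57104665655479536
    point_estimate: 268.0
    ci_low: 150.0
    ci_high: 419.0
    provenance: health-care cost/cycle, major depression; printed gamma(13, 11)
    degenerate: no
  cost_mde_soc:
    family: gamma
    shape_a: 11.40055363321799398
    shape_b: 53.9447486311597757
    point_estimate: 615.0
    ci_low: 308.0
    ci_high: 1022.0
    provenance: societal cost/cycle, major depression; printed gamma(14, 26)
    degenerate: no
  qol_sub:
    family: beta
    shape_a: 106.0
    shape_b: 11.0
    point_estimate: 0.90598290598290598
    ci_low: 0.84699999999999998
    ci_high: 0.95199999999999996
    provenance: quality of life, sub-threshold depression; printed 0.906 (0.847-0.952);
      disability weight = 1 - QoL
    degenerate: no

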