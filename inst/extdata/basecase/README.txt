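Base-case parameter bundle
==========================

basecase.yaml        model parameters; load with mcpcea::load_params()
recovery_curve.csv   per-cycle recovery probability by episode duration
relapse_curve.csv    per-cycle relapse probability by time since recovery

Provenance
----------
PUBLISHED: cascade fractions (0.725 / 0.266 / 0.357 / 0.595 of a 7.2
million target population), one-year incidence betas (21/90 control,
14/95 under minimal contact psychotherapy), per-cycle state costs
(gamma, rebuilt by method of moments from printed point estimates and
95% intervals), unit costs (5 / 119 / 423 euro), disability weights
(0.46 major depression, 0.097 sub-threshold), quality-of-life beta
(106, 11), discount rates (4% costs, 1.5% effects), 13 cycles/year,
65-cycle horizon, 13-cycle intervention effect duration.

SYNTHETIC: both probability curves.  The source estimates exist only
as graphs, so the bundled curves are exponential-decay stand-ins
(recovery: 0.25 * exp(-0.10 * (k - 1)); relapse: 0.04 * exp(-0.08 *
(j - 1)); 26-cycle span, hold-last tail).  Replace them with
empirically estimated curves for substantive use.
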