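# monotol

Systems modelling of the human monocyte response to endotoxin.

Monocytes challenged with bacterial lipopolysaccharide (LPS) mount a burst
of TNF-α and then reprogram into **endotoxin tolerance (ET)** — a transient
state, prominent in sepsis, in which they respond poorly to a second
challenge while producing more CCL2. `monotol` implements a six-stock
compartmental model of this process and the estimation workflow needed to
calibrate it from monocyte-culture data, for immunologists and modellers
who want to simulate LPS-challenge experiments or quantify the tolerance
status of a sample.

## The model

Three monocyte states (resting **R**, proinflammatory **P**,
endotoxin-tolerant **E**) and three molecular stocks (LPS **L** in ng/ml,
TNF and CCL2 in pg) obey

    dR/dt = -a(L) R
    dP/dt =  a(L) R - i P
    dE/dt =  i P
    dL/dt = -k_L L
    dTNF/dt  = s(L(t)) P(t - T_D) - k_T TNF
    dCCL2/dt = c_R R + c_P P + c_E E - k_C CCL2

with Hill dose-responses for activation and per-cell TNF synthesis,

    a(L) = a_max L^n / (AC50^n + L^n),   s(L) = s_max L^m / (SC50^m + L^m),

and a discrete delay `T_D` (default 1 h) between activation and TNF output.
`model_parameters()` carries the 14 calibrated defaults. The calibration
stack covers the full published workflow: one-phase decay estimation of
activation rates from two-stimulus readouts (`fit_decay`,
`build_activation_table`), Hill regression (`fit_hill`), joint kinetic
refinement against TNF time courses (`refine_tnf_kinetics`), CCL2
parameter optimisation (`fit_ccl2_params`), and estimation of a
**tolerance index** — the percentage of cells starting in the ET state —
from observed cytokine curves (`fit_tolerance_index`). A synthetic-data
generator (`generate_timecourse`, `generate_decay_protocol`) emulates
every experimental input the estimators consume.

## Worked example

Calibrate the activation Hill function from the packaged empirical
activation-rate table, then compare a control and a tolerant culture:

```r
library(monotol)

fit_hill(read_dose_rate_csv(fixture_path("activation")))
#> Fit (converged, n = 8, SSE = 0.455923):
#>   vmax                       4.499068956
#>   c50                        0.1889079862
#>   coef                       1.482471812

ctrl <- simulate_scenario(preset("fig5_control"))  # 1e6 resting, 5 ng/ml
et   <- simulate_scenario(preset("fig5_et"))       # 0/75,000/925,000 split
max(ctrl$tnf_pg); max(et$tnf_pg)
#> [1] 21321.87
#> [1] 1773.796
ctrl$ccl2_pg[ctrl$time_h == 24]; et$ccl2_pg[et$time_h == 24]
#> [1] 14446.48
#> [1] 16223.8
```

The fitted triple is the maximum activation rate (4.499 /h), the
half-saturation LPS concentration (0.189 ng/ml) and the Hill coefficient
(1.48): half-maximal activation occurs at ~0.19 ng/ml and the curve is
mildly sigmoidal. The tolerant culture's TNF peak is ~12-fold lower than
the control's while its 24 h CCL2 is higher — the ET signature. Closing
the loop, a noisy synthetic experiment at tolerance index 68 is recovered
by the estimator:

```r
g <- generate_timecourse(preset("fig6_tolerance"),
                         noise = noise_spec(multiplicative_cv = 0.1,
                                            replicates = 3, seed = 1))
fit_tolerance_index(
  data.frame(time_h = g$summary$time_h, tnf_pg = g$summary$tnf_mean),
  data.frame(time_h = g$summary$time_h, ccl2_pg = g$summary$ccl2_mean)
)$estimates
#> tolerance_index
#>        68.06516
```

A command-line interface wraps the same functions
(`inst/cli/monotol.R simulate --preset fig5_et --out et.csv`, plus
`fit-hill`, `fit-decay`, `calibrate-tnf`, `calibrate-ccl2`,
`fit-tolerance`, `synth`). See the vignette
(`vignettes/monocyte-endotoxin-model.Rmd`) for the model's assumptions,
numerical choices and limitations.

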