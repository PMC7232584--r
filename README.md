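# dopabuff

Simulation and estimation toolkit for **levodopa phMRI hysteresis
mapping** — a proposed imaging biomarker of Parkinson disease (PD)
severity based on dopamine buffering capacity.

## The problem

The benefit of a levodopa dose wears off faster as PD progresses, as if a
central reservoir that buffers dopamine were becoming leakier. In
effect-compartment PK-PD modelling this leakiness is a single number, the
effect-site rate constant *k*<sub>e</sub> (equivalently the equilibration
half-life *t*<sub>½e</sub> = ln 2 / *k*<sub>e</sub>), and it correlates
with disease severity. Clinical estimates of *k*<sub>e</sub> (tapping
speed, UPDRS) are confounded by fatigue and motivation; a regional brain
signal — the rCBF response to levodopa measured with ASL perfusion MRI —
could provide an objective alternative, simultaneously in every
levodopa-responsive region.

This package implements the feasibility-simulation machinery for that
idea, for PK-PD modellers and imaging methodologists:

* **Infusion regimen** — the i.v. loading + maintenance protocol
  (0.6426 mg/kg over 10 min, then 2.882×10⁻⁵ mg/kg/min × (140 − age)),
  including the dose-conserving stretched variant (twice as long at half
  the rate).
* **Plasma generation** — a two-compartment disposition model calibrated
  to the protocol's published targets (600 ng/mL maintenance steady
  state; 1,500–3,500 ng/mL transient peak), with high/low scenarios for
  between-subject PK variability.
* **Effect compartment** — the closed-form solution of
  *C*<sub>e</sub>′ = *k*<sub>e</sub>(*C*<sub>p</sub> − *C*<sub>e</sub>)
  for piecewise-linear *C*<sub>p</sub>(*t*), plus an independent RK4
  oracle used in tests.
* **Response model** — sigmoid E<sub>max</sub>:
  *E* = *E*₀ + *E*<sub>max</sub>·*C*<sub>e</sub>ⁿ / (EC₅₀ⁿ + *C*<sub>e</sub>ⁿ),
  with baseline CBF 50 ml/hg/min and maximal increment 35 ml/hg/min
  (a ~70% rCBF increase).
* **Acquisition** — 34-s CBF frames with Gaussian noise at a specified
  coefficient of variation (12.9% default, 5% comparison).
* **Estimation** — simultaneous recovery of (*k*<sub>e</sub>, EC₅₀, *n*)
  by a global grid/multistart search followed by Metropolis posterior
  sampling, with identifiability flagging.
* **Recovery study** — the full severity × plasma-scenario × noise ×
  duration grid with 5/50/95 percentile summaries.

## Worked example

```r
library(dopabuff)

reg <- build_regimen(weight_kg = 70, age_yr = 65)
reg
#> <infusion_regimen> 70 kg, 65 yr: 44.98 mg over 10 min, then
#>   0.1513 mg/min to 150 min (total 66.16 mg)

plasma <- simulate_plasma(reg)        # calibrated mean-scenario Cp(t)
plasma
#> <plasma_curve> 181 knots on [0, 180] min, C in [0, 2984] ng/mL

preset <- severity_presets()[[4]]     # Hoehn & Yahr III analog
preset$params
#> <pd_params> e0 = 50, emax = 35 ml/hg/min; ec50 = 884.054 ng/mL;
#>   n = 5.6; ke = 0.027826 /min (t1/2e = 24.91 min)

frames    <- frame_grid(0, 180, frame_duration_s = 34)
noiseless <- predict_time_effect(plasma, preset$params, frames)
observed  <- add_noise(noiseless, cov = 0.129, seed = 7)

fit <- fit_pkpd(plasma, observed, seed = 7)
fit
#> <fit_result> ke = 0.027619 /min (t1/2e = 25.1 min), ec50 = 868 ng/mL,
#>   n = 5.72
#>   SSR = 18117.6, converged
```

The true *t*<sub>½e</sub> of 24.9 min is recovered as 25.1 min from a
noisy 317-frame series — a 0.7% error at the realistic 12.9% noise level.
`fit$uncertainty` holds 5/50/95 posterior percentiles per parameter.

The full parameter-recovery study (severity × scenario × noise ×
duration grid, scaled down to 20 noise realizations per cell):

```r
res  <- run_recovery(study_config())
summ <- summarize_recovery(res)
```

`summ` has one row per cell with truth, percentiles of each estimate and
the fraction of fits flagged non-identifiable. At CoV 12.9% under mean
plasma levels the *k*<sub>e</sub> spread shrinks monotonically from the
mildest preset (median 0.0042 vs truth 0.0025 /min, wide) to the most
severe (median 0.1385 vs truth 0.1386 /min, tight), and every preset
tightens further at CoV 5% — more advanced disease and less noise both
sharpen the estimate.

## Command line

```sh
exec/dopabuff regimen  --weight 70 --age 65
exec/dopabuff simulate --weight 70 --age 65 --out-dir out/
exec/dopabuff noise    --in out/effect_HY-III.csv --cov 0.129 --seed 1 --out noisy.csv
exec/dopabuff fit      --plasma out/plasma.csv --effect noisy.csv --out fit.json
exec/dopabuff recover  --out-dir study/   # full recovery study
```

Time series are 2-column CSV (`time_min`, value); configs and results are
JSON.

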