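# hemobia

Bioimpedance and hemodynamic analysis of controlled hemorrhage and fluid
resuscitation experiments, with a fluid-kinetics simulator for generating
synthetic swine cohorts.

## What problem this addresses

In hypovolemic shock the choice of resuscitation fluid matters: balanced
crystalloid distributes through the extracellular space, 5% dextrose water
ends up two-thirds intracellular once its glucose is metabolized, and
concentrated (20%) albumin expands plasma beyond its own volume — and, when
it leaks through a shock-injured endothelium, draws intracellular water
outward. Segmental multifrequency bioelectrical impedance analysis (BIA)
can track these compartment shifts non-invasively: low-frequency current is
confined to extracellular water, high-frequency current samples total body
water, so impedance rises during hemorrhage and falls during infusion, and
the pair

```
x = |Z(5 kHz)|          (extracellular water)
y = |Z(5 kHz)| / |Z(1 MHz)|   (carries the intracellular impedance)
```

plotted over time is a straight line when intracellular water is constant
and a curved path when it changes. `hemobia` implements this analysis chain
for researchers working with segmental BIA in resuscitation experiments:

- **protocol** — the three-phase design (1 L bleed over 60 min, two 1 L
  infusion phases) with the three fluid arms, as a queryable object;
- **simulator** — a three-pool (plasma / interstitial / intracellular)
  fluid-kinetics model with Cole-model impedance mapping and a
  volume-driven hemodynamic model (PR, MAP, SV, SVV with
  undetectable-waveform missingness), generating noisy per-subject
  impedance and vitals tables with ground truth;
- **pipeline** — z-score standardization, group median ± IQR curves
  (Gaussian-ML location, linear-interpolation percentiles), interpolating
  B-spline smoothing, the x/y trajectory with a total-least-squares
  curvature classifier, and detection of the time at which 1 MHz impedance
  recovers its baseline (restoration of total body water);
- **statistics** — endpoint extraction at the five analysis timepoints,
  Jarque–Bera normality, pointwise two-sample t-tests, percent changes,
  the ΔSV ≥ 10% fluid-responsiveness rule, and per-variable "restored"
  flags.

The methods vignette (`vignettes/fluid-kinetics-bioimpedance.Rmd`) gives
the model equations, parameter defaults with rationale, and limitations.

## Worked example

```r
library(hemobia)

ds <- generate_dataset(n_subjects = 5, group = "crystalloid_albumin", seed = 1)

curve_1m <- impedance_group_curve(ds$impedance, frequency_khz = 1000)
recovery_time(curve_1m, infusion_start = 60)
#> [1] 82.2

traj <- impedance_trajectory(ds$impedance, window = "resus")
curvature_statistic(traj)
#> $score    0.000957
#> $label    "curved"

ep  <- extract_endpoints(ds$vitals, ds$protocol, recovery_minute = 82.2)
endpoint_comparison_report(ep)
#> Endpoint comparisons (alpha = 0.05)
#>  variable                 pair        t         p percent_change significant
#>       MAP start-end_hemorrhage  16.1989 2.120e-07         45.706        TRUE
#>       MAP   start-end_infusion  -0.8705 4.094e-01         -1.597       FALSE
#>       SV  start-end_hemorrhage  24.7315 7.636e-09         47.993        TRUE
#>       SV    start-end_infusion   1.1928 2.671e-01          2.489       FALSE
#>  ... (20 comparisons in total)
#> Restored at end of infusion:
#>   PR   yes
#>   MAP  yes
#>   SV   yes
#>   SVV  yes
```

Reading: in the albumin arm, MAP fell 45.7% during the hemorrhage
(p ≈ 2e-7) but the start-vs-end-of-infusion difference is non-significant
(−1.6%, p = 0.41) — MAP and SV are *restored*. Rerunning with
`group = "crystalloid"` leaves the start-vs-end comparisons significant
and the restored flags false; the trajectory curvature label is `linear`
for the crystalloid arm and `curved` for the dextrose and albumin arms on
noise-free curves. The 1 MHz impedance recovers its baseline at 82 min,
inside the resuscitation window.

`run_pipeline(run_config(out_dir = "out", seed = 1))` runs all three arms
end to end and writes `group_curves.csv`, `trajectory.csv`,
`recovery.json`, `curvature.json`, `endpoints.csv`, `comparisons.csv`,
`report.json` and a hash manifest; `inst/scripts/hemobia.R` wraps this as
a command line (`simulate` / `analyze` / `run`).

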