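# sclcgrowth

Growth kinetics of peripheral small-cell lung cancer (SCLC) — and solid
pulmonary nodules generally — from serial CT measurements.

Peripheral SCLC presents as a rapidly growing solid nodule; whether an
incidental nodule's growth is fast enough to raise suspicion is judged
from its **volume-doubling time** (VDT) over follow-up scans. This
package implements a complete, testable analysis pipeline for that
question, aimed at radiology/biostatistics researchers studying nodule
growth:

* **Dual-method VDT.** The calliper ("manual") method from three
  orthogonal diameters,

  VDT = ln2 · ΔT / ln[(X₂·Y₂·Z₂)/(X₁·Y₁·Z₁)],

  and the segmentation ("ROI") method via the modified Schwartz
  equation, VDT = t·log2 / log(V₂/V₁), applied to the first and last
  scans of each series. Growth rate is GR = 1/VDT (doublings/day).
* **Growth-curve models.** Log-linear exponential fits and Gompertz
  fits, V(t) = V∞·exp{ln(V₀/V∞)·e^(−kt)}, with pattern classification
  (exponential-like vs Gompertz-like) from log-scale curvature.
* **Volumetry.** Label-mask voxel counting with nearest-neighbour
  isotropic resampling (default 0.5 mm), plus digital ellipsoid
  phantoms with analytic oracles.
* **Cohort statistics.** ICC method agreement from two-way ANOVA mean
  squares, Mann–Whitney/t group comparisons with a Shapiro–Wilk gate,
  Spearman correlations, univariate logistic screens of fast vs slow
  growers (cut-off 60 days), and de-novo lesion reports.
* **Synthetic cohorts.** A seeded generator of serial-CT cohorts with
  latent exponential/Gompertz trajectories and multiplicative
  measurement noise, providing exact ground truth for every estimator.

## Worked example

```r
library(sclcgrowth)

# a three-scan patient: volumes 630.5 / 2490.9 / 3895.75 mm^3
scans <- data.frame(
  scan_date    = c("2021-02-20", "2021-07-23", "2021-08-26"),
  voxel_volume = c(630.5, 2490.9, 3895.75))
series_vdt(scans, method = "volume")
#> VDT (volume method): 71.2 days  [GR = 0.014 /day, over 187 days]

# an end-to-end synthetic cohort of 27 patients
run <- run_pipeline(pipeline_config(
  sim_config = cohort_config(n_patients = 27),
  output_dir = "demo-run", seed = 1, verbosity = 0))
run$summary
#> Cohort growth summary (27 patients):
#>   diameter method: median VDT 74 days (IQR 55-92), GR 0.0161 +/- 0.0109 /day (n=27)
#>   volume method  : median VDT 69 days (IQR 54-82), GR 0.0176 +/- 0.0106 /day (n=27)
#>   method agreement: ICC 0.84 (VDT), 0.92 (GR)
#>   fast (< 60 d) / slow: 7 / 19
```

The VDT of 71.2 days means the lesion doubled in volume roughly every
ten weeks; anything under ~60 days puts a patient in the fast-growing
group. In the simulated cohort the two measurement methods agree
strongly (ICC 0.84 on VDT, computed over patients growing by both
methods), mirroring what dual-method studies of real cohorts report.

A command-line front end with `simulate`, `measure`, `fit`,
`summarize` and `run-all` subcommands is installed at
`system.file("cli", "sclcgrowth.R", package = "sclcgrowth")`.

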