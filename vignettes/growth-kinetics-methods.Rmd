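---
title: "Methods: doubling-time estimation and growth-curve analysis of pulmonary nodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: doubling-time estimation and growth-curve analysis of pulmonary nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sclcgrowth)
```

This vignette is the package's account of its methods: the measurement
models, the statistical procedures, the synthetic-data generator that
stands in for patient data, and the design decisions taken where more
than one defensible choice existed.

## The measurement problem

A solid pulmonary nodule followed over two or more CT scans yields a
growth signal from which malignancy and aggressiveness are judged. The
standard kinetic index is the volume-doubling time (VDT): the number of
days the lesion needs to double in volume, under the assumption of
exponential growth between the two observations. Small-cell lung cancer
is among the fastest-growing lung tumours (VDTs near two months), so
accurate, reproducible VDT estimation matters for deciding how soon to
re-scan a suspicious nodule.

Two measurement routes are in clinical use, and the package implements
both so their agreement can be quantified:

* **Diameter (calliper) route.** The maximal axial diameter $X$, its
  in-plane perpendicular $Y$, and the cranio-caudal diameter $Z$ are
  measured with a calliper. Treating the lesion as an ellipsoid,
  volume is proportional to $XYZ$ and

  $$\mathrm{VDT} = \frac{\ln 2 \cdot \Delta T}
    {\ln\!\big( X_2 Y_2 Z_2 / X_1 Y_1 Z_1 \big)},$$

  where $\Delta T$ is the exact calendar-day interval. The ellipsoid
  constant $\pi/6$ cancels in the ratio, so the method needs no shape
  assumption beyond proportionality.
* **Volume (segmentation) route.** The lesion is contoured on images
  resampled to isotropic 0.5 mm voxels; the volume is the foreground
  voxel count times the single-voxel volume. VDT follows from the
  modified Schwartz equation $\mathrm{VDT} = t \cdot \log 2 /
  \log(V_2/V_1)$ (any logarithm base, since only the ratio of logs
  enters).

For a patient with three or more scans, both formulas use the **first
and last** scans; intermediate scans feed the growth-curve analysis
instead. Growth rate is reported as $\mathrm{GR} = 1/\mathrm{VDT}$
(doublings per day), rounded to four decimals in human-readable output
while full precision is kept internally.

Two conventions are worth stating explicitly:

* **Fast/slow boundary.** Patients are dichotomised at a VDT cut-off
  of 60 days; the boundary value itself is classified *slow*
  (`vdt >= cutoff`), matching the usual "greater than or equal to the
  cut-off" phrasing for slow growers. The cut-off is a parameter
  everywhere it appears.
* **Negative VDT.** A measured shrinkage gives a negative VDT. Cohorts
  of untreated cancer should contain none, but measurement noise can
  produce one; such values are returned with a `negative_vdt` flag
  rather than raising, so a single artifact cannot crash a pipeline
  run. Downstream, agreement statistics are computed over patients
  measured as growing by **both** methods: one spurious negative VDT
  (a large-magnitude outlier by construction) otherwise dominates the
  ICC variance components and turns an informative coefficient into
  noise.

## Growth-curve models and pattern classification

Patients with at least three volume measurements get two model fits,
both in **log-volume space** — the natural scale under multiplicative
measurement error, and the scale on which clinicians read growth
curves (exponential growth is a straight line):

* **Exponential:** OLS of $\ln V$ on $t$; $k$ is the slope, implied
  VDT $= \ln 2 / k$.
* **Gompertz:** $\ln V(t) = \ln V_\infty + \ln(V_0/V_\infty)
  e^{-kt}$, fitted by Levenberg–Marquardt with multi-start
  initialisation ($k$ from the exponential slope; carrying volume from
  $\{2, 5, 20\} \times$ the largest observed volume). The model
  describes growth whose specific rate decays exponentially, producing
  a plateau at the carrying volume $V_\infty$.

In log space every Gompertz curve is concave, and the straight line is
its $k \to 0$ boundary. On data with no log-scale deceleration the
Gompertz SSE therefore has no interior minimum below the exponential
SSE; the fit "runs away" toward an enormous carrying volume. The
package treats this boundary explicitly: when no interior optimum beats
the straight line, `fit_gompertz()` returns the exponential-limit
solution (criterion equal to the exponential SSE, very large
$V_\infty$) flagged `degenerate_exponential_limit`. This makes the
nested-model property — Gompertz SSE never worse than exponential SSE —
hold exactly, and is the honest reading of a boundary optimum rather
than a convergence failure.

**Pattern classification.** Series are labelled by the sign of the
log-scale curvature: per-interval specific growth rates
$r_i = \Delta \ln V / \Delta t$ are differenced across interval
midpoints, giving second differences of $\ln V$ in day$^{-2}$. All
second differences below $-10^{-6}$/day$^2$ → *gompertz-like*
(decelerating); none below → *exponential-like* (steady or
accelerating); mixed → *indeterminate*. The $10^{-6}$ tolerance guards
against floating-point noise, not measurement noise. A
small-sample-corrected AIC comparison of the two fits is consulted as
a cross-check only when it is defined — the correction term
$2k(k+1)/(n-k-1)$ requires $n \ge 6$ points for the four-parameter
Gompertz likelihood, which follow-up series of three or four scans
never reach — so at clinical series lengths the curvature rule decides
alone.

**Limitation, stated plainly.** With three noisy points the curvature
sign carries very little information: at a realistic 10% volume CV the
second difference of $\ln V$ has a noise standard deviation far above
the deceleration signal of a moderately Gompertzian tumour, so labels
on individual short noisy series should be read as descriptive of the
observed curvature, not as reliable model identification. The
package's tests therefore validate the classifier where it is
identifiable — noise-free mixed cohorts (labels track the generating
model and recover the configured exponential:Gompertz mix) and noisy
cohorts with strong deceleration (majority correctly labelled) — and
the vignette records that no rule can do materially better at $n = 3$
without replicate measurements.

## Volumetry

Label masks are 3-D binary rasters with explicit per-axis spacing
(mm). Volume is foreground count × single-voxel volume; disconnected
components all count. Resampling to the 0.5 mm isotropic analysis grid
uses **nearest-neighbour** interpolation — the only interpolator that
keeps a label image binary without a thresholding convention — with
voxel centres at $(i - \tfrac12) \cdot s$. Digital ellipsoid phantoms
(centre-inclusion rasterisation) provide analytic oracles: at 0.5 mm
and semi-axes ≥ 4 mm the discretisation error is under 2%, and
resampling is idempotent to under 0.5%. Masks travel as NIfTI (spacing
in the header) or as a plain-text JSON format (dims, spacing,
foreground indices) for fully text-based pipelines.

## Cohort statistics

* **Method agreement:** single-measure ICC from the classical two-way
  mean squares. The default is the absolute-agreement form ICC(A,1),
  the stricter and conventional choice for method comparison (it
  penalises a systematic offset between methods); the consistency form
  ICC(C,1) is exposed alongside.
* **Group comparisons:** Shapiro–Wilk at $\alpha = 0.05$ on each group
  gates a two-sample $t$ test (both normal-looking) versus a
  two-sided Mann–Whitney U (exact for small tie-free samples, normal
  approximation with tie correction otherwise). The gate is a
  documented surrogate: "normality assessed by $t$ tests" is not an
  actionable prescription, and Shapiro–Wilk is the standard small-$n$
  normality test. Single-member groups (rare covariate categories) are
  computed but flagged low-power.
* **Correlations:** Spearman's rank $\rho$ with average ranks and a
  two-sided asymptotic $p$.
* **Univariate speed analysis:** per-covariate single-predictor
  logistic regression of fast vs slow with Wald odds ratios; complete
  or quasi-complete separation (or any zero cell) triggers a flagged
  Fisher's-exact fallback. No multiplicity correction is applied —
  raw $p$-values are reported, and the output says so.
* **Summaries:** medians and IQRs use type-7 (linear-interpolation)
  quantiles, the R default, so printed intervals are reproducible from
  the per-patient table.

## The synthetic cohort generator

No patient-level data ship with the package; the generator emulates
the structure the analysis assumes, with exact ground truth:

* **Kinetics.** True VDT is lognormal with median 61 days and
  log-scale SD 0.53 — the SD is calibrated so the implied IQR
  (51–104 days around a 61-day median: $\ln(104/51)/(2 \times 0.6745)
  \approx 0.53$) matches a surgical peripheral-SCLC cohort. A
  configurable fraction (default 25%) of patients get Gompertz
  trajectories; for these, the Gompertz decay rate is set so the
  *initial* doubling time equals the drawn VDT
  ($k = \ln 2 / (\mathrm{VDT} \cdot \ln(V_\infty/V_0))$), with the
  carrying volume 10–50× baseline (log-uniform) — deep enough into the
  decelerating regime to be visible over a few-month follow-up.
* **Schedules.** 2, 3 or 4 scans per patient with probabilities
  19/27, 7/27, 1/27 (so a 27-patient cohort centres on 63 scans);
  inter-scan gaps uniform on [20, 180] days, honouring the 20-day
  minimum-interval inclusion rule; baseline dates uniform over
  2015–2022.
* **Measurements.** Baseline volumes log-uniform on 200–6000 mm³.
  Diameters and volume are tied by the ellipsoid identity
  $V = \pi/6 \cdot XYZ$ with per-patient axis-ratio shape factors;
  each axis and the volume get independent multiplicative lognormal
  noise with unit mean (CV defaults: 5% diameters, 10% volume —
  plausible repeat-CT variability; these are conventions of the
  generator, not estimates from data). If noise swaps the in-plane
  axes, the larger is relabelled maximal, as a human measurer would;
  products are unaffected.
* **Covariates** are drawn independently of kinetics with fixed
  marginal frequencies (mostly male smokers, pleural retraction rare,
  etc.), so the univariate screen is null by construction and its
  type-I error can be verified.
* **Determinism.** One integer seed drives a single R RNG stream in a
  documented order (kinetics, shapes, schedules, covariates, then
  per-patient noise); identical configs give byte-identical cohorts.

What the generator does **not** emulate: partial-volume and
slice-thickness effects (noise is scale-free lognormal, real
volumetric error grows as lesions shrink relative to the voxel),
correlated errors between the two methods (a reader measuring both
would not err independently), covariates linked to growth, treatment
effects, or regression. Passing tests on synthetic cohorts therefore
demonstrate estimator correctness under the stated noise model, not
clinical performance on real images.

## Numerical choices and degenerate inputs

* Calendar arithmetic uses R's `Date` (proleptic Gregorian), so leap
  years are exact; a lenient `"26 March 2018"` parser covers
  clinical-table dates, locale-independently.
* Equal volumes (or equal diameter products) make the doubling-time
  ratio undefined; this raises a "no measurable growth" error rather
  than returning ±Inf.
* A zero exponential slope is flagged `zero_growth` with implied VDT
  `Inf`.
* Gompertz non-convergence from every start is flagged
  `non_converged`, never an uncaught failure; ties between interior
  and boundary optima (within $10^{-12}$) resolve to the boundary.
* Problem sizes in the test-suite simulations (500 two-scan patients
  for noise recovery, 200 four-scan patients for Gompertz recovery,
  1500 for the median check) are chosen so Monte-Carlo standard errors
  are several times smaller than the asserted tolerances.

## Known limitations

* The exponential/Gompertz pattern label is information-limited at 3–4
  noisy points (discussed above).
* VDT from two scans inherits the exponential-interpolation
  assumption; for a truly Gompertzian tumour the first/last-scan VDT
  is a weighted average of a changing instantaneous doubling time.
* The ICC is reported in its ICC(A,1) form; other published "alpha"
  agreement coefficients (e.g. Krippendorff's) are not computed, and
  on small cohorts different agreement forms can differ noticeably.
* Short inter-scan gaps combined with slow growth give weak signals
  ($\ln$ ratio comparable to noise), producing heavy-tailed VDT
  errors; the generator includes such cases on purpose, and summaries
  built on them (e.g. raw-scale ICC at $n = 27$) vary considerably
  between seeds.
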