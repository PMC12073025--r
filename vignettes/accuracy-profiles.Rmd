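---
title: "Accuracy profiles and total-error validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accuracy profiles and total-error validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accuprofile)
```

# The problem

A quantitative LC-MS/MS assay reports a concentration for every sample it
measures, and a validation campaign has to answer one question: how far can
a *single future measurement* be from the true concentration? The
total-error framework answers it directly. For each concentration level of
the validated range, replicate QC measurements are collected over several
days, the systematic error (bias) and the random error (within- and
between-day variability) are estimated, and the two are combined into a
**β-expectation tolerance interval** — an interval expected to contain a
fraction β of future individual measurements. Plotting these intervals
against acceptance limits ±λ across the range gives the **accuracy
profile**; the assay is fit for purpose over the region where the profile
stays inside the corridor, and the lowest such level is the lower limit of
quantification (LLOQ).

`accuprofile` implements this framework end to end for multiplexed assays:
calibration modelling with inverse prediction, variance components,
tolerance intervals, accuracy profiles, expanded measurement uncertainty,
and the surrounding acceptance checks (selectivity, crosstalk, carryover,
matrix effect, stability, freeze-thaw, dilution integrity, inter-laboratory
comparison, signal-to-noise). The shipped worked example is a
therapeutic-drug-monitoring panel of four CFTR modulators (ivacaftor,
lumacaftor, tezacaftor, elexacaftor) and three active metabolites in plasma,
with six calibrator levels in duplicate and five validation QC levels
measured in triplicate on three days per analyte.

# The statistical model

Back-calculated QC concentrations at one level, expressed as percent of
nominal, follow a one-way random-effects layout over `p` days with `n`
replicates per day:

$$x_{ij} = \mu + \alpha_i + \varepsilon_{ij}, \qquad
  \alpha_i \sim N(0, \sigma_B^2), \quad
  \varepsilon_{ij} \sim N(0, \sigma_W^2).$$

Method-of-moments estimates come from the ANOVA mean squares:
$\hat\sigma_W^2 = MS_W$ and
$\hat\sigma_B^2 = \max\!\big(0, (MS_B - MS_W)/n\big)$ — the negative-moment
case is clamped to zero, the standard repair that keeps the variance ratio
nonnegative. Repeatability is $\hat\sigma_W$, intermediate precision
$\hat\sigma_{IP} = \sqrt{\hat\sigma_W^2 + \hat\sigma_B^2}$, both reported as
CV% of nominal (the unit validation reports print; absolute-scale variants
are derivable but not reported).

The β-expectation tolerance interval is the Mee-type construction used by
the SFSTP accuracy-profile guidance. With
$R = \hat\sigma_B^2/\hat\sigma_W^2$ and $B^2 = (R+1)/(nR+1)$,

$$\text{bias} \pm t_{\nu,\,(1+\beta)/2}\;
  \sqrt{1 + \frac{1}{p\,n\,B^2}}\; \hat\sigma_{IP},$$

with Satterthwaite degrees of freedom

$$\nu = \frac{(R+1)^2}{\dfrac{(R + 1/n)^2}{p-1} + \dfrac{1 - 1/n}{p\,n}}.$$

Degenerate corners are handled explicitly: both components zero collapses
the interval to the bias; a zero within-day component uses the limits
$B^2 \to 1/n$, $\nu \to p - 1$. When the between-day component vanishes the
construction is numerically close to the classical one-sample tolerance
form with $pn - 1$ degrees of freedom (the half-widths agree within about
1% for the default design) — close, not identical, because the Satterthwaite
formula does not reduce to $pn-1$ exactly at $R = 0$.

The interval construction is *verified by simulation*, not assumed: the
test suite and the acceptance script draw 10,000 balanced datasets, compute
each dataset's interval, draw one new observation from the same model and
count how often it falls inside. Coverage lands within two percentage
points of β at both β = 0.80 and β = 0.95 for the default design; the
slight conservatism (≈ +1.5 points at β = 0.80) is the known finite-`p`
behavior of moment estimators with clamping, and we report it rather than
recalibrating the multiplier.

**Measurement uncertainty.** The expanded uncertainty attached to a
reported concentration is the half-width of the same interval evaluated at
the MU coverage (default β = 0.95). It is reported separately from the
±x column a validation report may print next to trueness, because the
equivalence of the two is a convention that differs between laboratories.

**Two β values.** Profiles default to β = 0.80 and uncertainty to β = 0.95,
both overridable in `validation_config()`. Published accuracy profiles are
not consistent about which β the plotted interval uses — figure captions at
β = 0.95 with a stated profile β of 0.80 occur in practice — so the choice
is deliberately configuration, not a constant.

# Calibration

The response model is fitted by weighted least squares of the (optionally
log-transformed) analyte/IS response ratio on the (optionally
log-transformed) nominal concentration:
$\log r = a + b \log C + c (\log C)^2$ for the quadratic log-log family.
Logs are natural; fit quality is base-invariant, and the coefficients are
documented as natural-log quantities. Under the log-log transform the
default weighting is unit weighting — the transform itself stabilizes the
multiplicative variance typical of MS responses — while raw-scale fits
support $1/x$ and $1/x^2$ weights.

Inverse prediction solves the quadratic exactly with the numerically stable
root form (the naive quadratic formula loses all precision when the fitted
curvature is ~1e-16, which is exactly what happens when a truly linear
dataset is fitted by the quadratic family). The root inside
$[0.5 \times \text{lowest level}, 2 \times \text{highest level}]$ is
returned; no root in the window is an out-of-range error, and two roots in
the window is an ambiguity error that is reported, never silently resolved.
Back-calculated calibrator deviations are reported but calibrators are
never dropped automatically — curation is the analyst's decision, flagged
rather than automated.

**Model selection.** Candidates are ranked by (1) the lowest achievable
LLOQ, then (2) the narrowest mean *total-error envelope* of the per-level
tolerance intervals, $\text{mean}_\ell \max(|\text{low}_\ell|,
|\text{high}_\ell|) = |\text{bias}| + \text{half-width}$, then (3) the
fewest parameters. The envelope rather than the bare interval width is used
in step (2) deliberately: width excludes bias, and a misspecified
straight-line model can produce tight but badly displaced intervals that
would otherwise outrank the correct curved model while both clear the
generous ±30% corridor. For unbiased candidates the envelope equals the
half-width, and exact ties (e.g. both families fitted to noise-free linear
data) still fall through to parsimony.

# LLOQ, LOD and the acceptance checks

The LLOQ is the smallest *validated level* whose tolerance interval lies
entirely within ±λ, provided every higher level also passes; no
interpolation between levels is performed, so a failing lowest level moves
the LLOQ up to the next validated concentration. If no level qualifies the
result is an explicit no-valid-LLOQ sentinel (`NA`), not an error. The LOD
comes from a serial dilution of the lowest calibrator: the smallest
concentration in the series whose signal-to-noise ratio still meets the
configured minimum (default 3). S/N is baseline-SD based —
`(peak maximum − baseline mean) / baseline SD` — which matches the
"signal k times the background noise" arithmetic directly; the peak maximum
is taken from a lightly smoothed trace (5-point moving average when the
sampling density permits) because the raw maximum rides the upper tail of
the noise and biases S/N upward by ~15% at realistic sampling densities.

Boundary semantics across the checks follow the wording of the governing
guidelines: inclusive for every ≤-type criterion (crosstalk 20%/5%,
carryover, and the ±15% matrix/stability/dilution/ILC limits), strict for
selectivity, whose limits are phrased as "< 20%" and "< 5%". Verdicts are
taken on statistics rounded at 1e-9 so that an intended deviation of
exactly 15% is not tipped over the limit by floating-point representation.
The carryover limit defaults to 20% of CAL1 (the harmonized guideline
criterion); a stricter achieved value like 15% is a result, not a limit,
and the threshold is configurable. Stability deviations are computed
against the *nominal* concentration (the t = 0 target), not the measured
t = 0 mean; freeze-thaw deviations, by contrast, are against the measured
cycle-0 reference, as the cycles are a paired comparison. The
inter-laboratory check treats the home laboratory as the reference with
bias = (external − home)/home.

# The synthetic-data generator

Every stage is testable without instrument data because the generator
produces datasets with known ground truth under the study design it
emulates: per analyte, six calibrator levels in duplicate and five QC
levels × `p` days × `n` replicates. Noise is applied on the concentration
scale —

$$C_{\text{meas}} = C_{\text{nom}} (1 + \text{bias})
  (1 + \gamma_{\text{day}} + \varepsilon), \qquad
  \gamma \sim N(0, s_B), \; \varepsilon \sim N(0, s_W)$$

— and then mapped through the response model to peak areas with the IS area
held constant. This makes the generating SDs directly interpretable as CV%
and keeps recovery tests sharp (note that with a nonzero bias the generated
spread, expressed as CV% of *nominal*, is $(1+\text{bias}) \cdot s$; the
parameter-recovery tests compare on that scale, and aggregate spread
estimates on the variance scale, where the moment estimator is unbiased —
the plain mean of a square-root estimator with two between-day degrees of
freedom is ~10% low by Jensen's inequality, an estimator property, not an
implementation defect). Day effects are drawn once per day and analyte and
shared across levels — a common run effect, which is what makes the
between-day component identifiable from a three-day design — scaled by the
level-specific between-day CV.

The default truth mirrors the shipped caftor panel: per-level CVs decrease
from 4.5%/4.0% (within/between) at the lowest level to 3.0%/2.2% at the
highest, with biases within ±3% — inside the precision ranges the panel's
printed validation summary reports (repeatability 1.1–8.1%, intermediate
precision 1.3–10.9%). The response curvature is c = −0.04, sized so that a
straight line on the log-log scale misfits by roughly 10–20% at the
extremes of a hundred-fold range: the regime in which a quadratic term is
genuinely warranted, which is the situation the fixture is meant to
emulate. Calibrators carry residual noise at the mean within-day CV on a
single day; whether duplicate calibrators span days is left open by typical
run sheets, and the reader accepts either layout.

What the generator does *not* emulate: chromatographic drift and injection
order effects, co-elution and in-source fragmentation, heavy-tailed or
correlated residuals, and lot-by-analyte interaction beyond a multiplicative
factor per channel. Passing recovery tests therefore demonstrate the
statistics are computed correctly, not that any real assay meets its
acceptance criteria.

# Numerical choices and scale

Concentrations are µg/mL internally; readers accept ng/mL rows through an
explicit unit column (×10⁻³) because published concentration tables mix the
two. Day and replicate indices are 1-based, matching run sheets. Designs
are assumed balanced; mild imbalance is flagged with a warning and handled
with the mean group size (REML components for seriously unbalanced designs
are out of scope). Problem sizes in the test suite — 10,000 Monte-Carlo
datasets for coverage, 2,000 replicates for parameter recovery, a 10⁶-point
two-stage grid for the inversion oracle — were chosen as the smallest sizes
at which the Monte-Carlo error is comfortably below the asserted
tolerances.

# Worked example

A complete campaign from a single seed:

```{r example, eval = FALSE}
report <- run_validation(seed = 42)
report$summary
report$analytes$ELX$profile
```

And the reconstruction path used when only printed summary statistics are
available (the per-level trueness/repeatability/intermediate-precision
block of a published validation report):

```{r reconstruct, eval = FALSE}
block <- caftor_validation_summary()
profiles <- profiles_from_summary(block, design = list(p = 3, n = 3))
profiles$ELX_M23      # lowest level fails; LLOQ moves to 0.3 ug/mL
report_ranges(block)  # headline trueness / precision ranges
```

# Known limitations

* Balanced method-of-moments variance components only; unbalanced designs
  are flagged, not modelled.
* The LLOQ is restricted to validated levels; a profile crossing between
  levels is not interpolated.
* Tolerance intervals are frequentist β-expectation intervals;
  β-content/γ-confidence and Bayesian variants are not implemented.
* The generator's lot effects are multiplicative per channel; ionization
  suppression that varies across a chromatographic run is out of scope.
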