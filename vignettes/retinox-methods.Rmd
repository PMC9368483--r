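---
title: "Quantifying retinal hemodynamics and oxygen metrics: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal hemodynamics and oxygen metrics: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinox)
```

## The measurement chain

`retinox` implements the quantification chain used in two-group preclinical
studies of retinal vascular physiology — wild-type versus 5XFAD transgenic
mice being the motivating design — from raw-style measurement signals to
per-eye hemodynamic, oxygen and morphometric metrics, and on to the cohort
statistics. Because such studies rarely deposit raw animal data, the package
pairs the measurement chain with a calibrated synthetic-cohort generator, so
every estimator can be validated end-to-end against known truth.

### Phosphorescence lifetime oximetry

Vascular oxygen tension is measured by phosphorescence quenching of an
intravascular Pd-porphyrin probe. In the frequency domain, emission under
modulated excitation at $f_{mod}$ lags by a phase $\varphi$ determined by
the lifetime $\tau$:

$$\varphi = \arctan(2\pi f_{mod}\,\tau), \qquad
  \tau = \frac{\tan\varphi}{2\pi f_{mod}}.$$

`estimateLifetime()` recovers $\varphi$ by linear least squares on cosine and
sine regressors at $f_{mod}$; the sampled sinusoid lies exactly in the span
of the regressors, so the noiseless fit is exact regardless of the sampling
grid. The Stern–Volmer quenching relation then converts lifetime to oxygen
tension,

$$\frac{1}{\tau} = \frac{1}{\tau_0} + k_q\,\mathrm{PO_2}
  \;\Longleftrightarrow\;
  \mathrm{PO_2} = \frac{\tau_0/\tau - 1}{k_q\,\tau_0},$$

which is strictly decreasing in $\tau$ and zero at the unquenched lifetime
$\tau_0$. Saturation follows from a Hill model of the mouse hemoglobin
dissociation curve, $\mathrm{SO_2} = \mathrm{PO_2}^n/(P_{50}^n +
\mathrm{PO_2}^n)$, and blood oxygen content sums hemoglobin-bound and
dissolved fractions:

$$C = c_{Hb}\,[\mathrm{Hb}]\,\mathrm{SO_2} + \alpha\,\mathrm{PO_2}
  \quad [\mathrm{mLO_2/dL}].$$

The probe and blood-gas constants are not universal; the defaults
($\tau_0 = 637\,\mu s$, $k_q = 381\,\mathrm{mmHg^{-1}s^{-1}}$,
$P_{50} = 40$ mmHg, $n = 2.59$, $[\mathrm{Hb}] = 15$ g/dL,
$c_{Hb} = 1.39$ mLO$_2$/g, $\alpha = 0.003$ mLO$_2$/dL/mmHg) are literature
values for this probe and for C57BL/6 mouse hemoglobin, exposed in the
`oximetry` block of the config file. Using identical constants in both
groups means absolute inaccuracies cancel from between-group comparisons.
Lifetimes that exceed $\tau_0$ by at most 2% (a noise allowance) are clamped
to $\mathrm{PO_2} = 0$; larger excursions are an error rather than a silent
negative tension.

### Velocimetry and caliber

Venous blood velocity comes from fluorescent microspheres imaged at 104 Hz.
Each track is projected onto its principal axis (vessels are treated as
locally straight at this scale — no centerline model is attempted), and the
velocity is the magnitude of the least-squares slope of projected
displacement against time, making the estimator invariant to rigid rotation
and temporal offset. Per-vein velocity is the unweighted mean over tracks;
eye-level $V_V$ is the unweighted mean over veins, matching the averaging
convention of the source protocol (no diameter weighting).

Vessel diameter is the full width at half maximum (FWHM) of a 1-D
angiographic cross-profile, with half-maximum defined relative to a
background estimated as the median of the profile's outer 10% of samples
(robust and deterministic), and crossings located by linear interpolation.
FWHM is our documented choice of caliber criterion; edge-gradient criteria
exist but are noisier at these pixel pitches.

### Flow, delivery, metabolism, extraction

Per-vein flow is $Q = V\,\tfrac{\pi}{4}D^2$ with the fixed unit factor
$\mathrm{mm/s}\cdot\mu m^2 \to \mu L/min = 6\times10^{-5}$; TRBF is the sum
over veins (veins only — arterial flow is not computed). Oxygen delivery and
metabolism are $DO_2 = TRBF \times O_{2A}$ and $MO_2 = TRBF \times O_{2AV}$
(unit factor $\mu L/min \cdot mLO_2/dL \to nLO_2/min = 10$), and
$OEF = MO_2/DO_2$, which reduces algebraically to $O_{2AV}/O_{2A}$. All
derived metrics are computed **per eye first** and only then averaged across
a group: a mean of products is not a product of means, so group-level
$DO_2/MO_2/OEF$ are *not* recoverable from group-level TRBF and content
summaries. This ordering is asserted by test.

### Morphometry

Histological layer boundaries (depths from the inner limiting membrane)
convert to layer thicknesses by successive differences. Because the nerve
fiber and ganglion cell layers cannot be separated in mouse histology, the
combined NFL/RGCL is reported through the inner-retina identity
$\mathrm{NFL/RGCL} = \mathrm{IRL} - (\mathrm{IPL} + \mathrm{INL})$.
Nasal and temporal records are averaged element-wise; if one region is
missing the other is used with a warning (a robustness fallback — a study
would typically drop the eye). At wild-type calibration means the NFL/RGCL
occupies $100 \times 16.2/83.9 \approx 19\%$ of the inner retina. Histology
total thickness (sum of the six layers, about 172 µm at calibration) is
systematically below OCT total retinal thickness (242/235 µm), reflecting
histological shrinkage; the two are kept as independent metrics with their
own calibrations rather than linked by an explicit shrinkage factor, which
would double-count an offset already present in the calibration tables.

## The synthetic cohort generator

The generator emulates the study conditions: two groups of 13 animals, 4
arteries and 4 veins per eye, microsphere imaging at 104 Hz. Its
calibration tables are the printed group means and SDs of the motivating
study design (diameters, venous velocity, oxygen contents, layer
thicknesses, OCT thickness, amyloid-beta levels). Three conventions deserve
explanation.

**Positivity with exact moments.** Physiological quantities are strictly
positive, but a normal with mean 2.8 and SD 1.9 (venous oxygen content)
puts ~7% of its mass below zero, and naive rejection of negative draws
would inflate the realized mean by ~10%. Per-animal truths are therefore
drawn through a Gaussian copula whose marginals are zero-truncated normals
with latent parameters moment-matched (by deterministic optimization at
build time) so the truncated distribution has exactly the calibrated mean
and SD. Metrics whose truncation probability is negligible reduce exactly
to correlated normals.

**Correlation structure.** Only three cross-metric dependencies are
calibrated, all anchored at arterial oxygen content (a star structure;
remaining pairs are conditionally independent given $O_{2A}$):

* $O_{2A}\sim V_V$ and $O_{2A}\sim$ NFL/RGCL within-group correlations are
  solved by one-dimensional root search so that the *pooled* two-group
  correlations equal the targets (−0.57 and −0.53). Between-group mean
  separation already induces part of the pooled correlation; the
  within-group component supplies the remainder.
* $O_{2A}\sim O_{2V}$ is solved from the target SD of the arteriovenous
  difference (1.3 mLO$_2$/dL in the first group), via
  $\mathrm{var}(O_{2AV}) = s_A^2 + s_V^2 - 2\rho s_A s_V$. Independent
  draws would give an $O_{2AV}$ SD of 2.4 and frequent negative
  differences; the calibrated $\rho \approx 0.73$ keeps negative
  arteriovenous differences below ~0.5% (they are flagged, not removed).

An infeasible combination (a correlation matrix that is not positive
semi-definite, or an unattainable pooled target) is rejected with a message
rather than silently adjusted.

**Drawn versus derived metrics.** Per-animal TRBF is *derived* from the
per-vein velocity and diameter draws ($Q$ summed over four veins), not
drawn from its own calibration entry: at wild-type means four veins give
$\approx 1.78\ \mu L/min$ against a printed $1.73 \pm 0.52$, so the derived
and printed values are consistent but not identical. The same applies to
$O_{2AV}$, $DO_2$, $MO_2$ and $OEF$. Calibration-fidelity tests therefore
check the drawn metrics (means within 1%, SDs within 2% at $n = 10^4$ per
group); derived metrics are checked for consistency of magnitude only.

Per-vessel values are distributed around the per-animal mean with a 10% CV
(the study reports only per-eye averages, so within-eye spread is a free
knob), with deviations centered so the vessel mean equals the animal truth
exactly — this is what makes noiseless round-trip tests exact identities.
Vessel counts per eye (4 + 4) are likewise conventions, not published
values; both are config knobs.

Raw signals are then synthesized from the per-vessel truths: a sampled
modulated-emission sinusoid per vessel (additive Gaussian *phase* noise,
default 0.01 rad), microsphere tracks with isotropic centroid jitter
(default 1 µm), and caliber profiles. Without optical blur the profile is
the pixel-integrated boxcar — a trapezoid whose edge ramps span two pixel
pitches, chosen so that linear interpolation of the half-maximum crossings
recovers the true edges *exactly* for any sub-pixel vessel position;
vessels narrower than two pixel pitches are rejected as unresolvable. With
blur the profile has error-function edges whose FWHM deviates from the true
diameter only by edge-interaction terms, negligible for diameter ≫ blur.

**What the generator does not emulate.** Truth-level draws are (truncated)
Gaussian; real cohorts may be skewed or contain segmentation artifacts.
Proteins and OCT thickness are generated at truth level only (no raw ELISA
or B-scan signals). Vessels are straight, spheres never cross vessels, and
profiles contain a single vessel. Passing tests therefore certify the
estimators and the statistical machinery under the stated noise models, not
robustness to imaging pathologies.

## Statistics

Group comparisons use unpaired two-tailed Student t-tests with pooled
variance (the stated convention of the motivating design; Welch is not
used). Pearson correlations are computed on the pooled two-group data, as
in the source analyses. Normality is checked by Shapiro–Wilk as an advisory
only, and no multiple-testing correction is applied — matching the source
convention — with the number of tests reported alongside.

Post-hoc power for the two-sample design uses the observed effect size
$d = |\bar x_1 - \bar x_2|/s_p$ and the noncentral t distribution with
noncentrality $d\sqrt{n_1 n_2/(n_1+n_2)}$, both rejection tails included.
At the printed venous-velocity summaries (10.5 ± 3.1 vs 6.6 ± 1.4,
13 + 13, $\alpha = 0.05$) this gives 97.7% ≈ 98%.

For correlation power two methods are provided. The default integrates the
**exact** sampling density of the correlation coefficient under the
bivariate normal (a Gauss-hypergeometric form), the convention of standard
power software for this test: it yields 88.7% at $\rho = 0.57, n = 26$ and
67.9% at $\rho = 0.53, n = 19$, i.e. 89% and 68% to the whole percent. The
bias-corrected Fisher-z approximation is retained as `method = "fisher"`;
it gives 88.4% and 67.5% at the same inputs — about a percentage point low
at these sample sizes, which is why the exact method is the default. Both
routes are validated against Monte-Carlo rejection rates ($10^5$ replicates
on a 3 × 3 grid of effects × sample sizes, agreement within 3 binomial SEs).

## Numerical choices

* Content-to-tension inversion: bisection on the strictly increasing
  content curve, absolute tolerance $10^{-9}$ mmHg, search bound
  1000 mmHg; contents above the attainable maximum are an error.
* Phase estimation: closed-form linear least squares (no iterative fit, no
  starting values); phases outside $(0, \pi/2)$ are non-physical errors.
* Truncated-normal moment matching: Nelder–Mead on (mean, log SD) with
  squared-moment objective; residual above $10^{-10}$ is an error. Skipped
  when the mean exceeds six SDs.
* Hypergeometric series: term-ratio recursion, terminated at a $10^{-16}$
  relative term; the density argument is bounded away from the unit
  circle for $|\rho| < 1$.
* Degenerate inputs: zero-variance groups give $p = 1$ for equal means and
  an error otherwise; empty vessel classes propagate `NA` sentinels with
  warnings rather than crashing the pipeline.
* Determinism: every stochastic step derives from the single config seed;
  re-running the pipeline with the same config produces byte-identical
  CSVs (asserted by checksum in the tests).

## Problem sizes

The validation suite uses $10^4$ animals per group for calibration
fidelity, 200 replicate cohorts of 13 + 13 for correlation recovery, $10^5$
Monte-Carlo replicates per cell for the power oracles, and 3-animal
noiseless cohorts for round-trip identities — sizes chosen to hold sampling
error well below the tested tolerances while keeping the default suite
around two minutes.

## Known limitations

* The probe constants and dissociation parameters are defaults, not
  measured per-study values; absolute PO$_2$ and content levels shift with
  them even though group contrasts largely do not.
* The 5XFAD calibrations for IPL, INL and PRL reuse the wild-type values,
  because only their nonsignificance (not their summaries) is published.
* The generator's pooled-correlation calibration assumes a common
  within-group correlation in both groups; real groups may differ.
* Correlation power assumes bivariate normality; the pooled two-group
  mixture is only approximately bivariate normal, which is visible as a
  slightly wider replicate spread than the nominal sampling CI.
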