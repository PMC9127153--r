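---
title: "Estimating carotid endothelial shear stress from pulsatile velocity waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating carotid endothelial shear stress from pulsatile velocity waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carotidflow)
```

## The problem

Endothelial shear stress (ESS) — the frictional force per unit area that
flowing blood exerts on the vessel wall — is the principal mechanical
stimulus regulating endothelial function, and exercise transiently raises it.
Clinical studies of exercise hemodynamics record a Doppler velocity envelope
at the common carotid artery together with the lumen diameter and hematocrit,
and must convert one cardiac cycle of centerline velocity into wall shear
stress and a flow-regime classification. carotidflow implements that
conversion, a calibrated synthetic-study generator, and the repeated-measures
statistical pipeline used to compare exercise modalities and intensities.

## The Womersley model

Flow is modelled as fully developed pulsatile flow of a Newtonian fluid in a
straight rigid tube of radius $R$. The measured centerline velocity over one
cycle of period $T$ is decomposed into harmonics at $\omega_n = 2\pi n / T$:

$$v(t) \;=\; C_0 + \sum_{n=1}^{N} \operatorname{Re}\!\left(2\,C_n e^{i n \omega t}\right).$$

Each harmonic's departure from a parabolic profile is governed by the
Womersley number $\alpha_n = R\sqrt{\omega_n \rho / \mu}$. With
$\Lambda_n = i^{3/2}\alpha_n$, the oscillatory velocity profile is
$u_n(r) \propto 1 - J_0(\Lambda_n r/R)/J_0(\Lambda_n)$, and differentiating
it at the wall under the centerline normalisation $u_n(0) = C_n$ gives the
per-harmonic transfer function actually used:

$$\tau_n \;=\; \frac{\mu\, C_n\, \Lambda_n J_1(\Lambda_n)}
{R\left(1 - J_0(\Lambda_n)\right)},
\qquad
\tau_0 \;=\; \frac{2 \mu C_0}{R},$$

with the fluid-side sign convention $\tau = -\mu\,\partial u/\partial r$ at
$r = R$, so that the steady term is the familiar Poiseuille centerline form
and every $\tau_n \to 2\mu C_n / R$ as $\alpha_n \to 0$. (The opposite sign
in the denominator, $J_0 - 1$, is sometimes seen; it flips the oscillatory
component relative to the steady one and breaks the quasi-steady limit, so
the package fixes the convention by requiring that limit.) The shear series
is resynthesised on the waveform's own grid and reported in dyn/cm²
(1 Pa = 10 dyn/cm²); the cycle **mean** of $\tau(t)$ is the primary summary
("ESS"), with the cycle peak reported alongside. Because the oscillatory
harmonics time-average to zero, the cycle mean depends only on $C_0$ — a
useful exactness property that the calibration below exploits.

$J_0$ and $J_1$ at complex argument are evaluated by the ascending power
series (no complex Bessel routine ships with base R). The series converges
everywhere; round-off cancellation limits it in practice, so evaluation
refuses $|\Lambda| > 40$ — far above any physiological harmonic
($\alpha_8 \approx 25$ at 200 bpm in a dilated carotid) while retaining
about ten significant digits at the boundary. A transfer evaluation with
$|J_0(\Lambda) - 1| < 10^{-14}$ (i.e. $\alpha \lesssim 10^{-7}$) is refused
as numerically degenerate rather than silently switched to the quasi-steady
formula.

### Blood properties

Whole-blood viscosity follows a quadratic hematocrit law
$\mu = \mu_p (1 + 2.5\,H + 7.35\,H^2)$ with plasma viscosity
$\mu_p = 1.2\times10^{-3}$ Pa·s, a standard Einstein-type suspension
expansion; without a hematocrit the population default
$3.5\times10^{-3}$ Pa·s is used. Density is fixed at 1060 kg/m³. Both are
overridable; supplying a viscosity that contradicts the supplied hematocrit
is an error rather than a silent preference.

### Reynolds number and regime

$\mathrm{Re} = \rho V D / \mu$ with $V$ the cycle-averaged centerline
(envelope) velocity. A defensible alternative halves $V$ (the spatial mean of
a parabolic profile), but that convention is internally inconsistent with the
published condition-level results this package is calibrated to: the cycle
mean ESS pins $C_0 = \bar\tau R / (2\mu)$, so halving $V$ gives
$\mathrm{Re} = \rho \bar\tau D^2/(8\mu^2)$, and the weakest exercise
condition (bench press, low intensity, 34.8 dyn/cm²) could only exceed the
turbulent threshold with a carotid diameter above 7 mm and hematocrit below
0.36 — outside this package's own physiological defaults. Envelope-velocity
Re reproduces both the ESS table and the all-conditions-turbulent result with
ordinary defaults, and matches single-gate Doppler practice where the
envelope is what is measured. Regimes: Re < 200 undisturbed laminar,
200–1800 disturbed, > 2000 turbulent; the published ranges leave 1800–2000
undefined, which is surfaced as `indeterminate` rather than merged.

## The synthetic-study generator

The generator emulates a repeated-measures exercise study: 14 participants
(7 per sex), six modalities (treadmill, cycle-ergometer, arm-ergometer,
squat, bench press, biceps curl) crossed with three intensities, plus two
resting baseline visits. Its stated world:

* **Condition calibration.** Per-condition ESS mean ± SD defaults are the
  published condition summaries (treadmill high 84.7 ± 9.7 dyn/cm² … baseline
  23.8 ± 4.8), embedded in `default_calibration()` and replaceable by CSV.
* **Heart-rate schedule** rest 65, low 100, moderate 140, high 175 bpm —
  physiological defaults, since the source reports none.
* **Diameter** 6.3 ± 0.4 mm between participants, constant within;
  **hematocrit** 0.45 ± 0.03 (males) / 0.40 ± 0.03 (females).
* **Correlation structure.** Each participant's standardised intercept
  $b_i$ is shared across conditions; a condition target is
  $\mu_c + \sigma_c(\sqrt{\rho}\, b_i + \sqrt{1-\rho}\,\varepsilon_{ic})$
  with intraclass correlation $\rho = 0.5$ by default (the source reports a
  strong participant random effect but no variance components).
* **Truncation.** Draws are truncated at ±3 SD; the residual is drawn
  conditionally on the intercept so the combined deviate cannot push a
  target below 5% of its condition mean — a naive per-draw rule still allows
  a −4.2 SD excursion, which turns the widest condition (arm-ergometer high,
  57.8 ± 20.7) negative.
* **Waveforms.** A deterministic canonical carotid shape (systolic peak,
  dicrotic notch, secondary wave; strictly positive, unit mean) is scaled per
  record so the Womersley pipeline recovers the drawn target *exactly* — the
  scale factor is exact by linearity. Waveforms carry no measurement noise;
  all between-record variability lives in the drawn targets, diameters and
  hematocrits.
* **Seeding.** One master seed; each participant consumes an independent
  substream derived from it, so record order cannot perturb reproducibility.

What the generator does **not** emulate: Doppler spectral broadening and
envelope-tracing noise, beat-to-beat variability, diameter pulsation within
the cycle, exercise-duration differences between modalities, and any
intensity-dependent waveform shape change. Consequently a green end-to-end
test establishes that the estimator and the statistics behave correctly in a
world with the published condition-level distributions — not that the
physical model is unbiased for real ultrasound data. One implication worth
stating: calibrating mean ESS through a Poiseuille-coupled centerline
velocity implies exercise centerline velocities of 2–3 m/s at the highest
conditions, higher than typically measured; the calibration reproduces the
published ESS scale, not a full velocity field.

## The statistical layer

* **Mixed model.** `ESS ~ modality + intensity + sex + modality:intensity +
  (1 | participant)`, REML via lme4. Type-III F tests use sum-to-zero factor
  coding; denominator df are Satterthwaite, computed in-package: with a
  single random intercept the marginal covariance has a closed Woodbury
  form, the covariance of the variance-component estimates comes from a
  central-difference Hessian of the REML criterion, and multi-df tests pool
  per-eigencontrast dfs. On paired two-level designs this reproduces
  F = t² with df = n − 1 exactly; between-subject factors get df near
  n<sub>participants</sub> − 2. A residual-df fallback (`ddf = "residual"`)
  is available. The random intercept is tested by a REML likelihood ratio
  with the ½χ²₀ + ½χ²₁ boundary mixture.
* **Post hoc.** Paired t-tests with Holm adjustment applied *within* each
  family — one family per modality (intensity contrasts) and one per
  intensity (modality contrasts), mirroring how such tables are reported.
  Hedges' g uses the difference-score standardiser with
  $J = 1 - 3/(4(n-1) - 1)$; magnitudes: < 0.2 very small, < 0.5 small,
  < 0.8 moderate, ≥ 0.8 large (0.8 itself resolves to large, closing the
  gap a "0.5–0.79 / > 0.8" phrasing leaves open). Identical paired vectors
  are defined as t = 0, p = 1, g = 0 rather than an error.
* **Reliability.** CV = 100·SD/mean on the pooled baseline records, with a
  seeded percentile bootstrap CI (default 10,000 replicates) — chosen for
  distribution-freeness since no interval method is canonical; the interval
  is widened, if necessary, to contain the point estimate, keeping the
  invariant lower ≤ CV ≤ upper under resampling quirks. Bands: < 10% very
  good, 10–20% good, 20–30% acceptable, > 30% poor.
* **Demographics.** Sex differences are tested by pooled-variance two-sample
  t from printed group summaries (at n = 7/7, Welch and pooled SEs coincide;
  only the df would differ). The height row is retained but flagged: its
  printed t cannot be recovered from the rounded summaries.
* **Reynolds summaries.** Per-condition t-based 95% CIs; a condition is
  flagged turbulent when the whole interval clears 2000.

## Numerical and design choices

* All computation is SI internally; dyn/cm² appears only at reporting
  boundaries (exactly ×10).
* Harmonic truncation defaults to N = 8; truncation error is observable as
  the reconstruction residual and is negligible for carotid-like shapes.
* Estimated marginal means equal cell means in the balanced complete design,
  and are computed as such.
* Monte-Carlo acceptance checks reduce waveform sampling to 64 points/cycle:
  the cycle-mean ESS depends only on $C_0$, which is exact at any sampling
  density, so this is a pure speed choice.

## Limitations

Rigid straight tube, Newtonian rheology, axisymmetric fully developed flow —
no secondary flow at the bifurcation, no wall compliance, no non-Newtonian
shear thinning. The Reynolds thresholds are conventional cut-offs, not
predictions; the 1800–2000 band is genuinely indeterminate. Synthetic
calibration reproduces condition-level summary distributions only; exact
published t and g values from the original raw data are not recoverable from
summaries and are covered qualitatively (sign, magnitude class, approximate
percent change) by the test suite.
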