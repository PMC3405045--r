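---
title: "Methods: appendage heat budgets, multimodel inference, and the synthetic experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: appendage heat budgets, multimodel inference, and the synthetic experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(billheat)
```

`billheat` estimates how much "dry" heat a small bird sheds through its
bill, legs and body, and whether a larger-billed population sheds more.
This vignette is the package's own account of the science: the models, the
assumptions they rest on, the parameters that matter, and what the
synthetic data can and cannot demonstrate.

## Surface areas from morphometrics

Region areas use deliberately simple solids, matching how field
morphometrics are taken with calipers:

* **Bill**: lateral area of a nearly circular elliptical cone,
  $A = \frac{W + D}{4} L \pi$, evaluated twice — at the anterior edge of
  the nares (the protruding "bill cone", comparable across studies) and at
  the base of the bill (the full heat-exchanging surface). The printed
  length is used as-is; no slant-height correction is applied, because the
  formula is a field convention, not an attempt at exact geometry. For
  bills (length ≫ depth) the difference is under a percent.
* **Legs**: both tarsi as elliptical cylinders,
  $A = 2\pi l \sqrt{2((w/2)^2 + (d/2)^2) - (w-d)^2/2}$. Toes are excluded
  (not resolvable in thermal images); the feathered tibia counts as body.
* **Body**: the passerine allometry $A = 8.11\,m^{0.67}$ (cm², mass in g).
  Because the allometry is concave, cohort means must be computed as means
  of per-bird areas, never as the area at the mean mass; the package's
  summary functions do this.
* **Volume**: $V = m/\rho$ with $\rho = 0.913$ g/cm³.

Areas are carried in mm² throughout the morphometrics layer and converted
to m² at exactly one point inside the heat-budget module, so a silent
$10^6$ unit error cannot arise from mixing conventions.

## The dry heat budget

Per region and observation, $Q = Q_r + Q_c$:

$$Q_r = \varepsilon \sigma A (T_s^4 - T_a^4), \qquad
  Q_c = h_c A (T_s - T_a), \qquad
  h_c = \frac{Nu \, k}{D}, \qquad
  Nu = c\,Re^n, \qquad
  Re = \frac{V D}{\nu}.$$

Assumptions and defaults:

* $\varepsilon = 0.96$ (biological tissue), $\sigma = 5.6703 \times
  10^{-8}$ W m⁻² K⁻⁴, $V = 0.1$ m/s (still chamber air). All are
  overridable through `physical_constants()`.
* $(c, n) = (0.174, 0.618)$ for bill and legs (cylinder-like forced
  convection) and $(0.34, 0.6)$ for the body.
* The characteristic dimension $D$ is the region's vertical length scale:
  half the bill depth, the tarsus length, the cube root of body volume.
  For the bill we use the depth **at the base** — the largest vertical
  dimension of the heat-exchanging surface; this is a documented choice,
  configurable through the `dims` argument, since only "half the depth" is
  conventionally specified.
* Kelvin is used only inside the radiative fourth-power term; the
  convective term works in °C differences (identical to K differences).
* A surface colder than the air returns *negative* heat loss, not zero:
  clamping would bias totals. When total heat loss is not positive, the
  percent-through-bill statistic is undefined and reported as `NA`.

Air properties come from standard dry-air correlations at 1 atm:
$k = 0.02624\,(T_K/300)^{0.8646}$ W m⁻¹ K⁻¹ and $\nu = \mu/\rho_{air}$
with Sutherland's law $\mu = 1.458\times10^{-6}\,T_K^{1.5}/(T_K + 110.4)$
and ideal-gas density. Both agree with published dry-air tables to well
within 2% over 0–50 °C (tested against a table fixture). Outside −20 to
60 °C the functions refuse to extrapolate unless told to. Conductivity is
evaluated at the film temperature $(T_s + T_a)/2$ by default — the
standard boundary-layer convention — while viscosity is evaluated at the
ambient temperature; whether a given historical analysis evaluated $k$ at
film or ambient temperature is rarely stated, so the choice is exposed as
`conductivity_at` and its effect (fractions of a percent over this
temperature range) can be checked directly.

The default analysis unit is the per-(bird × ambient step) mean of the
five frames, giving 216 rows for the default design; frame-level analysis
is available via `average_frames = FALSE`. Heat-loss differences convert
to water savings by $\dot m = \Delta Q \cdot 3600 / L \cdot 1000$ mg/h
with $L = 2418$ J/g, the latent heat of vaporization of water.

## Multimodel inference

Each response (bill, bill-base, body and leg surface temperatures; bill
heat loss; percent of heat through the bill; relative humidity) is
modelled with Gaussian linear mixed models: fixed effects drawn from
subspecies (SSP), ambient temperature ($T_a$, with quadratic and cubic
terms to capture vasomotor nonlinearity) and their interactions; the
square root of activity (hops/min) in **every** model, since activity has
a quadratic relationship with ambient temperature and adds metabolic
heat; and a per-individual random intercept absorbing repeated-measures
correlation. Random slopes are deliberately excluded — all individuals
share the temperature response.

The candidate set has 11 members, from the null model (√activity only)
through the saturated
$SSP * T_a + SSP * T_a^2 + SSP * T_a^3$, respecting marginality.
Parameter counts include the two variance components, so $SSP + T_a$ has
$K = 6$ and the saturated model $K = 11$.

Numerical and design choices:

* **ML, not REML.** Candidates differ in fixed effects, so REML
  likelihoods are not comparable; all AICc values use full ML
  (`lme4::lmer(REML = FALSE)`). This is the standard
  information-theoretic choice.
* **AICc** is computed as $-2\ell + 2K + 2K(K+1)/(n-K-1)$ with $n$ the
  number of rows entering the fit (216 at the default design); the
  correction is refused when $n \le K + 1$.
* **Weights and evidence ratios** follow the usual softmax-of-deltas
  form; comparison tables are truncated at $\Delta AICc < 5$ for display
  only — averaging always uses the full set.
* **Model-averaged predictions** use
  $\bar{\hat y} = \sum_i w_i \hat y_i$ with unconditional standard error
  $\sum_i w_i \sqrt{se_i^2 + (\hat y_i - \bar{\hat y})^2}$, so model
  uncertainty inflates the SE. Per-model prediction SEs are
  fixed-effects-only (random effects at zero); they describe the
  population-mean curve, not a particular bird.
* **Residual correlograms** pool within-individual autocorrelation of
  residuals (ordered by ambient step, the protocol's time axis) with
  white-noise bounds $\pm 1.96/\sqrt{n}$, as a diagnostic that the random
  intercept has absorbed the serial structure.
* Cohort morphometric comparisons use pooled-variance two-sample t-tests
  with Bonferroni correction across the compared measurements.

## The synthetic experiment

The generator emulates the study design: two subspecies × 9 birds,
ambient stepped 15 → 37 °C in 2 °C increments (12 steps, 15 min each),
five analysed frames per step — 1080 frame-level observations. Response
structure, all configurable via `response_config()`:

* **Bill**: elevation above ambient interpolates linearly 9.8 → 4.7 °C
  across the ambient range (the observed relationship is close to
  linear); the coastal subspecies adds a constant 0.3 °C — small because
  a whole-bill subspecies temperature effect is only weakly supported;
  set it to 0 for null simulations.
* **Bill base**: same baseline with a subspecies × ambient interaction —
  coastal birds run 1.2 °C hotter at the cold end, shrinking to 0.2 °C at
  the warm end. This is the structure the model-selection stage is
  expected to recover.
* **Body**: 4.4 → 2.6 °C elevation, no subspecies effect.
* **Legs**: a logistic vasodilation threshold (midpoint 29 °C, width
  1.5 °C) between a vasoconstricted 1 °C and a vasodilated 4 °C
  elevation, since the leg response is non-linear with a
  constriction/dilation transition.
* **Covariates**: activity is quadratic in ambient temperature (same for
  both subspecies), truncated at zero; relative humidity falls linearly
  70% → 30% across the range plus noise — only its anticorrelation with
  ambient temperature matters downstream.
* **Variance components**: individual random-intercept SD 0.5 °C per
  region, frame-level residual SD 0.4 °C. These are stated assumptions —
  plausible for thermography of captive passerines — not literature
  values, because variance components of this kind are rarely reported.
* Morphometrics are drawn from truncated normals (±3 SD, avoiding
  non-physical negatives) at the cohort means/SDs; bill depth at the base
  (mean 6.0/6.3 mm, SD 0.3 mm) is likewise an assumption, needed for the
  convection length scale.

Determinism: every generator call takes a seed and restores the caller's
RNG state; identical seeds give bit-identical outputs.

**What passing tests show — and don't.** The generator reproduces the
*statistical shape* of a chamber thermography experiment: elevations,
interactions, thresholds, variance structure, protocol bookkeeping. It
does not render radiometric images of birds (ROI extraction is tested on
abstract temperature grids), does not model evaporative or respiratory
heat exchange, radiative gain, or wind, and draws region areas directly
rather than simulating caliper error. Parameter-recovery results
therefore validate the inference machinery under the stated generating
model, not the biophysics of any particular real bird. One consequence
worth stating plainly: with 9 birds per group and a deliberately small
0.3 °C bill offset, the subspecies contrast in bill heat loss scatters
widely between cohorts (the systematic value implied by the defaults is
roughly +20%, dominated by the +16.7% area difference); single-seed runs
can land well away from it, which is why the package's checks average
replicates before asserting on it.

## Problem sizes

Tests and the acceptance script run the default design (18 birds, 12
steps, 5 frames; 216 analysis rows). Structure-recovery checks use 50
seeded replicates of the full 11-model set in the test suite and 30 in
the acceptance script; Monte-Carlo bias checks use 40 replicates of a
single model. These sizes give comfortable margins on the stochastic
assertions while keeping a full run in minutes on one core.

## Known limitations

* Forced convection only; free convection at very low air speed is out of
  scope, and $V = 0.1$ m/s is an assumption about chamber air.
* Air-property correlations ignore humidity and pressure dependence
  (sub-percent effects in this regime).
* The elliptical-cone and cylinder areas are field conventions; they
  under- or over-estimate true integument area in ways that cancel only
  partially in between-group comparisons.
* Surface temperatures are taken as ROI means; within-region temperature
  gradients (e.g. bill tip vs base) enter only through the separate
  bill-cone and bill-base responses.
* Two related reported cone-area summaries (99.81 vs 99.89 mm²) differ in
  the source material; all package summaries carry full precision and
  leave rounding to the caller.
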