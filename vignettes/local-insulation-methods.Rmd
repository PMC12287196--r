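---
title: "Predicting local clothing insulation: models, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting local clothing insulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(localclo)
```

## The model

Clothing insulation is measured in clo (1 clo = 0.155 m²·K/W). Multi-node
thermoregulation models need the insulation of each body segment,
`I_cl,i`, but most data sources record only the whole-body value `I_cl`
(the sum of the garments' effective insulations). `localclo` predicts the
per-segment distribution with one regression rule per segment and posture:

$$I_{cl,i} = \max(a \cdot I_{cl} + b,\; c)$$

where the line may be replaced by a *continuous* two-branch piecewise-linear
function when a single line underfits. The minimum threshold $c$ is the
smallest local insulation observed for that segment — predictions should
not undercut the thinnest ensemble actually measured. Two segments are
constants: the head (0.13 clo — headwear is rare and nearly independent of
the rest of the ensemble) and the hand (0 clo — bare hands). The neck has
no model and defaults to 0 clo, the convention used when feeding a
multi-node simulation whose scheme includes a neck segment.

Note a consequence of the $\max(\cdot, c)$ form: at $I_{cl} = 0$ a segment
evaluates to $\max(b, c)$, which for segments with positive intercepts
(thigh, foot) sits slightly *above* the threshold. The threshold is a
floor, not the value at zero.

The packaged coefficient set covers chest, back, pelvis, shoulder, arm,
thigh, leg and foot for standing, sitting and generic (pooled) postures,
fitted to 240 harmonized thermal-manikin ensembles spanning 0.22–2.17 clo
overall. Predictions above 2.17 clo warn: heavy protective clothing lies
outside the support of the fits. The same models are applied to both sexes;
sex differences in the underlying data are minor.

## Harmonization

Manikin datasets disagree in two ways, and `harmonize_dataset()` resolves
both:

1. **Value convention.** Regional totals include the air boundary layer;
   effective values are increments over nude. The conversions are
   $I_{t,i} = I_{clu,i} + I_{a,i}$ and the ISO 9920 pair
   $I_{cl,i} = I_{t,i} - I_{a,i}/f_{cl,i}$, $f_{cl,i} = 1 + 0.28\,I_{cl,i}$.
   The second relation is implicit in $I_{cl,i}$; substituting gives the
   quadratic $0.28x^2 + (1-0.28 I_t)x - (I_t - I_a) = 0$, solved in closed
   form (unique non-negative root) rather than by iteration — exact,
   deterministic, and validated in the tests against a fixed-point
   iterator. A total below the nude baseline would imply negative clothing
   insulation; it is clipped to 0 with a warning.
2. **Segmentation.** Manikins split the body differently (left/right limbs,
   etc.). For manikins operated at uniform surface temperature, resistances
   combine in parallel, so merged segments take the area-weighted harmonic
   mean of the originals' *totals*. Merging happens before the total→local
   conversion. Nude baselines are merged by the same rule — published datasets do not
   document this step, but the physics (parallel conductances) is
   identical.
   Records already in the local convention cannot be merged (the parallel
   rule is not defined for clothing-layer-only values) and must arrive on
   the canonical segments.

The 11-segment scheme is head, neck, chest, back, pelvis, shoulder, arm,
hand, thigh, leg, foot, with left/right collapsed. A default area map ships
with conventional body-surface-area fractions (head 7 %, chest 13 %, both
feet 7 %, ...); any consistent fraction set preserves the harmonic-mean
semantics, and users can supply their own CSV. All internal arithmetic is
in clo; `clo_to_si()`/`si_to_clo()` convert at I/O boundaries only.

Per-ensemble failures (missing segments, mixed conventions, missing nude
baselines) reject that ensemble with a logged reason rather than aborting
the run: one bad record in a 240-ensemble dataset should cost one record.

## Fitting

`fit_linear()` is ordinary least squares. `fit_piecewise()` fits a hinge
that is constrained continuous at the breakpoint: for each candidate
breakpoint the model is linear in its remaining parameters
(`y ~ 1 + x + max(x - bp, 0)`), so the search is an exact least-squares
solve per candidate plus a grid search over candidates. Choices made here,
since neither the functional form's continuity nor the search procedure is
standardized:

* **Continuity is imposed.** Every packaged piecewise coefficient pair
  meets at its breakpoint to within 0.01 clo (most to within 0.002), which
  is strong evidence the underlying fits were continuous; an unconstrained
  two-line fit can produce jump discontinuities that make no physical
  sense for clothing.
* **Candidate breakpoints** are the observed overall-insulation values
  strictly inside their 10th–90th percentiles, each needing at least two
  distinct x-values on both sides. No interior candidate ⇒ fall back to the
  linear fit with a warning.
* **Model selection** (`select_model()`): the piecewise form is kept only
  if it reduces the SSE by more than 10 % (relative, configurable), with an
  absolute 1e-12 guard so floating-point dust on an exactly linear dataset
  cannot trigger a spurious hinge; ties go to the simpler model.
* **R²** is reported for the unclipped regression line, before
  $\max(\cdot, c)$ is applied — one number per fit, as coefficient tables
  conventionally report it.
* **Thresholds** default to the smallest observed local value, clamped at 0
  (noise around a near-zero line can put the sample minimum below zero,
  which is non-physical).

`local_clo_fit()` wraps this per segment over a harmonized dataset and
returns an object with the usual modelling methods (`coef`, `predict`,
`plot`, `residuals`, ...).

## The comfort solver

`pmv()` implements the Fanger predicted mean vote in the ISO 7730 form:
clothing-surface temperature by damped fixed-point iteration (tolerance
1e-4 °C, capped at 300 iterations with a diagnostic error), convective
coefficient $h_c = \max(2.38\,|t_{cl}-t_a|^{0.25},\, 12.1\sqrt{v})$,
vapour pressure from relative humidity via the standard saturation
exponential, external work 0 by default. "Operative temperature" here
means air = mean radiant temperature, a single knob. The whole-body
clothing area factor inside PMV uses the two-branch ISO form
(1 + 1.29·I below 0.078 m²K/W, else 1.05 + 0.645·I) — deliberately distinct
from the regional `fcl_from_local()`; conflating the two is a real hazard
since both are "f_cl".

`neutral_band()` brackets PMV = ∓0.5 with `uniroot` (temperature tolerance
0.005 °C) over a default 0–45 °C bracket. The bracket is wide on purpose:
at 1.5 clo and 2 met the lower endpoint drops below 10 °C. At the still-air
reference conditions (0.1 m/s, 50 % RH, 1 met, 0.3 clo) the solver returns
26.00–28.32 °C; these endpoints are pinned in the acceptance tests to
±0.05 °C of the reference values 25.99 and 28.31 °C, since PMV
implementations legitimately differ in the last rounding of their physical
constants.

## Simulation and evaluation

The thermoregulation model itself is behind an adapter (`thermo_backend`):
the package does not re-implement multi-node physiology. The bundled
`stub_backend()` is a deterministic affine response
$T_i = T0_i + \alpha_i (t_{op} - 27) + \beta_i I_{cl,i} + s$ (sex offset
$s$, defaults ±0.15 °C) chosen so that every pipeline output has a
closed-form expectation — the tests exploit this as an exact oracle. It
reproduces the two monotonicities the workflow relies on (warmer
environment ⇒ warmer skin; more clothing ⇒ warmer skin) and nothing else;
passing tests with the stub validates the *plumbing*, not physiological
realism.

`run_neutral_endpoints()` runs male and female subjects at both band
endpoints, averages the sexes at each endpoint, and takes min/max across
endpoints as the simulated range (min/max so a non-monotone backend still
yields a valid interval). `simulate_scenario()` adds the variants: `local`
(the method), `uniform-overall` (the simplification it replaces),
`with-wind` (log-law correction
$I' = \max(0, I + d\ln v_{rel} + e)$ with user-supplied per-segment
coefficients — none ship, as published coefficient sets are
campaign-specific), and `with-overrides` (e.g. foot = 1.580 clo for sports
shoes with ankle socks when the regression's 0.425 clo sandals
underestimate actual footwear). Wind correction operates on the
already-thresholded static values and clips at 0 only. The dorsal-hand
conversion $T_D = 0.88\,T_P + 2.9$ compensates for AVA-driven palmar
temperatures in backends that model them; sensors sit on the back of the
hand.

Measured ranges come from vote series: records with overall thermal
sensation vote in [-0.5, 0.5] (bounds inclusive — "between −0.5 and 0.5"
is read inclusively) are pooled across subjects, and each segment's range
is the interquartile interval (linear-interpolation percentile convention,
R type 7). Pooling before the IQR, rather than per-subject IQRs averaged,
is a choice; with per-subject neutral windows of very different sizes the
two differ. Agreement is the interval Jaccard similarity — overlap length
over union length of the closed intervals, with degenerate-point
conventions (equal points ⇒ 1, otherwise 0) that real data never hits.
`jsc_report()` gives per-segment values, unweighted means per variant, and
pairwise mean deltas.

## Synthetic data

`gen_clothing_dataset()` draws overall insulation uniformly on the
harmonized ensembles' range (0.22–2.17 clo), evaluates a truth model table
per segment, adds Gaussian noise (default sd 0.05 clo, a plausible manikin
repeatability figure), and clips at the model minimum. It can re-export
through the forward ISO 9920 maps as regional-total or effective-local
records (nude baselines uniform on 0.4–0.7 clo — only positivity and
consistency matter for round-trips) to exercise ingestion.
`gen_skin_series()` plants neutral samples uniformly inside true
temperature ranges and non-neutral samples shifted outside, with seeded
reproducibility throughout (generators save and restore the caller's RNG
state).

What the generators deliberately do not emulate: posture-dependent garment
compression, correlated noise across segments, subject physiology, or the
time structure of field protocols. Tests that pass on synthetic data
therefore demonstrate the correctness of the estimation machinery under
the model's own assumptions, not field validity.

Problem sizes used in the test suite — 1,000-case round-trip and
interval-similarity property sweeps, 500-point noisy refits, 120–140-point
noiseless recovery grids, 600-sample evaluation series — are desk-scale:
the full suite runs in seconds.

## Numerical choices and degenerate inputs

* Total→local inversion: closed-form quadratic root; totals below the nude
  baseline clip to 0 with a warning.
* Parallel merging rejects zero insulation values (infinite conductance)
  and non-positive areas outright.
* Noiseless-recovery testing uses a truth table idealized to exact branch
  continuity; the printed packaged coefficients meet only to ≤ 0.01 clo at
  their breakpoints (rounding), so they are near, but not exactly in, the
  continuous-hinge family.
* Breakpoint recovery is only identifiable when the true breakpoint lies
  inside the candidate window; the smallest packaged breakpoint (leg,
  0.450 clo) sits at ~12 % of the 0.22–2.17 range, so recovery tests use
  sampling dense at the low end.
* JSON and CSV written by the CLI sort keys and fix floats at 6 significant
  digits, making identical runs byte-identical.

## Known limitations

* The regression models capture *typical* dressing patterns; individual
  preference (notably footwear) can deviate by over 1 clo — hence the
  override mechanism rather than any claim of per-person accuracy.
* Sitting-posture fits for the lower body are weak in the underlying data
  (thigh R² ≈ 0.08); the pooled generic models are the recommended default.
* Above ~2 clo overall the models extrapolate; they warn but do not refuse.
* Evaporative/vapour resistance and clothing heat-moisture transfer are out
  of scope; the models treat dry insulation only.
* The PMV solver assumes air = mean radiant temperature; strongly
  asymmetric radiant environments need a different front end.
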