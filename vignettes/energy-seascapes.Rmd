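---
title: "Energy seascapes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy seascapes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model chain
and its assumptions, the parameters that matter, what the synthetic
generators do and do not emulate, the numerical choices, and the places
where the design was genuinely open and we chose.

## The energy-balance chain

The package treats habitat quality as a daily energy budget rather than a
temperature envelope. Four Gaussian additive smooth regressions are fitted
independently and then chained:

* **Diel depth (1a/1b).** Day and night mean depth of tagged juvenile
  albacore as smooth functions of upper-200 m mean temperature (T200,
  °C), moon illumination (%), and the depth of the 3.5 ml L⁻¹
  dissolved-oxygen surface (m) — the last being a hypoxia-avoidance proxy
  for epipelagic tunas. Days are split from nights in longitude-derived
  local solar time, daylight being the half-day-length window around local
  solar noon.
* **Movement cost (2).** Mass-specific oxygen consumption (mg O₂ kg⁻¹
  h⁻¹) as a tensor-product smooth of water temperature and swimming speed
  (body lengths s⁻¹), from captive-tuna respirometry. On seascape maps the
  speed is fixed by the diel convention — 2 BL s⁻¹ by day, 1 BL s⁻¹ by
  night — and the two phases are weighted by astronomical day length; on
  observed tracks the speed is the measured 3-D daily distance converted
  to BL s⁻¹. Oxygen converts to energy at 13.59 J per mg O₂.
* **Foraging (3).** Daily Heat Increment of Feeding (HIF, °C·hour) — the
  integral of visceral warming above the fasting baseline, a proxy for
  meal energy — as smooths of mesozooplankton biomass (mg C m⁻²), fish
  fork length (cm), and day length (h).
* **Ingestion (4).** Energy ingested (kJ) from HIF, water temperature and
  percent finfish in the diet (fixed at 70% where unobservable), from
  captive feeding trials.

The budget closes as

```
balance = ingested × (1 − sda_loss − egestion_loss) − movement_cost
        = ingested × 0.638 − movement_cost,
```

with fixed fractional losses of 9.2% (specific dynamic action) and 27%
(excretion/egestion). The chain deliberately omits somatic maintenance,
growth and maturation costs: a positive balance is energy *available* for
those processes, not growth itself.

## Key parameters

| parameter | default | units | note |
|---|---|---|---|
| oxycalorific coefficient | 13.59 | J (mg O₂)⁻¹ | fixed conversion |
| SDA loss | 0.092 | fraction of intake | fixed |
| excretion/egestion loss | 0.27 | fraction of intake | fixed |
| day / night speed | 2 / 1 | BL s⁻¹ | diel convention for maps |
| diet | 70 | % finfish | where diet is unobservable |
| reference fish | 80 / 11 | cm / kg | seascape maps |
| thermal envelope | [11, 22] | °C SST | inclusive bounds |
| length–weight | a = 11/80³, b = 3 | kg, cm | calibrated so 80 cm → 11.0 kg |
| posterior draws | k = 10 per model | — | 10⁴ chain realizations |

The length–weight coefficients are a calibrated configuration default (the
allometric exponent 3 with `a` chosen to pin the reference fish), not a
literature estimate; substitute published coefficients via
`energetics_constants(lw_a=, lw_b=)` for real data.

## The smooth-model engine

Fitting is penalized cubic-regression-spline regression (REML smoothness
selection, Gaussian/identity) via **mgcv**, wrapped behind a small engine
(`fit_gam()`, `predict.smooth_model()`, `simulate_coefficients()`) that
adds the behaviors the chain needs:

* **Training-range clamping.** Chained prediction under future climates
  invites wild spline extrapolation. `predict()` therefore pins
  out-of-range predictors to the training-range edge by default and counts
  the clamps (`"n_clamped"`). All chained use keeps clamping on.
* **Shape constraints.** A 1-d term may be declared monotone. After the
  unconstrained fit, the term's partial response is isotonized on a dense
  grid and refit in its own basis by penalized least squares, growing the
  curvature penalty until the refit is monotone — the penalty null space
  is linear and a linear fit of a monotone target is monotone, so the
  search terminates. Which terms are constrained is configuration; the
  default is none, because the source of each constraint in real
  applications is biological judgment, not data.
* **Posterior simulation.** Coefficient draws come from the multivariate
  normal with the Bayesian coefficient covariance, via eigen
  factorization; negative eigenvalues are floored at zero and the repair
  flagged. Draws are seeded and reproducible.
* **Degenerate inputs.** Constant predictors fail early with the term
  named; a constant response (zero variance) switches smoothness selection
  to the prediction-error criterion, which tolerates it, and reports 0%
  deviance explained.
* **Families.** Gaussian only. The responses (depth, MO₂, °C·h, kJ) are
  continuous and the chain is linear composition; non-Gaussian families
  would complicate posterior simulation for little gain here.

One deliberate deviation from a purely additive structure: the ingestion
model adds interaction-only tensor smooths (HIF × temperature and HIF ×
diet) to its three marginal smooths, because meal energy scales with HIF
*modulated by* temperature and diet — a multiplicative law that no additive
surface can represent. The remaining three-way modulation is of order 0.2%
of the response range and is left to the smooths' flexibility.

Model serialization (`write_smooth_model()`) is a self-describing JSON
provenance record — terms, coefficients, covariance, ranges, deviance
explained, constraint metadata. It documents a fit; it does not round-trip
predictions. Reproducibility comes from refitting under seeded generation,
which every pipeline stage does.

## HIF extraction

The fasting baseline is a rolling 5th percentile of body temperature over
a 6-h window, smoothed by a centered 24-h moving mean. The percentile
window tolerates digestion pulses occupying most of a day so long as some
fasting minutes fall in each window; the daily smoother enforces the
physiological expectation that fasting temperature drifts slowly. Both
parameters are configuration, and the estimator is encapsulated so a
different baseline algorithm can be swapped in — the default is this
package's choice, not a reimplementation of any published tag-processing
pipeline. Daily HIF is the trapezoid-rule integral of
`max(body − baseline, 0)` over each local-solar day at the native 1-min
sampling; negative excess is truncated (digestive heat cannot be negative;
dips are sensor noise), sampling gaps longer than 2 min are excluded from
the integral, and days under 80% coverage are flagged.

## What the synthetic generators emulate

The generators define the study conditions under which the package is
exercised and tested:

* **Fields.** Monthly climatological grids (mirroring earth-system-model
  output granularity, linearly interpolated to dates at point of use) with
  SST decreasing poleward (0.42 °C per degree latitude) around a 3 °C
  seasonal cycle; T200 a fixed 3.5 °C stratification offset below SST;
  mesozooplankton increasing poleward and eastward with a spring–summer
  peak; an oxygen surface shoaling in an offshore band. The future period
  adds a +2 °C warming offset (a mid-emissions, end-of-century magnitude)
  and a latitude-banded mesozooplankton factor (0.85 south, 1.05 north of
  the mid-latitude). Emulated climate sources differ by a deterministic
  SST bias (≤0.8 °C) and mesozooplankton scale (≤15%) derived from the
  source id, identical in both periods, plus their own noise realization —
  so the future-minus-historical difference stays exactly the configured
  perturbation while change metrics still spread across sources.
* **Tags.** A seeded random walk with seasonal east–west drift; a 1-min
  depth trace whose day/night means follow links to the oxygen surface and
  T200, with a dive oscillation that completes an integer number of cycles
  within each diel phase (so phase means equal the links exactly in
  noise-free mode); a body-temperature trace of constant baseline plus
  trapezoid feeding pulses with closed-form areas stored per day; linear
  growth between release and recapture.
* **Laboratory tables.** Respirometry from
  `mo2 = b0 + b1·U² + b2·exp(b3·T)` and feeding trials from
  `kJ = g0·HIF·(1 + g1(T − T0))·(1 + g2(%finfish − 70)/100)`, both with
  stored parameters and Gaussian noise.

Every generated object stores its generating parameters; recovery tests
read truth only from that store. With all noise set to zero
(`noise_free()`), every downstream quantity — daily HIF, cost, ingestion,
balance, per-cell map values — is analytically computable, and
`project_energetics_truth()` composes those closed forms as an end-to-end
oracle that never touches the fitted models.

What passing these tests shows: the statistical machinery recovers known
smooth structure, the accounting is exact, the chain composes correctly,
and uncertainty propagation behaves. What it does not show: performance on
real tag data, where geolocation error, broken thermistors, nonlinear
thermoclines, eddies and fronts, behavioral modes, and diet variability
all violate the generators' assumptions. The generators contain no ocean
physics and no light-level geolocation error model.

## Numerical and design choices

* **Temperature at depth.** The gridded fields resolve only SST and T200,
  so ambient temperature uses the unique linear profile with `T(0) = SST`
  and 0–200 m mean `T200` (hence `T(z) = SST + z(T200 − SST)/100`,
  clamped to 0–200 m). A documented stand-in: real thermoclines are not
  linear, and this is the chain's main structural approximation.
* **3-D distance.** Daily distance is the scalar sum of the smoothed
  horizontal great-circle distance (7-day centered moving mean, partial
  windows at the edges) and the vertical path length (half the summed
  absolute depth steps, descents assumed nearly free). A Euclidean
  composition would be smaller; the scalar sum is the conservative
  reading and the convention here.
* **Envelope bounds.** Inclusive at both 11 and 22 °C; boundary-measure
  cells are negligible on any realistic grid, and inclusivity is the
  simpler contract.
* **Seasons and climatology.** Boreal DJF/MAM/JJA/SON on seasonal-mean
  SST masks; periods are 30-year climatological monthly means, not daily
  model output. Moon illumination and day length use the mid-month date.
* **Ensemble structure.** The two depth models share one ensemble slot
  (drawn jointly), so the posterior product has exactly four factors —
  depth, cost, HIF, ingestion — and `k⁴` members, enumerated lazily as
  index tuples; maps for all members are never materialized at once. The
  draws are crossed (Cartesian), the literal reading of a
  `10 × 10 × 10 × 10` product.
* **Attribution.** Spread attribution is one-factor-at-a-time: the
  variance of the summary statistic when a single slot (one GAM, or the
  climate source) varies and all else sits at point estimates, reported
  ranked with the joint-variation total and its interaction remainder; no
  Sobol decomposition, and shares are not forced to sum to one.
* **Serialization formats.** Gridded fields and maps travel as long-format
  CSV with a JSON grid-metadata sidecar; tags as a daily + minute CSV
  pair; configurations as YAML; model records as JSON. Plain text keeps
  every artifact diffable and the test fixtures generatable in code.
* **Interface.** The package's surface is its exported functions plus
  `run_all()`, which chains the stages (generate → extract HIF → fit →
  tracks → project → uncertainty), skips stages whose outputs exist, and
  writes a content-hash manifest; there is no shell entry point, since the
  intended use is scripted analysis.

## Problem sizes

The shipped tests and the acceptance script run the study system at desk
scale, chosen so the full suite exercises every path in a few minutes: a
4° grid over 20–52°N, 150°E–130°W (8 × 20 cells), 12 climatological
months, three fish × 60 days (259,200 minute samples), 240 respirometry
and 300 feeding-trial rows, three to five emulated climate sources, and
posterior ensembles evaluated on member subsets (the full 10⁴ enumeration
is exercised combinatorially). Nothing in the method is tied to these
sizes; the generators accept field-scale configurations (e.g. dozens of
fish, 1° grids, multi-year deployments) at proportional cost.

## Known limitations

* Gaussian additive fits with clamped extrapolation cannot warn when
  future covariates leave the training manifold in *combination* (each
  marginal in range, the pair unobserved); clamp counts only catch
  marginal excursions.
* The linear temperature profile biases ambient temperature wherever the
  mixed layer is shallow relative to the predicted depth.
* The HIF baseline estimator assumes pulses do not occupy entire windows;
  sustained continuous feeding would bias the baseline upward and HIF
  downward.
* Area-weighted balance change conflates where habitat is with how good
  it is when masks shift; the intersection-mask ("consistently
  favorable") metric is reported alongside for that reason.
* Attribution shares from the one-factor-at-a-time design ignore
  interactions except through the reported remainder.
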