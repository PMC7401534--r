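---
title: "Modelling keel forces and locomotion in perch-to-perch transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling keel forces and locomotion in perch-to-perch transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Keel bone (carina) fractures are widespread in commercial laying hens.
Besides high-energy collisions, the keel absorbs load during perfectly
routine locomotion: in aviary systems hens must jump or fly between
platforms and perches many times a day. How much load the keel sees in a
controlled transition plausibly depends on how the perches are positioned:
the direction of movement (upward or downward), the angle of the path and
the distance covered.

`perchjump` implements a complete analysis for a trained-hen experiment
that probes exactly this. Forty hens of two hybrids (20 white-feathered
Nick Chick, 20 brown-feathered Brown Nick, housed 4-7 per pen in eight
single-hybrid pens) jump between a take-off platform and a landing perch
arranged in a 2x2x2 factorial design:

* **direction**: upward (platform at 60 cm) vs downward (platform at
  135 cm);
* **angle class**: flat vs steep, measured from the horizontal, and
  direction-specific (up: 30 vs 60 degrees; down: 15 vs 30 degrees);
* **diagonal distance**: 50 vs 100 cm.

Every hen performs one session per condition (320 sessions over 16
testing days, two pen groups alternating days) with five jumps per
session, the first serving only to acclimate the hen. A vest-mounted
triaxial accelerometer (800 Hz, +/-200 G range) sits directly on the keel;
a high-speed video gives six event timestamps per jump (Signal, Take-off
start/end, Landing start/end, First peck) plus a binary record of
balancing movements after landing.

Angles are interpreted as measured from the horizontal and "distance" as
the diagonal; this is the only reading under which the landing perch for
up/flat/50 cm sits at the same height (85 cm) as for down/steep/100 cm,
an identity the design relies on and which `resolve_geometry()` reproduces
exactly.

## From acceleration to keel load

For each jump phase (take-off, flight, landing, delimited by the video
events) the package computes from the axis signals $a_x, a_y, a_z$ (in G):

$$a = \sqrt{a_x^2 + a_y^2 + a_z^2}, \qquad F = m\,a, \qquad
  \mathrm{impulse} = \bar F \, \Delta t,$$

with $m$ the hen's body mass (the mean of pre- and post-study weighings)
and $\Delta t$ the phase duration. Two deliberate conventions:

* **No gravity subtraction.** The magnitude is computed on the raw axes,
  so a standing hen reads 1 G and all forces include the static
  component. No baseline correction is applied anywhere, and the
  simulator's standing baseline is 1 G to match.
* **Dual force units.** In `units_mode = "paper"` (the default), force is
  `mass x acceleration-in-G`, the convention under which a 100 G collision
  for a 1.5 kg hen reads "150 N" and keel peak forces in controlled
  transitions come out near 3-4 N. `units_mode = "si"` multiplies by
  9.80665 for physically correct newtons. The two modes differ by exactly
  that factor everywhere and are never mixed within a report. Whether the
  accelerometer's own 27 g mass should enter the calculation is left
  unaddressed; it does not enter here.

Impulse is literally mean force times duration (a left Riemann sum over
the window samples), not trapezoidal quadrature; at 800 Hz the two agree
to O(1/n) and the tests state the tolerance explicitly.

Millisecond event timestamps are mapped to samples by nearest-sample
rounding with ties toward the earlier sample, and phases are half-open
intervals `[start, end)`, so every sample belongs to exactly one phase
even when a boundary hits a sample exactly. At 800 Hz the 1.25 ms sample
period dominates quantization error. The video-to-logger clock offset is
an explicit per-session annotation field; estimating it from video frames
is out of scope.

## The synthetic study

No public recordings accompany the experiment, so the package ships a
generator (`sim_config()`, `emit_dataset()`) that produces a complete
ground-truth study: roster, counterbalanced schedule, latent per-jump
outcomes, 800 Hz traces and event tables, in exactly the formats the
extraction stage reads.

**Outcomes first, traces second.** For each response (peak force per
phase, impulse for take-off and landing, latency to jump, latency to
peck) the generator draws a latent value on the model's transformed scale
from the same hierarchical structure the analysis fits: fixed effects of
distance, angle, hybrid and all interactions, plus Gaussian random
intercepts for pen, hen, condition-within-hen (one level per session) and
crossed calendar date, plus a jump-level residual. Balancing is a
Bernoulli draw from a logit model with the same random structure. Random
effects are drawn independently per response and per direction, matching
the analysis convention of modelling each response and direction
separately (real hens would induce cross-response correlation; see
*Limitations*).

**Truth-first trace shapes.** Traces are then rendered so that a perfect
extraction recovers the drawn values: a half-sine thrust pulse whose
amplitude equals the drawn take-off peak, a flapping-sinusoid flight
segment (8 Hz wingbeat), and an exponentially decaying landing impact.
Take-off and landing durations are *derived* from the drawn peak and
impulse (pulse width and decay constant are solved so both are exactly
realizable); flight duration follows from the jump distance and a
lognormal flight speed (median 2.3 m/s), mimicking the strong
distance-flight duration correlation that excludes flight impulse from
inference. The shapes are deliberately truth-first rather than
physics-first: the acceptance surface of this package is the recovery of
the magnitude/force/impulse calculations, not flight dynamics.

**Boundary grid.** Event boundaries are snapped to the common grid of
whole milliseconds and sample times (5 ms at 800 Hz, comparable to the
4.2 ms frame period of the 240 fps video the annotations mimic). Without
this, nearest-sample rounding can pull one flight-phase sample into the
landing window across the contact discontinuity, and a "perfect"
extraction would see the flight peak instead of the landing peak.
`truth.csv` stores both the latent (drawn) and the realized
(sample-quantized) values; extraction reproduces the realized values
exactly on noiseless traces and the latent ones within the boundary
quantization stated in the tests.

**Defaults are the study conditions.** Coefficient defaults are set so
simulated outcome distributions and effect patterns sit in the ranges
reported for trained hens (peak forces 3-4 N in kg x G units, take-off
impulses 0.25-0.55 N s, landing impulses 1.4-2.3 N s, latencies 1-4 s,
balancing rates 17-58%, with the distance and distance-by-angle patterns
the experiment found). Body masses (Brown Nick 2.0 +/- 0.15 kg, Nick
Chick 1.6 +/- 0.12 kg) are invented plumbing -- the study reports no
masses -- and are configurable. Sensor noise defaults to 0.03 G per axis.
The acclimation jump is flagged and excluded from analysis by default
(configurable), and First-peck censoring defaults to off.

The schedule generator uses a seeded balanced-Latin-square assignment
stratified by hybrid and day-group, with pen and within-pen order rotated
across days, and verifies a tolerance-based counterbalance diagnostic -- each condition's
mean within-day order must sit within 20% of the largest order slot of
the grand mean order, with a 3-sigma sampling-noise floor for small
rosters -- rather than an exact combinatorial optimum; no published
algorithm exists to reproduce. The testing window is described
once as 17 days and once as 16 days of actual testing in the source
material; the package uses 16 testing days as the default and surfaces
the discrepancy here rather than resolving it.

## Inference

Each response x direction combination is modelled separately (angle
classes mean different geometric angles per direction, so directions are
never pooled) by `keel_model()`:

* **Transformations** follow a fixed table: peak forces are
  inverse-transformed (1/x); take-off impulse is untransformed upward and
  log-transformed downward; landing impulse and both latencies are
  log-transformed; balancing uses a binomial-logit GLMM. The inverse
  transformation is order-reversing, so back-transformed interval
  endpoints are swapped.
* **Random structure**: random intercepts for pen, hen (nested in pen by
  unique labelling), condition-within-hen (4 levels per direction, one
  per session -- the default reading of the nesting; 8-level pooling
  across directions never arises because models are per-direction), and
  crossed calendar date. The within-session jump index is the finest
  level: for Gaussian models it is absorbed into the residual; for
  binomial models an explicit observation-level intercept is kept by
  default (`jump_re`), configurable.
* **Estimation**: ML for every model comparison (valid likelihood
  ratios), REML refit for the final reported Gaussian model; Laplace
  approximation for the GLMM. Non-convergence is flagged, never silent;
  singular fits (variance components at zero) are allowed and flagged.
* **Parametric bootstrap** (`pb_modcomp()`): `n_sim` responses are
  simulated from the reduced ML fit with *new* random-effect and
  residual/Bernoulli draws, both models are refitted on each, and
  `p = (1 + #{T* >= T_obs}) / (n_ok + 1)` -- the finite-sample correction
  keeps p strictly positive. Refit failures are counted; more than 10%
  invalidates a test. Defaults: 1000 simulations for final analyses, 200
  or fewer in tests and exploratory runs.
* **Backward reduction** (`backward_reduce()`): starting from the full
  three-way factorial, every currently droppable term (one not marginal
  to a retained interaction) is tested; the largest-p term is removed if
  its p exceeds 0.05; marginality is always enforced; one term is removed
  per iteration with full refits in between. The trace records every
  test. Where the order was underdetermined ("stepwise-backwards" admits
  variants), largest-p-first with per-iteration refits was chosen.
* **Effect estimates** (`estimate_effects()`): model-based means per
  retained factor combination, averaging the fixed-effect predictor over
  the remaining design factors with equal weights (the design is
  balanced), with Wald z intervals from the fixed-effect covariance,
  back-transformed to the response scale. Kenward-Roger or Satterthwaite
  degrees of freedom are deliberately out of scope. For responses on a
  transformed scale the package can report both scales; patterns whose
  level means overlap heavily on the response scale (as happens for
  hybrid-by-angle contrasts on inverse-transformed peaks) should be read
  on the transformed scale on which they were tested.
* **Diagnostics** (`simulate_quantile_residuals()`): the observed value's
  mid-rank quantile within posterior-predictive simulations (new
  random-effect draws), uniform under a well-specified model, summarized
  by a KS statistic and deterministic given the seed.

### A fast bootstrap engine

A naive bootstrap refits each model from scratch; at 200 simulations per
test and a dozen tests per reduction that dominates runtime. The default
engine instead builds each model's lme4 deviance function once, swaps the
simulated response into the response module in place, and re-optimizes
the covariance parameters (plus fixed effects for GLMMs) with bounded
BOBYQA started at the parent fit. The test suite cross-checks this
engine against `lme4::refit()` on a small design; the two agree to
optimizer tolerance (and when they differ on hard simulated responses the
devfun engine tends to find the *lower* deviance).

## Numerical choices

* Seeds thread through every stochastic operation; identical
  configuration and seed reproduce datasets and reports byte for byte
  (numbers are written with fixed formats).
* Trace samples are written with 5 decimals (0.00001 G resolution), so
  file round-trips agree to 1e-5 rather than machine precision.
* Transformed-scale draws that would be nonpositive under log/inverse
  transformations are clamped (at 0.02 on the inverse scale); with the
  default variance components this is a > 5 sigma event.
* Rendered samples are clipped to the +/-200 G sensor range with a
  warning and a per-trace clipping flag.
* Windows that land outside a trace raise alignment errors naming the
  phase; corrupted sessions are skipped (and counted) by the extraction
  stage rather than failing the run.

## Problem sizes in the test suite

The suite runs the full 40-hen schedule arithmetic, but simulation-heavy
checks use reduced studies chosen to keep the whole suite comfortably
reproducible on one core: 8-16 hens with 2-4 jumps per session for
pipeline and reduction checks, 50 study-scale replicates for coefficient
coverage, 200 replicates x 200 bootstrap simulations on a 48-observation
single-grouping design for null calibration of the bootstrap test, and
25 replicates for reduction behaviour. `scripts/acceptance.R` runs the
full-scale simulate-extract-analyze loop once.

## Limitations

* The generator emulates the *statistical* structure of the experiment,
  not hen biomechanics: axis signals put the whole magnitude on one axis,
  flapping is a fixed-frequency sinusoid, and responses are drawn
  independently across outcomes given the design. Passing tests show the
  pipeline recovers what the generator encodes; they cannot validate the
  physics of real jumps, orientation effects, or video annotation error.
* Stepwise selection keeps each truly-null term with probability close to
  the exclusion level. With four null interaction terms in the full
  factorial, the chance that *no* interaction survives a reduction is
  about 0.95^4 (roughly 81%), a property of stepwise testing at a fixed
  level, not an implementation artifact; single terms are discarded at
  about the nominal 95% rate. Interpret retained borderline terms
  accordingly.
* Wald z intervals ignore degrees-of-freedom corrections; with eight pens
  the pen-level component is weakly identified and interval coverage for
  coefficients sits slightly below nominal (about 94% at study scale in
  the suite's coverage check).
* Unsuccessful landings (falls/collisions) are out of scope, as is any
  claim linking the computed loads to fracture thresholds.
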