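---
title: "Activity seascapes: models, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity seascapes: models, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seascaper)
```

## The problem

Reef sharks are central place foragers that never stop swimming: they hold
a core area by day and range more widely at night, so "resting" and
"travelling" cannot be separated by whether the animal moves. Two
independent data streams describe this behaviour at very different
resolutions. Animal-borne accelerometers sample body acceleration at 20 Hz
over a few days and resolve *how active* the animal is second by second.
Acoustic telemetry arrays log *where* the animal is, but only when it swims
within range of a receiver, over months to years. An **activity seascape**
fuses the two: a space–time volume of movement probability, weighted
voxel-by-voxel by the probability that the animal is in its high-activity
behavioural state at that time of day.

This vignette documents the models behind each stage, the parameters that
matter, and the numerical decisions taken where the design was genuinely
open.

## From raw acceleration to ODBA

Overall dynamic body acceleration (ODBA) is the sum of the absolute
dynamic (gravity-removed) accelerations on the three axes, a standard
proxy for activity and energy expenditure in fish. The static
(gravitational) component is estimated per axis by a centred box-car
moving average; the default window is 3 s, comfortably longer than a reef
shark tail-beat period (~1 s) and short against postural changes. The
window is configurable because the appropriate value depends on the
species' stroke frequency. At the series edges the window shrinks to the
available samples rather than padding, so no fabricated samples enter the
filter and `static + dynamic` reconstructs the raw signal exactly.

ODBA is then block-averaged to 1-s resolution (non-overlapping means;
trailing partial blocks dropped) and the first 4 h after tagging are
discarded so post-handling stress does not contaminate the behavioural
analysis. Both values are defaults, not constants.

## The two-state hidden Markov model

One-second ODBA is strongly autocorrelated, and that autocorrelation is
informative: how active an animal is now predicts how active it will be a
second from now. We therefore model ODBA with a hidden Markov model whose
latent chain has \(N = 2\) states — state 1, "relatively low activity",
and state 2, "relatively high activity" (including burst events).

* **State-dependent densities.** Gamma, one per state. ODBA is positive
  and right-skewed, and the gamma's shape/rate parameterisation separates
  a calm, low-mean state from a heavier-tailed active state. Exact zeros
  (below-resolution samples) lie outside gamma support; they are replaced
  by half the smallest positive observation and the replacement count is
  reported with the fit.
* **Covariate-driven transitions.** The two off-diagonal transition
  probabilities get logit-linear predictors in hour-of-day harmonics
  (default order 2; order 1 in the synthetic demonstrations, which
  generate from a single harmonic) and treatment-coded tidal phase
  dummies (high water as baseline). This lets the *switching dynamics* —
  not the states themselves — follow the diel and tidal cycles, which is
  what produces smooth diel activity curves.
* **Likelihood and fitting.** The exact likelihood comes from the scaled
  forward recursion (implemented in C++; the recursion is the hot loop of
  the whole package). Maximisation is quasi-Newton (BFGS) over
  unconstrained working parameters: log shape/rate, raw transition
  coefficients, and the initial-distribution logit. The optimiser runs
  from `n_restarts` randomised starting points (default 10; the first
  start is moment-based from a 60th-percentile split of the data) and
  keeps the best converged restart, making the fit deterministic given
  data and seed. Outside the numerically valid region the objective
  returns a large finite penalty rather than `Inf`, which keeps BFGS line
  searches well defined.
* **Label switching.** The likelihood is invariant to swapping the two
  states in every parameter block; the reported fit breaks this symmetry
  by relabelling so state 1 always has the smaller ODBA mean.

Decoding offers both global (Viterbi) and local (forward–backward)
answers; both are returned because bout statistics need the single best
path while per-time activity probabilities need the smoothed marginals.

### The diel activity curve

The probability of being in state 2 at hour \(h\) (tide held fixed) is
taken from the *periodically stationary* distribution of the fitted
inhomogeneous chain: build the 10-min transition matrices around one full
24-h cycle, form the one-cycle product starting at \(h\), and take its
stationary vector. Numerically we compute one stationary vector and
propagate it bin-by-bin (\(\delta_{b+1} = \delta_b \Gamma_{b+1}\));
products of 144 stochastic matrices converge towards rank one, so
inverse-based shortcuts are ill-conditioned while propagation is exact
and stable. Confidence bounds come from a parametric bootstrap (default
1000 draws) of the working parameters from their asymptotic normal
distribution, with percentile intervals.

## Space–time utilization distributions

Acoustic detections are snapped to receiver coordinates (receivers are
omni-directional; positional uncertainty is carried by the location-error
term). Consecutive detections are linked by Brownian bridges in the
standard location-error formulation: at fraction \(\alpha\) of the gap
\(T\) the animal's position is Gaussian with mean
\((1-\alpha)z_a + \alpha z_b\) and per-axis variance
\(\alpha(1-\alpha)T\sigma_m^2 + ((1-\alpha)^2 + \alpha^2)\sigma_{loc}^2\).
The location error defaults to \(\sigma_{loc} = 300\) m (an average
receiver detection range); the Brownian motion variance \(\sigma_m^2\) is
estimated by the leave-one-out likelihood of odd-indexed detections under
the bridges interpolating their neighbours (the held-out detection's own
location error enters that likelihood, without which the estimator is
biased upward).

Bridges are rasterised onto voxels of 100 m × 100 m × 10 min. Each bridge
is cut at the absolute 10-min boundaries it crosses; each segment
contributes its Gaussian slice, evaluated at the segment's midpoint
(single-point quadrature — adequate because the bridge SD changes slowly
within 10 min), discretised exactly through per-axis normal CDF
differences, weighted by the segment's duration, into the time-of-day bin
the segment falls in (timestamps folded modulo 24 h). Choices made where
the method is silent:

* **Gap rule.** No bridge is laid across gaps longer than 12 h
  (`max_gap`): a bridge over a day-long absence asserts knowledge the
  data do not contain.
* **Normalisation.** The default treats the whole volume as one
  probability distribution over space × time-of-day, so bins with more
  tracked time carry more mass; per-slice normalisation is available as
  an option for displays in which each time slice should be read as a
  conditional map.
* **Coordinates** are planar metric; projection happens upstream.

The planar (2-D) UD is the time-marginal, and cumulative-mass cell sets
(`ud_contour`) are built greedily by descending voxel mass with a
deterministic index tie-break — for this objective the greedy set is
provably minimal in cardinality.

## Central places, displacement, and fusion

Two central-place definitions are implemented, matching the two data
densities encountered in practice: the 50% UD contour (for individuals
detected on many receivers), and the receiver that logged ≥ 80% of an
individual's detections with a 1000-m buffer (for individuals detected on
few). The 80% rule is inclusive at exactly 0.80 and ties are broken
lexicographically by receiver id; both conventions are deliberate and
tested. Displacement is the distance from a detection to the *boundary*
of the central place (zero inside it) — "displacement from the central
place" reads most naturally as distance beyond the core, and a centroid
reference would penalise animals inside a large core. Per-individual
displacement series are folded onto hourly diel bins and averaged across
individuals unweighted; a bin is missing only if it is missing for every
individual. Individuals with fewer than 100 detections (boundary
inclusive) are excluded from volume work.

The seascape itself is a voxelwise product: UD voxel × probability of
state 2 at that voxel's time bin, with the hourly activity curve
interpolated cyclically to the 10-min bins. No renormalisation is applied
— the seascape is deliberately *not* a probability distribution but a
movement density weighted by activity, bounded above by the UD.

## Bioenergetics

The grey-reef-shark model composes four closed forms, evaluated hourly:

1. Mass from length: \(W = 0.0045\,L^{3.21}\) (L in cm). The power law is
   evaluated in grams and reported in kg. This is the standard
   length–weight convention and the only reading consistent with
   published average masses (≈ 37 kg at 143 cm); taken at face value in
   kg the formula would give a 37-tonne shark.
2. Routine metabolic rate: \(\log_{10} M = 0.79 \log_{10} W + 2.31\)
   (mg O₂ h⁻¹, the unit convention of the underlying allometry).
3. Q10 temperature correction: \(M \cdot Q_{10}^{(T_b - T_{ref})/10}\),
   with \(T_{ref} = 28.0\,°C\) and \(Q_{10} \in \{1.65, 3.0\}\) spanning
   the range reported for tropical sharks.
4. Speed scaling: the average speed is treated as the optimal travel
   speed, and a 1% change in speed maps to a 1% change in metabolic
   rate, applied to the full routine rate (an active-component-only mode
   is available but off by default) and floored at 50% of the unadjusted
   rate to exclude non-physical values at very low speeds.

Scenario comparisons use a paired t-test on the 24 hourly values,
computed from the closed form \(t = \bar d / (s_d/\sqrt{n})\) so that
identical profiles can be reported as such (with \(t = 0\)) instead of
erroring. The diel body-temperature amplitude is a scenario parameter,
not a constant: field reports differ between a "0.5 °C diel change" and
observed day/night means 0.3 °C apart, so the default scenario uses a
±0.25 °C sinusoid and the amplitude is exposed in the configuration. A
worked consequence of the closed forms, useful as a sanity check: a
symmetric ±0.25 °C cycle at \(Q_{10} = 3\) moves the hourly rate over a
range of \(3^{0.025} - 3^{-0.025} \approx 5.5\%\) of its mean —
about 2.5% at \(Q_{10} = 1.65\) — while the observed 7% diel speed swing
moves it by 7%; and because the temperature cycle is symmetric around the
reference, the paired comparison between observed-temperature and
constant-temperature scenarios is near-null (\(|t| \ll 1\)) at any
plausible \(Q_{10}\). Speed, not temperature, dominates the diel energy
budget.

## Diel sensor profiles

Hourly speed/depth/temperature series are summarised by harmonic
regression — sines and cosines of period 24 h and its first overtones
(default order \(K = 2\)) — with AR(1) errors fitted by full joint
maximum likelihood (via generalised least squares), not a two-stage
plug-in. A harmonic basis was chosen over penalised cyclic splines
deliberately: it is fully specified by \(K\), periodic by construction,
and adequate for the single-peaked diel patterns at issue; `K` is
configurable where more structure is suspected. Fits are compared against
an intercept-only null by AIC, with "improved" requiring ΔAIC strictly
greater than 3 — at the boundary the verdict is "not improved".

## The synthetic-data generator

No field data ship with the package, so the generator produces data with
the statistical structure the pipeline assumes; its defaults *are* the
study conditions used throughout the tests:

* **Track:** positions are a deterministic central-place/excursion target
  plus mean-reverting Ornstein–Uhlenbeck noise (30-min relaxation,
  stationary SD one third of the 500-m day radius, clamped at the day
  radius). By day the target is the central place; during the 20:00–08:00
  excursion window it moves along a per-night random bearing out to
  3000 m and back following a half-sine, peaking at 02:00. This is the
  simplest process that reproduces day-confined residency with nocturnal
  round trips; it is not a behavioural model (no habitat, no memory, no
  speed–turning structure).
* **Detections:** one candidate ping per 120-s interval; each receiver
  within its 300-m detection range logs it independently (probability 1
  by default, linear distance decay optional), recording the receiver's
  coordinates. The demonstration array is a 500-m grid over the core plus
  receiver rings at 1.5, 2.25 and 3 km so that every excursion bearing is
  detectable — denser than a field array, which keeps desk-scale runs
  informative at 30 days where a field study accumulates years.
* **ODBA:** drawn from the same gamma-HMM family the fitter assumes
  (night-elevated switching into state 2), which is exactly what makes
  simulation-recovery tests meaningful and is also their limitation: they
  validate the estimator, not the model's adequacy for real sharks.
* **Tides:** a fixed 12.42-h M2 cycle split into four equal phases
  anchored at a reference high water; no tidal-height realism.

Passing tests on these data demonstrate that every algorithmic step does
what it claims under the model's own assumptions. They cannot demonstrate
robustness to ODBA families other than gamma, non-harmonic diel patterns,
heterogeneous receiver performance, or position-dependent detection loss
— all known gaps between the generator and field data.

## Verification problem sizes

The package verifies itself at sizes chosen to make every oracle exact or
statistically sharp while staying desk-scale: path-enumeration oracles at
series lengths ≤ 12 (2¹² paths); parameter recovery at 50 000
observations with two optimiser restarts; the analytic activity curve
against a 10⁶-step simulation whose validation spec uses mirrored
transition logits (identical transition rows), making hourly state counts
exactly binomial so the 3σ binomial yardstick is the correct one — and,
because 24 simultaneous 3σ checks false-alarm for roughly 6% of seeds even
for an exact curve, the all-hours bound is required to hold in the
majority of three fixed replicates rather than in one; bridge
moments against 10⁵ conditioned-random-walk draws; and a 30-day,
one-individual end-to-end run. The end-to-end checks (≥ 60% of daytime
seascape mass inside the central place; 02:00 displacement more than
twice the 12:00 displacement; higher nocturnal spatial entropy) are
properties of the generator's study conditions, fixed before the
pipeline is run, not tuned afterwards.

## Known limitations

* Two states only; no observation-level covariates on the state
  densities; individuals are fitted separately or pooled, never jointly
  with random effects.
* The Brownian bridge variance is behaviour-independent (no dynamic
  BBMM), and volumes are 2-D space × time-of-day — depth is a covariate
  elsewhere, not a UD dimension.
* Bridge rasterisation uses midpoint quadrature per 10-min bin;
  configurable refinement is available but rarely needed at 100-m cells.
* The bioenergetics model is deliberately relative: no daily ration, SDA,
  growth or waste terms — it ranks drivers of diel variation, it does not
  estimate absolute energy budgets.
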