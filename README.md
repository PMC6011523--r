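# seascaper

Activity seascapes for marine predators that never stop swimming:
R tools that fuse **when animals are active** (from accelerometry) with
**where they are** (from acoustic telemetry) into a single space–time
picture, plus the surrounding central-place, diel-profile and
bioenergetics analyses.

The package is aimed at movement ecologists working with reef sharks or
similar central place foragers tracked on fixed receiver arrays, but
every stage is generic: any 1-s activity series and any detection table
with planar receiver coordinates will do. Because field deployments of
this kind are rarely shareable, the package also ships a synthetic-data
generator that emulates the whole observation process (central-place
movement, range-limited detections, covariate-driven activity), so the
full pipeline can be exercised and verified end to end on a laptop.

## What it computes

1. **ODBA** — overall dynamic body acceleration from raw tri-axial
   20-Hz accelerometry: gravity removed by a centred moving average,
   `odba = |dx| + |dy| + |dz|`, block-averaged to 1 s, first 4 h trimmed.
2. **A 2-state hidden Markov model** for 1-s ODBA with gamma
   state-dependent densities and logit-linear diel-harmonic + tidal-phase
   covariates on the transition probabilities
   (`γ12(t) = logit⁻¹(η12ᵀx_t)`, likewise 2→1). Exact forward-recursion
   likelihood (C++), multi-start BFGS fitting, Viterbi and
   forward–backward decoding, dwell-time and occupancy summaries, and the
   diel **activity curve** `P(state 2 | hour, tide)` from the periodically
   stationary distribution of the fitted cycle of transition matrices,
   with parametric-bootstrap confidence bands.
3. **Space–time utilization distributions** — Brownian bridges with
   location error (`σ_loc = 300` m default) between consecutive
   detections, motion variance `σ_m²` by leave-one-out maximum
   likelihood, rasterised into 100 m × 100 m × 10 min voxels folded onto
   the 24-h cycle; planar UDs, 50% contours, central places (UD contour
   or dominant-receiver + 1000-m buffer), and diel displacement series.
4. **Activity seascapes** — the voxelwise product
   `UD(x, y, τ) × P(state 2 at τ)`.
5. **Bioenergetics** — `W = 0.0045 L^3.21` (g → kg),
   `log10 M = 0.79 log10 W + 2.31` (mg O₂/h), Q10 temperature correction,
   1%-speed-to-1%-rate scaling, hourly profiles, paired t-test between
   scenarios.
6. **Diel sensor profiles** — cyclic harmonic regression with AR(1)
   errors (full ML) and a strict ΔAIC > 3 improvement rule.

## Worked example

```r
library(seascaper)

res <- run_pipeline(pipeline_config(seed = 1), outdir = "demo_out")

res$fit
#> 2-state gamma HMM fit (72000 obs)
#>   state 1: shape 2.006 rate 20.06 (mean 0.09999)
#>   state 2: shape 4.867 rate 9.679 (mean 0.5028)
#>   logLik 62543.376  AIC -125064.752  zeros replaced 0

round(range(res$curve$p_state2), 3)
#> [1] 0.057 0.565

ds <- res$displacement
ds[ds$hour %in% c(2, 12), ]
#>    hour      mean_m    n
#> 3     2 2370.397040  927
#> 13   12    0.480974 1045
```

Reading the output: the fitted HMM separates a calm state (mean ODBA
≈ 0.10 g) from an active state (≈ 0.50 g); the diel activity curve ranges
from a 5.7% probability of the active state (midday) to 56.5% (night);
and the simulated shark sits essentially on its central place at noon
(mean displacement 0.5 m) while averaging 2.37 km away at 02:00 — the
classic central-place-forager signature the seascape then maps in space
and time. `demo_out/` receives every artifact as CSV/JSON (ODBA series,
HMM fit, activity curve, UD volume, seascape volume, displacement series,
energetics report) plus a provenance file with the config hash and seed.

A thin CLI over the same functions lives at `inst/cli/seascaper.R`
(subcommands `simulate`, `odba`, `fit-hmm`, `ud`, `seascape`,
`displacement`, `energetics`, `run-all`).

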