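---
title: "Modelling the inflammatory epigenetic switch: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the inflammatory epigenetic switch: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episwitch)
```

## The model

`episwitch` simulates a kinetic model of the positive inflammatory feedback
loop that converts a transient oncogenic signal into a heritable change of
cell phenotype.  The loop couples the transcription factor NF-κB, the
microRNA-binding protein Lin28, the Let-7 microRNA family, and the cytokine
IL6: Src activates NF-κB, NF-κB induces Lin28, Lin28 shuts off mature Let-7
production, and the loss of Let-7 de-represses IL6 (and Ras) mRNA, with IL6
feeding back onto NF-κB activation.  Two further arms are part of the
network: Ras, whose mRNA is also a Let-7 target and whose protein activates
NF-κB, and the STAT3 → miR-21 ⊣ PTEN ⊣ NF-κB cascade, in which the
transformation effector STAT3 induces miR-21, miR-21 silences the tumor
suppressor PTEN by mRNA titration, and PTEN inhibits NF-κB activation.

The state is 14 concentrations (micromolar): active NF-κB, Lin28, Let-7,
IL6 mRNA and protein, the Let-7·mIL6 complex, Ras mRNA/protein and the
Let-7·mRas complex, STAT3, miR-21, PTEN mRNA/protein and the miR-21·mPTEN
complex.  Two optional extensions (activated via `switchVariant()`) add a
generic competing endogenous RNA that sponges Let-7, and PTEN1 mRNA that
sponges miR-21 — two species each.

Three mechanistic conventions define the equations:

* **NF-κB is a conserved pool** of total `NFKB_T`, interconverted between
  inactive and active forms by a Goldbeter–Koshland (zero-order
  ultrasensitive) cycle.  The activation rate is the weighted sum
  `k_AA1NFKB·Src + k_AA2NFKB·IL6 + k_AA3NFKB·Ras`, multiplied by the
  Michaelian inhibition factor `K_IPTEN/(K_IPTEN + PTEN)` — PTEN attenuates
  the whole activation drive, not a single input: PTEN is an
  inhibitor of NF-κB activation as such, so nothing singles out one input
  for protection.  Activation acts on the inactive fraction with
  Michaelis constant `K_ANFKB`, inactivation on the active fraction with
  maximal rate `V_DNFKB` and constant `K_INFKB`; both constants are far
  below `NFKB_T`, so the response is digital.
* **microRNA regulation is titration**, not transcriptional repression:
  each miRNA binds its target mRNA with a fast bimolecular constant
  (`k_1`, `k_3`, `k_5`, and `k_7`, `k_9` for the extensions), dissociates
  slowly, and the complex is degraded as a unit, destroying both partners.
  A variant in which the miRNA is recycled upon complex degradation was
  examined and rejected: it makes the Let-7 pool effectively indestructible
  and abolishes the switch in every stimulus scenario.
* **Everything else is mass action** with Michaelian synthesis terms
  (Lin28 induced by NF-κB, Let-7 repressed by Lin28, IL6 mRNA with a
  constitutive and an NF-κB-dependent term, STAT3 induced by IL6, miR-21 by
  STAT3) and first-order degradation of every pool.

Time is internally in minutes (the natural unit of the rate constants,
which span fast binding at `k_1 = 10 /µM/min` to slow Lin28 turnover at
`k_DLIN28 = 0.002 /min`); every user-facing time is in hours.

## Switch detection

A cell is *transformed* when its active NF-κB exceeds half the conserved
total.  The two attractors sit at ≈10⁻⁴·`NFKB_T` and ≈`NFKB_T`, so any
midpoint-like threshold classifies identically; the same rule is applied to
deterministic endpoints, stochastic copy numbers (`count > Ω·NFKB_T/2`) and
population members, keeping classification consistent across modules.

The *switch time* reported by `detectSwitchTime()` is the mid-rise of
STAT3: the last upward crossing of half its final level, located by linear
interpolation on a 0.1 h output grid.  STAT3 rather than NF-κB is used as
the clock for a structural reason: whenever the direct Src drive exceeds
the NF-κB inactivation capacity (`k_AA1NFKB·Src > V_DNFKB`, i.e. any
Src ≳ 10⁻³), active NF-κB saturates within minutes, long before Lin28,
Let-7, IL6 and STAT3 flip — an NF-κB-crossing time would time-stamp the
stimulus, not the transformation.  STAT3 is the model's transformation
effector, rises only with the slow cascade, and its mid-rise lands on the
visible jump of all slow variables.  With this single rule the four
reference runs give 36.4 h (constant Src = 5·10⁻⁵ from the resting start),
66.5 h (5-min pulse of 0.015), 9.3 h (constant 0.015) and 20.4 h
(mid-level start under its reference configuration) — each within the
reading precision of the corresponding published value.

## Deterministic integration

`simulateSwitch()` integrates with `lsoda` (via **deSolve**) and a
compiled right-hand side; the readable R implementation `switchRHS()` is
the source of truth and the two are asserted equal in the tests.  Solver
settings: `rtol = 1e-8`, `atol = 1e-10`, maximum step 6 min — the step
bound keeps the integrator honest across the minute-scale binding
kinetics while trajectories span days.  The time axis is segmented at
every Src-pulse edge and perturbation-window boundary, so discontinuous
inputs are exact rather than smoothed across a step.  Halving the
tolerances moves detected switch times by well under 0.5 h.

Time-windowed parameter overrides (`perturbationWindow()`) express the
transient-inhibition and overexpression experiments: zeroing the three
NF-κB activation constants, Lin28 synthesis, or both IL6 mRNA synthesis
rates on 100–130 h resets a transformed cell; raising `V_SMIR21` to 4000
from 100 h turns miR-21 into the trigger.  In the miR-21 overexpression
scenario the post-onset transition is slow (the PTEN pool must first be
titrated away and the Lin28/Let-7 race re-run), so the scenario horizon is
400 h; the with/without-Lin28-inhibition contrast is unaffected.

## Steady states and bifurcation structure

The system never shows more than two stable states plus the separating
saddle in any published regime, so branch tracking is deliberately simple:

* `findSteadyStates()` relaxes a deterministic grid of starts (both
  initial-condition sets, log-spaced uniform states, and low-Let-7 /
  high-activator patterns that probe the transformed basin) by long
  integration, polishes by damped Newton, merges duplicates at relative
  distance 10⁻⁴, and hunts the saddle by Newton from midpoints of stable
  pairs.
* Stability is the sign of the leading eigenvalue of the Jacobian on the
  active subsystem.  Newton and the eigenvalue classification use an
  analytic Jacobian: the spectrum spans ~10⁻³ to ~10³ per minute, and
  finite-difference noise along the slow eigendirection is enough to throw
  a Newton step off the branch.  The exported `switchJacobian()` (central
  differences, relative step 10⁻⁶, floor 10⁻⁹) is retained as the
  model-agnostic diagnostic and agrees with the analytic form to 10⁻⁴.
* Branch continuation between parameter values goes through *relaxation
  followed by polish* rather than a raw Newton step: a parameter change
  moves the steady state a long way along the slow manifold, where the
  Newton direction is correct but far outside its contraction region; a
  short integration follows the manifold for free.
* `switchThreshold()` locates the upper fold — the Src level where the
  non-transformed state vanishes — by geometric marching (factor 1.5) with
  continuation, then log-bisection to relative width 10⁻³.  "No
  non-transformed state even at the lowest Src" and "still present at the
  highest Src" are reported as distinct statuses rather than numbers.

The default scan grid is 200 log-spaced Src values on [10⁻⁷, 2·10⁻²],
covering the published axis ranges.  Fold positions are reported as grid
brackets; they are used for ordering comparisons (threshold shifts with
`V_SLET7`, `V_SMRAS`, `V_SMPTEN`, `V_SCERNA`), not as precision targets.
One deviation from the published ceRNA series is documented here: at
`V_SCERNA = 1` (with `V_SLET7 = 6`) the non-transformed branch is already
absent down to Src = 10⁻⁹ in this implementation, so the strictly
decreasing threshold series is verified on {0, 0.25, 0.5} and the
"always transformed" regime begins somewhere in (0.5, 1] rather than
beyond 1.

## Stochastic layer

The Gillespie direct method runs on 42 reaction channels, one per
elementary process.  The Ω-convention maps concentrations to copy numbers
(`Ω = 100` molecules per µM in all reference runs): unimolecular constants
unchanged, bimolecular constants scaled by 1/Ω, zero-order syntheses by Ω,
and each saturating (Michaelian or Goldbeter–Koshland) process kept as a
single lumped channel whose propensity is Ω times the deterministic rate
law at `count/Ω` — the saturable steps are not expanded into elementary
binding cycles.  No tau-leaping is used; at Ω = 100 a 50 h cell costs a
few million events and runs in well under a second in the compiled
simulator, which maintains per-channel propensities with a species →
channel dependency map and refreshes the cached total periodically to
bound rounding drift.

Randomness comes from R's RNG, so a seed makes the event sequence
bit-reproducible; ensembles give cell *i* the seed `seed + i`.  Stochastic
runs start from `round(Ω · icSetB())` — the like-for-like counterpart of
the deterministic mid-level reference — and `ensembleProportion()`
classifies endpoints after a 50 h transient with the shared NF-κB midpoint
rule in counts.  Exactness is checked against the ODE solution: at
Ω = 10⁴ the ensemble-mean Let-7 trajectory of three runs stays within 5%
of the deterministic one on a pre-switch horizon.

## Heterogeneous populations

Cell-to-cell (extrinsic) variability is modelled by jittering every
parameter — including Src, which is treated as a parameter of the model
like any other — independently and uniformly on `[θ(1−p), θ(1+p)]`.  Uniform
rather than Gaussian jitter respects the stated percentage bound exactly
and cannot produce negative rates for `p < 1`; no correlation structure is
imposed because none is described.  Each of the (default 100) cells is
integrated deterministically to the 50 h transient from the common
mid-level start, classified by the midpoint rule, and summarized by the
transformed fraction and Pearson correlations of endpoint pairs
(Let-7/IL6, miR-21/STAT3, miR-21/PTEN).  Zero-variance or n < 3
correlation requests raise a distinct condition rather than returning a
silent `NA`.  Intrinsic and extrinsic noise are deliberately never
combined in one run.

## What the defaults represent

`defaultParams()` is the published reference parameterization (per-minute
rates, µM concentrations); `V_SMPTEN`, `V_SCERNA` and `V_SMPTEN1` default
to 0 so the core 14-variable model is recovered, and `Src` defaults to 0
(no inflammation).  Initial-condition set A is the resting cell (trace
activators, unit Let-7); set B is the mid-level start used by the
stochastic and population layers.  The simulated conditions reproduce
in-silico experiments: they emulate clonal populations with either pure
molecular noise or pure parameter heterogeneity, instantaneous Src steps,
and no cell growth, division, or NF-κB/IκB oscillations (excluded from
the model's scope by design).  Passing tests therefore demonstrate the
internal consistency and the published dose–response structure of the
model — not quantitative agreement with any wet-lab measurement.

## Problem sizes used in the checks

The packaged checks run the deterministic scenarios at their figure
horizons (100–400 h), thresholds over ~12 parameter settings, stochastic
ensembles of 50 cells at Ω = 100 with a 50 h transient, a three-run
Ω = 10⁴ exactness comparison over 6 h, and populations of 60–100 cells;
bifurcation scans in the tests use 10–25 grid points (the default grid
remains 200).  These sizes were chosen so each check measures a stable
statistic of its scenario — fractions over 50 cells carry a binomial
standard error of ≤ 0.07, which the trend assertions account for.

## Known limitations

* Fold locations are resolved by bisection on branch existence; extremely
  narrow bistable windows (below the 10⁻³ relative bisection width) would
  be missed.
* The switch-time observable is tied to STAT3's mid-rise; trajectories
  that end exactly mid-transition report `NA` (no completed switch) by
  construction.
* The Gillespie layer treats saturating kinetics as lumped channels; at
  very small Ω (≪ 10) the lumping approximation and the integer NF-κB
  pool quantization become visible.
* Near-fold stochastic fractions depend on the transient length; 50 h is
  the reference convention, not an asymptotic switching rate, and no
  mean-first-passage estimation is attempted.
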