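---
title: "Methods: the modified LR1 model, its protocols and measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the modified LR1 model, its protocols and measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`cardiowave` simulates the 1991 Luo–Rudy (LR1) guinea-pig ventricular action
potential, extended in two ways that are the scientific focus of the package:

* a **fast transient-outward potassium current** in the Mahajan rabbit-model
  formulation, `Ito,f = Gtof · xtof · ytof · (V − Etof)`, with activation
  `xtof` and inactivation `ytof`;
* **multiplicative scale factors `kd`, `kf` on the L-type calcium gate time
  constants** `tau_d(V)` and `tau_f(V)`.  Values below one accelerate the
  slow-inward current `ISi`; `kd = kf = 0.3` means "30% of the control time
  constant".  Steady states are never rescaled.

The membrane equation is `dV/dt = −(Iion − Istim)/Cm` with
`Iion = INa + ISi + IK + IK1 + IKp + Ib + Ito,f`; a positive `Istim`
depolarizes.  In tissue the voltage additionally diffuses:
`∂V/∂t = −Iion/Cm + D (∂²V/∂x² + ∂²V/∂y²)` with no-flux boundaries.  All
conductances are in mS/cm²; with `Cm = 1` µF/cm² these are numerically
identical to mS/µF, and the two unit spellings are interchangeable
throughout.

The LR1 rate functions, the `ESi(Cai) = 7.7 − 13.0287 ln Cai` pseudo-Nernst
potential and the calcium balance
`dCai/dt = −10⁻⁴ ISi + 0.07 (10⁻⁴ − Cai)` follow the original LR1
formulation with `[K]o = 5.4` mM; the sodium conductance is `GNa = 16`
mS/cm², which together with `D = 0.001` cm²/ms gives a planar conduction
velocity of ≈ 0.55 m/s (the package measures 0.553 m/s on a 400-site
cable).  Every rate function is cross-checked in the test suite against an
independent plain-R transcription.

### The Ito,f reversal potential

The source formulation pins `Ito,f` to "EK" without saying which of LR1's
two potassium reversals is meant: the time-dependent-K reversal
(−77 mV, which folds in a small sodium permeability) or the pure potassium
Nernst potential (≈ −87.9 mV at `[K]o = 5.4`, `[K]i = 145` mM).  The choice
matters: with −87.9 mV the spike-and-dome morphology collapses to early
repolarization already near `Gtof ≈ 0.25` and the cell shows **no** APD
alternans at `Gtof = 0.268`; with −77 mV the dome survives to
`Gtof ≈ 0.30`, the cell alternates at `Gtof = 0.24–0.29` at PCL 500 ms, and
at `Gtof = 0.268` alternans is present at PCL 600 ms and eliminated at
PCL 1200 ms — the published phenomenology.  The package therefore defaults
to `Etof = −77` mV.  This identification was made from the alternans
behaviour, and it leaves the measured early-repolarization threshold at
≈ 0.300 rather than the published 0.278 (about 8% high); the residual is
consistent with the generally longer action potentials of the source
model's variant (its restitution curves reach ≈ 450 ms where this
implementation saturates near 372 ms) and is reported as measured, not
adjusted.

## Numerics

* **Integration**: explicit forward Euler for `V` and `Cai`, Rush–Larsen
  exponential updates for all eight gates, evaluated at the pre-step
  voltage.  Rush–Larsen is exact under voltage clamp and keeps every gate in
  `[0, 1]` unconditionally.  The working step is `dt = 0.01` ms
  (`dt = 0.02` ms for the large 2D classification runs; halving `dt`
  changes a paced APD by well under 1 ms, which the suite asserts).
* **Rate lookup tables**: the heavy integrators tabulate gate steady
  states, Rush–Larsen factors and the voltage-only current factors on a
  0.02 mV grid over −130…100 mV with linear interpolation.  The exact-rate
  path remains available (`simulate_cell(exact = TRUE)`) and agrees with
  the tabulated path to < 1 mV along a full AP.  Gate deviations from
  steady state are snapped to zero below 10⁻²⁴ to keep quiescent tissue out
  of denormal arithmetic (a pure performance guard, three hundred orders of
  magnitude below physiological resolution).
* **Diffusion**: 5-point Laplacian with conservative zero-flux ghost nodes
  (boundary-value copy); the explicit stability bound `dt < dx²/(4D)` (0.039 ms at
  defaults) is enforced at call time.  A point release reproduces the 2D
  heat kernel to < 1% and the spatial mean is conserved to 10⁻¹⁰ per step.
* **Degenerate inputs**: non-positive `Cai` (the `ESi` log), unknown gate
  names, non-finite voltages, sub-3-site grids and stability-violating
  steps raise errors; numerical blow-up aborts a run with the time of
  failure rather than returning garbage.

## Protocols (the synthetic-data layer)

All inputs are generated, never read from data files:

* **Pre-pacing**: the reference conditioning is 1000 beats at PCL 500 ms;
  the beat-to-beat APD change converges below 0.1 ms by 50 beats, so the
  bundled experiments and tests use 50 (the suite asserts 50 ≈ 1000 within
  2 ms).  Tissue runs copy the end-of-pacing state into every lattice site.
* **Stimulus**: rectangular pulse, 1 ms × 60 µA/cm² — about twice the
  diastolic threshold (28.7 µA/cm², found once by bisection and frozen in
  `default_stimulus()`).
* **Restitution**: S1S2 by default (20 S1 beats at PCL 500 ms; one S2 per
  diastolic interval, every DI branching from the same saved
  post-repolarization state).  The DI is measured from the last S1 crossing
  of −75 mV to the S2 onset, consistent with the APD definition
  (`V > −75` mV, crossings linearly interpolated).  A dynamic-pacing mode
  is available behind `method = "dynamic"`.
* **Cross-field induction**: a plane wave from a 5-column strip on the left
  edge; once the centre cell has depolarized above −55 mV and fallen back
  below it, the bottom half of the sheet (rows `≥ ny/2`, y increasing
  downward) is clamped to exactly −30 mV for 2 ms, then released.
* **Morphology pacing**: the phase-1 notch deepens markedly with rate
  (control notch +3.3 mV at PCL 500 ms vs +8.7 mV at PCL 2000 ms) because
  the `x` gate and `Cai` recover over hundreds of ms.  The published
  control notch ("about 10 mV") is only attained at slow pacing, so the
  notch acceptance runs pace at PCL 2000 ms — the cycle length its
  companion tissue experiments state — while the early-repolarization
  threshold keeps PCL 500 ms.

## Measurements

* **APD / alternans**: suprathreshold episodes above −75 mV; alternans is a
  sustained mean successive difference > 5 ms with strictly alternating
  sign.
* **Morphology**: notch = first local minimum after the upstroke peak
  within the first half of the APD; dome = a later local maximum at least
  5 mV above the notch; early repolarization = no dome and APD below half
  the Ito-free reference.  The 50% window, the 5 mV prominence and the 50%
  APD fraction are fixed documented conventions standing in for a visual
  reading.
* **Phase singularities**: time-delay embedding with `V* = −30` mV and a
  2 ms lag; tips are plaquettes whose wrapped phase differences wind by
  ±2π.  Signed chirality sums are tracked per frame.
* **Dynamics classes**: `no_wave` (no tip at the end), `breakup` (≥ 4 tips
  sustained for ≥ 500 ms), `stable` (a single tip whose core stays within a
  0.5 cm box after a 500 ms post-induction transient), else
  `quasiperiodic`.  All constants are explicit arguments; the
  stable/quasiperiodic boundary is our convention — the source calls are
  visual.
* **Pseudo-ECG**: the infinite-medium integral
  `φ = Σ ∇V · ∇(1/|r − r_probe|) dA` with unit gain, evaluated against a
  brute-force oracle in the tests.  Probe geometry (0.5 cm beyond the right
  and top edges in-plane; 1.0 cm above the centre; bipolar pair 0.1 cm
  apart) is conventional, so amplitudes are arbitrary units and only shape
  and irregularity (sample entropy, dominant-power fraction) are compared.

## Problem sizes and what reduced scale can and cannot show

The source experiments run on a 1024² sheet (12.8 cm at `dx = 0.0125` cm).
Estimated wavelengths `λ ≈ CV × APD` for the key parameter sets:

| Gsi | Gtof | kd = kf | APD (ms) | λ (cm) |
|-----|------|---------|----------|--------|
| 0.01 | 0 | 0.3 | 62 | ≈ 3.4 |
| 0.03 | 0 | 0.3 | 98 | ≈ 5.4 |
| 0.08 | 0 | 0.3 | 192 | ≈ 10.6 |
| 0.09 | 0 | 0.3 | 218 | ≈ 12.0 |
| 0.09 | 0.51 | 0.3 | 65 | ≈ 3.6 |

The packaged classification runs use 256² (3.2 cm) and 192² (2.4 cm)
sheets with `dt = 0.02` ms and horizons of 1–2.5 s, sized so the whole
suite completes on one CPU in minutes.  Consequences, measured and
reported rather than hidden:

* short-wavelength spirals (`Gsi = 0.01`, and `Gsi = 0.09, Gtof = 0.51`)
  rotate stably at 256²;
* the `Gsi = 0.03` breakup case fragments (multiple tips appear) but the
  wavelets extinguish within ~1 s because the domain holds fewer than one
  wavelength — sustained breakup chaos needs several wavelengths of room;
* long-wavelength stable spirals (`Gsi ≥ 0.08`, `Gtof` small; the τ-scale
  0.1/0.2 breakup onsets with APDs of 0.5–1.2 s) cannot re-enter at all on
  these domains and the wave leaves the sheet (`no_wave`).

Passing reduced-scale tests therefore demonstrate induction, tracking and
classification machinery plus the short-wavelength phenomenology; they do
not certify the full-scale breakup phase diagram, whose boundaries are
domain-size sensitive.  `run_spiral`/`run_sweep` accept full-size grids
(`nx = ny = 1024`, `dt = 0.01`, horizons of several seconds) unchanged when
hours of compute are available.

## What the generator emulates — and does not

The protocol layer reproduces the source study's computational conditions:
deterministic, homogeneous, isotropic monodomain tissue with identical
cells.  It does not emulate features of real myocardium such as cellular
heterogeneity, fiber anisotropy, electrotonic loading by bath or torso,
stochastic channel gating, or concentration homeostasis beyond LR1's single
calcium pool — conclusions about real tissue inherit all the idealizations
of the source model class.

## Design choices on genuinely open points

* **Restitution protocol type** (unstated in the source): S1S2, because the
  published curves plot APD against DI; dynamic pacing is provided behind a
  flag.
* **Sign convention** of the printed membrane equation: read as
  `dV/dt = −(Iion − Istim)/Cm` with positive depolarizing stimulus; an AP
  is elicited from rest within 5 ms, which the suite asserts.
* **Tip-detection method** (none given in the source): voltage time-delay
  embedding, the standard choice when only voltage fields are available.
* **CV measurement** (method unstated): two interior sensors in the middle
  half of the cable, upstroke = interpolated crossing of −40 mV.
* **`resting_state`** polishes the relaxed state to the exact fixed point
  (gates at `y_inf(V)`, `Cai` balancing its ODE, `V` a root of `Iion`), so
  rest really is invariant under stepping to machine precision.

## Known limitations

* The early-repolarization threshold is measured at ≈ 0.300 mS/cm² against
  a published 0.278 (see the reversal-potential discussion above).
* Explicit-FD conduction velocity is `dx`-dependent; at `D/4` the measured
  CV ratio is 0.452 rather than the asymptotic 0.5.
* Reduced-grid dynamics labels shift for wavelengths comparable to the
  domain, as quantified above.
* Pseudo-ECG amplitudes are arbitrary units by construction.
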