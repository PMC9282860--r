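---
title: "Ghost-state working memory in receptor polarity: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ghost-state working memory in receptor polarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ghostnav)
```

This vignette is the package's account of the science it implements: the
models, the estimators, the numerical choices, and — importantly — where
the design was genuinely open and what we decided.

## 1. The signaling model

The polarity circuit couples the EGF receptor to two dephosphorylating
enzymes. Four species live on a one-dimensional circular membrane of
radius `R = 2` µm split into 20 equal bins:

* `Ep` — ligandless, phosphorylated receptor (diffusing, noisy);
* `EEp` — liganded phosphorylated receptor (immobile, `D_EEp = 0`);
* `RGa` — active PTPRG, a membrane phosphatase in double-negative
  feedback with the receptor (diffusing);
* `N2a` — active PTPN2, an ER-bound phosphatase in negative feedback,
  slower than the phosphorylation cycle by the factor
  `epsilon = 0.01`.

Mass is conserved: the totals `Et`, `RGt`, `N2t` are parameters, and
`Et` — the receptor concentration at the membrane — is the bifurcation
parameter of the whole story. The reaction terms are mass-action
(autonomous `alpha1`, autocatalytic `alpha2` and liganded-driven `alpha3`
activation of the unphosphorylated pool; dephosphorylation `gamma1`,
`gamma2`; phosphatase regulation `beta1`, `beta2`; ligand
binding/unbinding `kon`, `koff`, with half the unbinding flux returning
to `Ep` because an unbinding dimer releases one phosphorylated monomer).
The calibrated default rate set is stored in `signaling_params()`.

Numerics: explicit Euler–Maruyama with `dt = 0.01` min; periodic
central-difference Laplacian on the bin ring; additive noise
`sigma * dW` only on the `Ep` equation. The printed noise description
(amplitude 0.02, increments of variance 0.01 = `dt`) identifies `dW` as a
standard Wiener increment, so the scheme is ordinary Euler–Maruyama and
noise intensity is `dt`-invariant. PTPN2 is treated at quasi-steady state
by default (`n2a_mode = "qss"`); the full slow equation is available, and
the two agree exactly in steady conditions and to roughly 10% RMS during
a one-hour gradient transient — the slow variable genuinely lags its
quasi-steady value at `epsilon = 0.01`, so tighter agreement should not
be expected there.

Species are clipped into their invariant boxes after each step and clip
events are counted. At the basal state `Ep` is only ~0.003 while the
per-step noise s.d. is 0.002, so sub-zero excursions of the `Ep`
equation are a percent-level (not a 0.1%-level) event; `clip_fraction`
reports the realized rate (~0.6% of species-bin-steps on a criticality
run).

**Ligand bookkeeping.** Free ligand enters the binding terms as
`EGFt - EEp` per bin (bin-local depletion). Whether the published
simulations depleted ligand bin-locally or from a well-mixed pool is not
stated; bin-local is the faithful one-dimensional reading and a global
variant would only matter for strongly asymmetric binding.

**Stimuli.** `stimulus_protocol()` composes non-overlapping segments:
uniform doses and wrapped-Gaussian gradients with linear-in-time
amplitude/width schedules ("dynamic" gradients), including two
simultaneous opposed sources. The standard templates
(`make_stimulus_protocol()`) encode the experimental timings: a 60-min
gradient starting at t = 5 min, the 5-h dynamic migration gradient whose
steepness halves, and the triple-field sequence (dynamic → interruption →
static same-direction → interruption → dynamic opposite). Template
amplitude (`A = 0.1` in the model's concentration units) and angular
width (1.0 rad) are package choices — the gradient amplitudes used in the
published simulations are figure-only — selected once so that a cell at
criticality polarizes robustly within the one-hour protocol.

## 2. Where the regimes live: the two-compartment projection

The four regimes of the receptor total are statements about the
bifurcation diagram of the **front/back projection**: two compartments
exchanging `Ep` and `RGa` linearly (exchange coefficients 0.02/min, the
dimensionless lateral-coupling value), each carrying the reduced
two-variable reaction dynamics with PTPN2 at quasi-steady state and no
ligand. The homogeneous curve admits a closed-form parametrization (the
uniform `Ep` balance is quadratic in `Et - Ep`), so
`scan_bifurcation_diagram()` sweeps the whole S-shaped symmetric branch
in one pass, evaluates stability from the analytic 4×4 Jacobian, and
locates the pitchfork from the odd-mode criterion: at a symmetric state
the Jacobian has block structure `[[A, B], [B, A]]`, and the
antisymmetric (front ≠ back) perturbation goes unstable where
`det(A - B) = 0`. The polarized branch is continued by pseudo-arclength
with a secant predictor from a Newton-refined asymmetric fixed point.

With the default parameters: pitchfork at `Et ≈ 2.096` (on the
homogeneous curve), stable polarized window `Et ∈ [1.267, 1.357]`. Hence

* `Et = 1.10` — basal: only the low homogeneous state; a gradient
  polarizes the cell transiently, washout collapses it immediately;
* `Et = 1.26` — **criticality**: 0.007 below the saddle-node; after
  washout the trajectory is trapped in the ghost of the just-vanished
  polarized state for tens of minutes (≈ 70 min deterministic for the
  standard protocol) before snapping back;
* `Et = 1.35` — stable polarized: a transient gradient switches the
  system permanently onto the polarized branch;
* `Et = 1.85` — pre-activated: the high homogeneous state, uniformly
  phosphorylated, with no stimulus-locked polarization.

Because the polarized states coexist with the homogeneous state below
the pitchfork, the pitchfork is subcritical; this is certified
independently by the weakly nonlinear (Stuart–Landau) expansion of the
nondimensionalized reduced system: `nondimensionalize()` rescales by
`t0 = 1/(k1+k2)`, `E0 = k1/beta2`, `RG0 = (k1+k2)/gamma1`, expands the
slow-phosphatase term quadratically about the dimensionless steady state,
and `stuart_landau_coeffs()` evaluates the quintic amplitude equation;
`c2 > 0` and `c3 > 0` at the operating point. The leading wavenumber
defaults to mode 1 of the ring, `km = 1/R`; the printed analysis calls it
"the fastest growing mode" without a value, and the subcriticality
classification is insensitive to `km` of order one (it flips only for
`km` an order of magnitude smaller, where the expansion's denominators
approach resonance). The amplitude-equation fold and the 4-ODE
saddle-node agree in order of magnitude only — the expansion is an
asymptotic approximation — and the package asserts nothing tighter.

**A deliberate inconsistency to know about.** The 20-bin spatial model
and the two-compartment projection do not place their folds at the same
`Et`: mode-1 perturbations on the ring are damped by `D (m/R)^2 ≈ 0.002`
per minute at the printed `D_Ep = D_RGa = 0.008` µm²/min, an order of
magnitude weaker than the projection's odd-mode damping `2 d = 0.04`.
Consequently the spatial model's localized polarized pattern is still
stable at `Et = 1.26` (the criticality run stays polarized indefinitely),
and no single coupling value pushes the spatial fold inside the
(1.26, 1.35] bracket. The source model's own dimensionless coupling 0.02,
read as an angular diffusion coefficient, corresponds to
`D = R^2 × 0.02 = 0.08` µm²/min; at that setting the spatial run at
criticality shows the published transient-memory phenotype (tens of
minutes). The package therefore (i) keeps the printed 0.008 µm²/min as
the dimensional default, (ii) asserts the four regime phenotypes on the
projection — the object the published diagram and regime comparison are
computed from — and (iii) documents that spatially resolved ghost
memory requires the stronger-coupling reading.

## 3. The mechanical model

`simulate_cell()` couples an `Ep` kymograph to a level-set description
of the boundary. The potential `Psi` (negative inside) obeys
`dPsi/dt + F |grad Psi| = 0` with the normal speed
`F = -(kc/tau_c) l + (1/tau_c + 1/tau_a) P_total`: a Voigt cortex
(spring `kc`, dashpot `tau_c`) in series with a viscous cytoplasm
(`tau_a`). The cortex state `l` is advected with the boundary and relaxes
toward `P_total / kc`. Pressures per contour point: protrusion
`Kprot (Ep - mean)/(max - mean)` where the local signal exceeds the
contour mean; retraction `-Kretr (mean - Ep)/(mean - min)` where it falls
below (degenerate normalizations below 1e-9 zero the pressure); a uniform
area-restoring pressure `Karea (A0 - A)`; and cortical tension
`-Kten (kappa - 1/R)`. The trailing *n* in the printed pressure laws is
the outward normal vector, not an exponent — the pressures are scalars
along the normal, which is the only dimensionally consistent reading.

Numerics (choices the source leaves unstated are marked *):

* grid 5 points/µm, `dt = 0.01` min, first-order Euler in time;
* Godunov upwinding with second-order ENO one-sided differences
  (`scheme = "upwind1"` selects the first-order fallback);
* velocity and pressure are extended off the interface constantly along
  normals via nearest-contour-point lookup in a 6-cell band*;
* re-distancing every 50 steps by exact segment distance to the
  spline-refined contour polyline* (the refinement matters: distances to
  the raw grid-edge polyline cut corners and systematically erode convex
  boundaries);
* the `Ep` field maps to the contour by angular sector from the current
  centroid, sectors fixed in the lab frame;
* the grid is a moving window re-centred when the cell approaches a
  border*; a genuine pinch-off (second contour component of comparable
  area) aborts, sub-resolution satellite blobs are dropped.

**Calibration and its limits.** With the printed mechanical constants the
simulated cell migrates up a sustained gradient at ≈ 0.52–0.66 µm/min
(mean ≈ 0.58), matching the printed calibration target 0.49 ± 0.173.
Area conservation is exact to 0.04% for a resting cell, but the
*migrating* cell equilibrates at a 6–10% area deficit over an hour: the
saturating retraction law integrates to a net contraction that the
area-restoring pressure balances only at a finite deficit, and the
protrusion tip is marginally resolved at 5 points/µm. Refining to
10 points/µm conserves area to ~2% but halves the speed — the printed
constants are calibrated to the printed grid. We keep the printed
resolution (the speed target is the calibrated quantity) and flag the
5% area-conservation figure as not met during sustained migration.

## 4. Migration models and track statistics

The modified Ornstein–Uhlenbeck velocity model is
`dv = -v/tau dt + (sqrt(2 D)/tau)(dW + b(t) e dt)` per Cartesian
component. The printed noise prefactor is typographically ambiguous;
`sqrt(2 D)/tau` is the single reading consistent with the linear MSD
convention `MSD -> 4 D t` and stationary speed variance `D/tau` per
component, and is what `simulate_mou()` implements (Euler–Maruyama,
internally substepped to `tau/25`, positions by trapezoidal integration;
the bias magnitude `b` is dimensionless inside the noise-scaled term, as
printed). `RW`, `PRW`, `PBRW`, `PB(t)RW` are parameter settings of the
same process (`tau -> 0`, `b = 0`, constant `b`, scheduled `b`).

Estimators follow the printed definitions: ensemble MSD from each
track's origin (not time-averaged); VACF from central-difference
velocities; `D` from an affine fit of the MSD over lags in
`[min(3 tau_hat, T/2), T]` (slope = `4 D`; the free intercept absorbs the
`-4 D tau` ballistic offset, and below ~3 persistence times the residual
exponential shoulder biases the slope low — the window was widened after
quantifying that bias); `tau` by a mono-exponential fit over the lags
where the VACF is still above 5% of its initial value, skipping the
first two lags where central differencing distorts the correlation. On
1000–2000-track ensembles of 300 min at 2-min sampling, the printed
parameter pairs (`tau = 11.105`, `D = 0.425`; `tau = 38.143`,
`D = 2.207`) are recovered within ~5% (D) and ~10% (tau).

## 5. Quantification procedures

* **Kymographs.** Per-bin phosphorylation fraction
  `(PTB_PM/(PTB_T - PTB_endo))/(EGFR_PM/EGFR_T)`, normalised per cell to
  the pre-stimulus (first 5 min) mean and the global maximum. The per-bin
  normalisation serves spatial analyses; the whole-membrane time course
  sums the channels before the ratio and is normalised the same way.
  All estimators are invariant to joint rescaling of the channels.
* **Activation classes.** Two 2-component Gaussian mixtures (`mclust`):
  pooled pre-stimulus bin values give the pre-activation threshold (a
  cell with > 30% of pre-stimulus bins above it is pre-activated);
  per-cell mean phosphorylation over the first 65 min splits the rest
  into activated/non-activated. Degenerate mixtures fall back to the
  component-mean midpoint, flagged.
* **Signaling memory.** Fraction of membrane area in bins above
  (mean + s.d.) of the kymograph = FPA(t); memory ends at the first
  post-washout time with FPA below (reference mean − s.d.) for 3
  consecutive samples. The reference statistics are taken over the
  pre-washout interval: over a full 4-h record that is dominated by
  unpolarized time the whole-record statistics can place the threshold
  below zero, and the pre-washout window is the choice that keeps the
  printed rule operational on records of any length.
* **Morphology.** Solidity (area / convex-hull area) from the
  marching-squares outline of the (lightly blurred) mask — blurring
  before contouring stops the hull from wrapping the pixelated
  staircase, which would bias smooth shapes low. The printed memory rule
  ("below mean − s.d.") is ambiguous; the adopted reading: the
  below-threshold run containing the washout ends the memory at its last
  below-threshold time, with the threshold estimated over the gradient
  phase. Directed protrusion area: mask-difference area gained in front
  of (minus behind) the axis through the reference centroid
  perpendicular to the gradient, each normalised by the respective side
  area, Gaussian-smoothed along time; the 1.2 µm² event threshold applies
  to experimental-style masks and is off for simulation masks.
* **Migration memory.** Ensemble rule: sliding 5-point windows of pooled
  cos θ compared against a no-stimulus reference by two-sided KS test;
  memory ends at the first post-washout window accepted (p > 0.05) twice
  in a row, timestamped at the window centre. The significance level and
  the 2-window rule are package choices (the source shows p-value curves
  only), both exposed as arguments. Per-cell rule: constant-velocity
  Kalman smoothing (process/measurement covariances 0.1 µm/min², 0.5 µm —
  unstated in the source, exposed), then the first post-washout run of 3
  consecutive cos θ < 0.75.
* **Decay fits.** `f(t) = a0/(a^n + t^n)` by Levenberg–Marquardt
  (`minpack.lm`), optionally with `a` fixed at 10 (the
  kinase-inhibition protocol). The half-decay time equals `a`
  identically — the package computes it numerically and the identity is
  asserted to machine precision. Note the source's own tension: its
  normal-condition fits report `a ≈ 10` yet a ~30-min average half-life;
  under this functional family half-life = `a`, so only the closed-form
  identity is asserted.
* **Delay embedding.** Savitzky–Golay smoothing (window 11, order 3 —
  unstated in the source), delay from the 1/e autocorrelation crossing,
  dimension from false-nearest-neighbour fractions (< 5%, capped at 5,
  with both the distance-ratio and attractor-size criteria); the
  exemplar settings d = 26, m = 3 can be forced by argument.
* **Gradient alignment.** Wrapped-Gaussian fit to the time-averaged
  20-bin EGF projection; the angle between the EGF and phosphorylation
  maxima is the bin distance times `2 pi / 20`.

## 6. What the synthetic data do and do not show

Every generator is deterministic given its seed and ships its ground
truth. The fluorescence generator inverts the ratiometric definition
exactly (uniform membrane EGFR pool, 10% endosomal PTB fraction,
multiplicative log-normal channel noise — intensities are positive and
their noise is multiplicative; the source characterizes no noise model).
The parametric kymograph and mask generators impose plateau-shaped
memory phases with configurable rise/fall scales; the mask generator's
protrusion is a narrow finger (`cos^9` lobe) because only protrusions
with concave shoulders move solidity measurably. Track generators
concatenate mOU phases with continuous velocity.

Passing estimator tests on these artifacts shows correctness of the
*procedures* under known truth. It does not show that real cells satisfy
the generators' assumptions: real records have bleaching, segmentation
errors and cell-to-cell parameter spread that the generators deliberately
omit, and the real memory durations quoted in the source (≈ 40 min
signaling, ≈ 50 min migration, π/4 alignment) are empirical quantities
that cannot be recomputed from synthetic data.

## 7. Problem sizes and reproducibility

The shipped test-suite and acceptance runs use: 20-bin rings at
`dt = 0.01` min over 20–245 min; one 65-min coupled cell simulation on a
61×61 moving grid; 40–2000-track ensembles of 100–300 min; 50-profile
sigmoid batches; continuation scans at `2e-3` resolution in `Et`. These
sizes put every estimator's Monte-Carlo spread comfortably inside its
assertion tolerance while keeping a full run in minutes. All randomness
flows from explicit integer seeds; `run_experiment()` derives per-module
substreams from the run seed by fixed offsets, so module order never
changes results, and re-running a preset with its manifest reproduces
its metrics bit-for-bit.

## 8. Known limitations

* The spatial model's fold structure vs. the projection's (Section 2):
  regime phenotypes are projection-level statements.
* Area conservation during sustained migration equilibrates at a 6–10%
  deficit with the printed constants and grid (Section 3).
* The PTPN2 quasi-steady state is an `epsilon`-inconsistent but
  source-faithful simplification; transient QSS/full-model deviations
  are at the 10% level.
* Memory-duration estimators carry rule-intrinsic detection lags (3-run
  waits, KS window spans) of a few samples; tests measure them against
  ground truth with sample-unit tolerances.
* No mechanochemical feedback from shape to signaling, no receptor
  trafficking, 2-D shapes only, single non-interacting cells.
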