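# ghostnav

Simulation and quantification toolkit for **working-memory navigation in
single cells**: how a migrating cell can keep moving toward a
chemoattractant source for tens of minutes after the gradient is gone,
while staying responsive to new signals.

The package is built around a receptor-network mechanism: the
EGFR–PTPRG–PTPN2 polarity circuit on the plasma membrane supports a
**subcritical pitchfork bifurcation** (PB) in the total receptor
concentration `Et`. The symmetry-broken branch — an inhomogeneous steady
state with high phosphorylation at the cell front and low at the back — is
stabilised by saddle-node bifurcations (SN_PB). A cell whose receptor
level sits *just below* the SN_PB ("organization at criticality") polarizes
under a gradient; when the gradient is removed the polarized attractor
vanishes, but its slow-escaping remnant — a dynamical **ghost** — traps the
trajectory near the polarized state for a finite interval. That interval is
the cell's working memory: long enough to carry directed migration across
signal interruptions, short enough to be overwritten by new gradients.

## What is implemented

* **`signaling_rd`** — stochastic reaction–diffusion simulation of the
  four-species network (ligandless phosphorylated receptor `Ep`, liganded
  `EEp`, phosphatases `RGa`, `N2a`) on a 20-bin circular membrane
  (Euler–Maruyama, periodic central-difference Laplacian, additive noise on
  `Ep`), with piecewise space–time EGF protocols
  (`stimulus_protocol()`, `simulate_rd()`, `polarization_metrics()`).
* **`bifurcation_analysis`** — the front/back two-compartment projection:
  steady states, analytic Jacobians, the odd-mode pitchfork criterion
  `det(A - B) = 0`, pseudo-arclength continuation of the polarized branch
  (`scan_bifurcation_diagram()`), nondimensionalization, and the
  Stuart–Landau amplitude expansion `dphi/dt = c1 phi + c2 phi^3 - c3 phi^5`
  whose coefficient signs certify subcriticality
  (`stuart_landau_coeffs()`).
* **`cell_mechanics`** — level-set model of shape and migration: the
  boundary is the zero set of a potential advected by a viscoelastic
  normal velocity (Voigt cortex in series with a viscous cytoplasm),
  driven by protrusion/retraction pressures slaved to the `Ep` kymograph
  plus area-conservation and cortical-tension pressures
  (`simulate_cell()`).
* **`motility`** — modified Ornstein–Uhlenbeck migration models
  (RW/PRW/PBRW and time-scheduled bias), ensemble MSD and VACF, and
  simulate-then-fit parameter recovery (`simulate_mou()`,
  `fit_motility()`).
* **`quantification`** — the single-cell analysis procedures: ratiometric
  phosphorylation kymographs and time courses, GMM activation classes,
  signaling/morphology/migration memory-duration estimators,
  inverse-sigmoid decay fits `f(t) = a0/(a^n + t^n)`, Takens delay
  embedding, and gradient-alignment quantification.
* **`synthetic_data`** — ground-truth generators for every pipeline input
  (protocols, parametric kymographs, fluorescence records, mask series,
  phase-switched track ensembles), each artifact shipping the truth needed
  to score the estimators.

## Worked example

Polarize a cell at criticality, let the gradient go, and measure how long
the polarized state survives:

```r
library(ghostnav)

prot <- make_stimulus_protocol("single_gradient_1h")  # gradient on t = [5, 65) min
sim  <- simulate_rd(signaling_params(Et = 1.26), membrane_grid(),
                    prot, t_end = 245, seed = 11)
pm   <- polarization_metrics(sim$Ep, prot)
round(c(max_index = max(pm$p), memory_min = pm$memory), 2)
#> max_index memory_min
#>      5.18        Inf
```

The polarization index `(max - min)/mean` rises far above the 0.2
threshold during the gradient. At the printed lateral diffusion the
20-bin ring keeps a localized polarized pattern alive past the
observation window (the `Inf` sentinel); the fold positions of the
spatial pattern sit below those of the front/back projection the regime
placement refers to (see the methods vignette). On that projection the
same protocol yields a clean, finite ghost memory:

```r
k  <- simulate_compartments(signaling_params(Et = 1.26), prot,
                            t_end = 400, noise_on = FALSE)
pm <- polarization_metrics(k, prot, threshold = 0.2, floor = 0.1)
round(c(peak_front_Ep = max(k$mat[1, ]), memory_min = pm$memory), 2)
#> peak_front_Ep    memory_min
#>          0.37         69.50
```

The front compartment polarizes during the gradient and the asymmetry
survives for ~70 min after washout before collapsing to the basal state.

Where does criticality live? Scan the receptor total:

```r
bd <- scan_bifurcation_diagram(signaling_params())
bd
#> bifurcation diagram (front/back compartment model)
#>   Et range scanned: [1.00126, 2.19285]
#>   pitchfork Et_PB = 2.095914
#>   saddle-node Et_SN = 1.267216  (subcritical: coexistence window below the PB)
```

`Et = 1.26` sits just below the saddle-node at 1.267 — criticality —
while `1.35` lies inside the stable-polarized window and `1.1` / `1.85`
are the basal and pre-activated homogeneous regimes.

Fit migration statistics the way the tracking pipeline does:

```r
en  <- simulate_mou(motility_params(tau = 38.143, D = 2.207),
                    n_tracks = 1000, seed = 5)
fit_motility(en)
#> motility fit: D = 2.118 um^2/min (MSD R^2 = 1.000)
#>               tau = 34.54 min (VACF SEOE = 0.00145)
```

recovering the generating persistence time (38.1 min) and diffusion
coefficient (2.21 um^2/min) to within the Monte-Carlo spread of a
1000-track ensemble.

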