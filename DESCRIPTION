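Package: ghostnav
Title: Metastable Receptor Polarity, Ghost-State Memory and Chemotactic Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantification toolkit for working-memory navigation in
    single cells. Implements a stochastic reaction-diffusion model of the EGFR-PTPRG-PTPN2
    polarity network on a circular membrane, its two-compartment bifurcation analysis
    (subcritical pitchfork stabilised by saddle-nodes, Stuart-Landau amplitude expansion),
    a level-set viscoelastic model of signal-driven cell-shape change and migration,
    modified Ornstein-Uhlenbeck migration models with MSD/VACF fitting, and the
    single-cell quantification procedures (ratiometric kymographs, polarization and
    memory-duration estimators, inverse-sigmoid decay fits, delay embedding,
    Kolmogorov-Smirnov migration-memory detection), together with ground-truth
    synthetic-data generators for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    minpack.lm,
    mclust,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
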