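Package: mdequil
Title: Convergence and Equilibrium Diagnostics for Molecular Dynamics
    Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Diagnoses convergence and operational equilibrium of molecular
    dynamics trajectories. Computes windowed normalized autocorrelation
    functions and characteristic decorrelation times, decorrelation curves
    over growing trajectory prefixes with plateau detection and power-law
    fits, cumulative overlap between anisotropic network model modes and
    principal components, RMSF and cluster convergence curves, dihedral
    state transition rates with cumulative-rate convergence, and histogram
    free-energy landscapes with minima and barrier readout. Ships synthetic
    generators (analytic composite signals, Ornstein-Uhlenbeck noise,
    Markov jump dihedral dynamics, overdamped Langevin sampling on 2D
    angular landscapes, and harmonic bead ensembles) so every diagnostic
    can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    ggplot2,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
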