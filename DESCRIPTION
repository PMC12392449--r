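Package: rasta
Title: Resolution-Annealed Stochastic Gradient Ascent for Single-Molecule
    X-Ray Scattering
Version: 0.1.0
Authors@R:
    person("RASTA", "Developers", email = "rasta@example.org", role = c("aut", "cre"))
Description: Direct real-space determination of atomistic electron densities
    from sparse single-molecule X-ray free-electron-laser scattering images.
    Represents the density as a mixture of Gaussian beads, evaluates an
    orientation-marginalized Poisson likelihood of photon lists on Ewald-sphere
    polar grids, and maximizes the Bayesian log-posterior by stochastic
    gradient ascent with resolution annealing (photon thinning matched to
    Gaussian smoothing of the density). Includes a forward simulator for
    synthetic photon-list images, a connectivity/repulsion prior on bead
    positions, rigid/enantiomer-aware alignment, Fourier shell correlation and
    earth-mover's distance evaluation, and file formats plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
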