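Package: hemekin
Title: Reactive Ligand Rebinding Kinetics on Coupled Heme Potential Surfaces
Version: 0.1.0
Authors@R:
    person("hemekin", "developers", email = "hemekin@example.org", role = c("aut", "cre"))
Description: Reduced-coordinate model of nitric-oxide photodissociation and
    geminate rebinding at a solvent-exposed heme site. Provides synthetic
    two-electronic-state (doublet/quartet) reference potentials pinned to
    published stationary points, reproducing-kernel Hilbert space (RKHS)
    interpolation of tabulated energies with a Legendre angular expansion,
    smooth two-state mixing with an asymptotic shift, Langevin dynamics under
    solvent surrogates (glycerol/water cage, pure water, water plus ions),
    censored multi-exponential survival-fraction fitting, and structural
    analyses of rebinding ensembles (iron out-of-plane distributions,
    rebinding-timescale clustering).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
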