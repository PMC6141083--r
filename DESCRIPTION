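Package: oxfold
Title: Methionine Oxidation, Folding Free Energies and Forced Unfolding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale analysis machinery for studying how methionine
    oxidation (conversion to methionine sulfoxide) affects protein
    stability, modelled on the force-sensing A2 domain of von Willebrand
    factor. Implements alchemical free-energy estimation (exponential
    averaging and the Bennett acceptance ratio) over lambda schedules with
    soft-core van der Waals potentials, the thermodynamic-cycle
    delta-delta-G of folding, Shrake-Rupley solvent accessible surface
    area, geometric hydrogen-bond detection, switched nonbonded
    interaction energies, a coarse-grained constant-velocity pulling
    simulator with rupture-force identification, seeded synthetic-data
    generators with ground-truth sidecars, and replicate-level statistics
    (mean +/- SEM, one-tailed t-tests, significance tiers).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
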