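Package: morphoconverge
Title: Landmark-Based Analysis of Shape Convergence Between Lineages
Version: 0.1.0
Authors@R: person("morphoconverge", "developers", role = c("aut", "cre"),
    email = "dev@morphoconverge.invalid")
Description: Tools for 3D landmark geometric morphometrics aimed at testing
    phenotypic convergence between lineages sampled at two time strata.
    Implements generalized Procrustes superimposition with object symmetry,
    shape principal component analysis, permutation (residual-randomization)
    Procrustes ANOVA with pairwise mean and variance comparisons, Procrustes
    variance (disparity), and a multidimensional convergence index (MCI) with
    a randomization test. Includes landmark file readers/writers (CSV, TPS,
    pts), a synthetic landmark-data generator emulating a lineage-by-period
    design, and a command-line pipeline that runs the full analysis chain.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
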