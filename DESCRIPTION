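Package: morphpair
Title: Matched-Pair Voxel-Based Morphometry with Permutation Inference
Version: 0.1.0
Authors@R: person("Kenneth", "Doran", email = "kdoran@example.org",
    role = c("aut", "cre"))
Description: Tools for case-control brain morphometry on multi-site
    Jacobian-determinant images. Implements coarsened stratification and
    propensity-score nearest-neighbor matching of cases to controls,
    voxelwise residualization for brain-size and site nuisance effects,
    paired and unpaired permutation inference with threshold-free cluster
    enhancement (TFCE) and familywise error correction, bootstrap
    comparison of well-matched versus randomly matched designs,
    reading-disability profile classification (expert rules plus a random
    forest validated by leave-one-out cross-validation and embedded with
    classical multidimensional scaling), and a simulation study of the
    bias introduced by residualizing a nuisance variable that is highly
    collinear with case status. A seeded synthetic-data generator emulates
    the multi-site cohort structure so the full pipeline is testable
    without access to restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
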