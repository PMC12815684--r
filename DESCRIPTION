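Package: chisep
Title: Separating Iron and Myelin Contributions to Subcortical Magnetic
    Susceptibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for quantitative susceptibility mapping (QSM)
    case-control studies that separates iron from myelin contributions to
    subcortical magnetic susceptibility (chi). Provides region-of-interest
    group statistics (Cohen's d, t-tests, Benjamini-Hochberg FDR, robust
    confounder models), estimation of white-matter magnetic susceptibility
    anisotropy (delta-chi) from chi and the fiber-to-field angle, voxelwise
    robust regression with threshold-free cluster enhancement (TFCE) and
    permutation inference, and an imaging-transcriptomics stage linking
    voxelwise t-score maps to gene expression via NIPALS partial least
    squares regression with spatial-autocorrelation-preserving permutation
    nulls, bootstrap VIP z-scores, and cell-type median-rank enrichment.
    Includes synthetic-data generators emulating the statistical structure
    of such studies so that every stage is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
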