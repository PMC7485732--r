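Package: cortexage
Title: Simulated Multiparametric Quantitative MRI Analysis of Cortical Aging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Digital brain phantoms with calibrated linear age trends in
    cortical quantitative MRI parameters (T1, PD, T2, T2*, T2') and cortical
    thickness; forward synthesis of variable-flip-angle, multi-echo spin-echo
    and gradient-echo acquisitions with transmit/receive bias fields and
    noise; voxelwise relaxometry (B1, T1, PD, T2, T2*, T2' mapping); a
    cortical-ribbon surrogate with distance-transform thickness and lobe
    parcellation; and the three-level correlation statistics used in cortical
    aging studies (global and lobar partial Pearson correlations, voxelwise
    correlation maps with Gaussian smoothing and permutation-based
    cluster-level inference).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    mclust,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
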