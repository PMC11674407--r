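Package: sfcica
Title: Structural-Functional Connectivity Informed Spatially Constrained ICA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Subject-level estimation of intrinsic connectivity networks
    (ICNs) from fMRI by a multiobjective spatially constrained independent
    component analysis whose cost combines spatial-source non-Gaussianity
    (negentropy), similarity to a prior spatial template, and a structural
    connectivity weighted penalty on time-course distances, optimized by
    projected steepest ascent with Armijo backtracking. Includes a
    SimTB-style spatiotemporally separable fMRI simulator with a
    FiberCup-like structural connectivity phantom, functional network
    connectivity (FNC) evaluation metrics (time-course distances, global
    cost efficiency thresholding, sparsity, modularity, efficiencies,
    small-worldness), and a statistical comparison layer (paired t-tests,
    covariate-adjusted GLM group differences, Benjamini-Hochberg FDR,
    signed log-p maps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
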