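Package: plastimap
Title: Voxelwise Time-Course Morphometry and Myelinated-Fiber
    Quantification for Learning-Induced Brain Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping structural brain plasticity during motor
    skill learning. Implements voxelwise longitudinal morphometry with
    linear, asymptotic and quadratic time-course models fitted as linear
    mixed models (random intercept and slope per subject), small-sample
    Akaike information criterion (AICc) model comparison with pairwise
    Akaike probabilities, Benjamini-Hochberg FDR maps and preferred-model
    maps; quantitative 3D reconstruction of myelinated axons from
    confocal stacks (edge-preserving smoothing, Otsu binarization,
    topology-preserving thinning, half-micron node resampling with
    distance-transform radii, labeled-depth screening) yielding length
    density, diameter and volumetric fraction; three-class multi-Otsu
    densitometry of fluorescence sections; single-pellet reaching
    behavior scoring with logarithmic learning rates; and seeded
    synthetic-data generators emulating each data modality with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    lme4,
    Rcpp,
    RNifti,
    tiff,
    igraph,
    mgcv,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
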