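Package: scenefeedback
Title: Decoding and Representational Analysis of Occluded-Scene fMRI Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying cortical feedback to early visual cortex with
    partially occluded scene stimuli. Generates synthetic scene images, observer
    line drawings, rater scores and voxel response patterns with controllable
    signal structure; computes image-computable feature models (Weibull contrast
    statistics, Gist descriptors, HMAX C2 features, category and continuous
    depth models); estimates single-block GLM responses with a two-gamma HRF and
    selects voxels by population receptive field containment; performs
    leave-one-run-out multiclass SVM decoding with permutation nulls and
    cross-classification; fits channel-wise model representational
    dissimilarity matrices to cross-validated linear discriminant contrast RDMs
    by non-negative least squares with Kendall tau-a evaluation and noise
    ceilings; and relates line-drawing consistency to pattern decodability.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    MASS,
    pracma,
    lme4,
    lmerTest,
    jsonlite,
    png,
    ggplot2,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
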