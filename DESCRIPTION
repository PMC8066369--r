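Package: sliceforest
Title: Slice-Ensemble Random Forests for Diagnosis and Lesion
    Localization in 3D Brain MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies co-registered 3D structural MRI volumes by slicing
    each volume along the three orthogonal anatomical directions, training
    one random-forest classifier per slice position, filtering the
    resulting per-direction binary decision vectors with a
    k-consecutive-slice rule, and intersecting the retained slice runs in
    3D to obtain both a subject-level diagnosis and a voxel-level
    suspected-lesion mask. Includes stratified cross-validation,
    data-driven selection of the run-length threshold k, a synthetic
    brain-phantom generator with planted lesions for end-to-end
    parameter-recovery testing, NIfTI import/export, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    ranger,
    RNifti,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
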