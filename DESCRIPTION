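Package: searchmark
Title: Searchlight MVPA and Grouped Stability Analysis for Structural
    MRI Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A three-level machine-learning framework for identifying
    structural-MRI biomarkers of movement disorders (essential tremor and
    Parkinson's disease) from smoothed gray-matter volume maps.  The
    model level scans a spherical searchlight over the brain and scores
    every voxel by cross-validated PCA+SVM decoding accuracy; the feature
    level splits supra-threshold clusters along parcellation-atlas
    boundaries and keeps sub-clusters whose accuracy survives a label
    permutation test; the patient-versus-patient level classifies the two
    disease groups from the selected biomarker voxels with a panel of
    standard classifiers and rank-based ROC/AUC metrics.  Also includes a
    voxelwise two-sample t-map branch with nuisance-covariate regression
    and cluster-extent thresholding, and a synthetic cohort generator
    that emulates smoothed gray-matter maps with parcel-localized group
    effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    randomForest,
    rpart,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC,
    jsonlite,
    knitr
Config/testthat/edition: 3
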