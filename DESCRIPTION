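Package: landmarknet
Title: Cardiovascular Landmark Detection and Anatomy Classification from
    Axial Cine MRI Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects seven cardiovascular anatomical landmarks in axial cine
    MRI stacks with a multi-head 3D heatmap-regression network (a shared
    U-net-like 3D convolutional encoder backbone with one segmentation head
    per landmark) and classifies the centred landmark point cloud with a
    linear support vector machine, distinguishing hypoplastic left heart
    syndrome (HLHS) in Fontan circulation from normal cardiovascular
    anatomy. Includes Gaussian heatmap target construction, point-cloud
    centring and augmentation, evaluation metrics (landmark displacement,
    interobserver variability ratio, Bland-Altman agreement, classification
    accuracy), a stratified k-fold cross-validation harness, and a synthetic
    phantom generator that renders two-class cohorts of blob/tube volumes so
    every stage can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    e1071
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
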