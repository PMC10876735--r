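# landmarknet

Detection of seven cardiovascular anatomical landmarks in axial cine MRI
stacks with a multi-head 3D heatmap-regression network, and classification
of the resulting landmark arrangement as hypoplastic left heart syndrome
(HLHS, post-Fontan) or normal anatomy with a linear support vector
machine.  The package is aimed at researchers in cardiovascular image
analysis who want a transparent, geometry-based classifier: the SVM sees
only the centred landmark point cloud, never the image, so the decision
cannot be driven by scanner or protocol artefacts.

## The method in brief

1. **Preprocessing.** Any axial stack (17–54 slices, 1.2–2.3 mm in-plane,
   5–8 mm slices; NIfTI, DICOM series, or the package's internal format)
   is cropped/zero-padded to 33 slices and bilinearly resampled to
   256 × 256, with voxel spacings rescaled accordingly.
2. **Heatmap regression.** Each landmark j is encoded as a Gaussian
   temperature field t(v) = k·exp(−Σ_d (v_d − p_d)²/(2σ_d²)) with
   k = 10³ and σ = one voxel per axis.  A U-net-like 3D CNN — shared
   encoder (in-plane stride-2 downsampling to depth 7, filters growing
   +4 per step from 6), seven decoder heads splitting above depth 3 —
   regresses one 33 × 64 × 64 heatmap per landmark under MSE loss
   (Adam, lr 5·10⁻⁴, batch 2, 32 epochs, He init).  The network engine
   (im2col + BLAS convolutions, transpose convolutions, pooling, Adam)
   is implemented inside the package; no deep-learning framework is
   required.
3. **Extraction and centring.** The predicted landmark is the heatmap
   argmax (ties broken by the 7×7×7 neighbourhood sum S, then
   lexicographically).  The seven positions l_ji are converted to mm,
   centred at their centroid m_i = Σ_j l_ji/7, L_ji = l_ji − m_i.
4. **Classification.** A linear soft-margin SVM (cost 1) on the 21
   centred coordinates; per-landmark weight summaries (signed max and RMS
   of each landmark's three coefficients) expose which landmark drives
   the decision — for HLHS geometry, the aortic/neo-aortic valve.
5. **Evaluation.** Landmark displacement E = ‖g − l‖ (mm) with per-fold
   averaging, interobserver variability and its ratio to network error,
   per-component Bland–Altman analysis (bias, 95 % limits, proportional
   bias slope), classification accuracy, and a stratified 5-fold
   cross-validation harness.
6. **Phantoms.** A synthetic generator renders two-class cohorts
   (46 patients / 33 controls by default) of blob-and-tube volumes whose
   class geometry mirrors the clinical one (aortic-valve landmark shifted
   40 mm between classes, 3 mm within-class jitter), so the entire
   pipeline is testable without patient data.

## Worked example

```r
library(landmarknet)

# a synthetic two-class cohort at reduced desk-scale resolution
spec <- phantomSpec(nPatients = 10, nControls = 10,
                    shape = c(33, 64, 64), geometry = voxelGeometry(2, 6),
                    seed = 1)
cohort <- sampleCohort(spec, render = FALSE)

# classify the annotated landmark arrangements with 5-fold CV
res <- runCrossval(NULL, cohort$annotations, geometry = spec@geometry,
                   k = 5, seed = 1, useAnnotations = TRUE)
res$accuracy
#> [1] 1
weightSummary(fitClassifier(lapply(cohort$annotations, function(a)
  centerPointCloud(toPointCloud(a, spec@geometry)))))
#>   landmark                              name      max     rms
#> 1        1 left common carotid artery origin 0.001771 0.00818
#> 2        2                    aortic isthmus 0.000381 0.00858
#> 3        3                   tricuspid valve 0.006045 0.00369
#> 4        4         aortic / neo-aortic valve 0.050787 0.02957
#> 5        5                      mitral valve 0.004956 0.00503
#> 6        6            right ventricular apex 0.015600 0.01171
#> 7        7     descending aorta at diaphragm 0.001771 0.00768
```

The printed accuracy of 1.0 is the phantom analogue of classifying
manually annotated landmarks: with the aortic-valve landmark separated by
40 mm between classes and 3 mm jitter, the centred clouds are linearly
separable, and the weight summary identifies landmark 4 (the
aortic/neo-aortic valve — the structure that physically moves between the
two anatomies) as carrying the largest classifier weights, max 0.051 and
RMS 0.030 against at most 0.012 for any other landmark.

A full image-based run (simulate volumes, train the network, detect
landmarks, classify) is available through the command-line wrapper:

```sh
Rscript inst/scripts/landmarknet simulate --config sim.json --seed 1
Rscript inst/scripts/landmarknet train    --config train.json
Rscript inst/scripts/landmarknet predict  --config predict.json
Rscript inst/scripts/landmarknet classify --config classify.json
```

See `?landmarknetMain` for the config schema and exit codes, and the
vignette (`vignettes/landmark-detection.Rmd`) for the model, its
assumptions, parameter choices and limitations.

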