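#' Euclidean displacement between two mm positions
#'
#' @param g,l numeric mm positions (vectors of equal length, or matrices
#'   with matching shape, compared row-wise).
#' @return Displacement(s) in mm.
#' @export
displacement <- function(g, l) {
  if (is.matrix(g)) sqrt(rowSums((g - l)^2)) else sqrt(sum((g - l)^2))
}

cloudList <- function(x) {
  if (is(x, "PointCloud") || is(x, "CenteredPointCloud")) list(x) else x
}

#' Per-landmark detection statistics over a cohort
#'
#' For every landmark j, the mean and standard deviation over subjects of
#' the Euclidean displacement between predicted and annotated positions,
#' the per-component signed mean displacement (systematic shift), and --
#' when a second observer is supplied -- the interobserver variability
#' \eqn{E_{inter,j}} and the ratio of network error to interobserver
#' variability.  When fold labels are supplied the statistics are computed
#' per fold and averaged over folds.
#'
#' @param predictions list of \linkS4class{PointCloud}s (network output).
#' @param annotations list of \linkS4class{PointCloud}s (observer 1 /
#'   ground truth), aligned with \code{predictions} by subject.
#' @param secondObserver optional list of \linkS4class{PointCloud}s from a
#'   second observer.
#' @param folds optional integer vector of fold labels per subject.
#' @return A data.frame with one row per landmark: \code{landmark},
#'   \code{name}, \code{meanDisp}, \code{sdDisp}, \code{interobserver},
#'   \code{ratio}, and signed per-component means \code{biasZ},
#'   \code{biasY}, \code{biasX} (all mm).
#' @export
cohortLandmarkStats <- function(predictions, annotations,
                                secondObserver = NULL, folds = NULL) {
  predictions <- cloudList(predictions)
  annotations <- cloudList(annotations)
  n <- length(predictions)
  if (n == 0L || length(annotations) != n)
    lmnError("predictions and annotations must be non-empty and aligned",
             "landmarknetValidationError")
  sp <- unname(vapply(predictions, subjectId, character(1)))
  sa <- unname(vapply(annotations, subjectId, character(1)))
  if (!identical(sp, sa))
    lmnError("subject identifiers of predictions and annotations differ",
             "landmarknetValidationError")
  if (!is.null(secondObserver) && length(secondObserver) != n)
    lmnError("second-observer set must align with the cohort",
             "landmarknetValidationError")
  if (is.null(folds)) folds <- rep(1L, n)

  perFold <- lapply(unique(folds), function(f) {
    idx <- which(folds == f)
    stats <- t(vapply(1:7, function(j) {
      P <- t(vapply(predictions[idx], function(p) p@points[j, ], numeric(3)))
      G <- t(vapply(annotations[idx], function(p) p@points[j, ], numeric(3)))
      e <- displacement(G, P)
      bias <- colMeans(P - G)
      inter <- NA_real_
      if (!is.null(secondObserver)) {
        H <- t(vapply(secondObserver[idx], function(p) p@points[j, ],
                      numeric(3)))
        inter <- mean(displacement(G, H))
      }
      c(meanDisp = mean(e), sdDisp = stats::sd(e), interobserver = inter,
        biasZ = bias[1], biasY = bias[2], biasX = bias[3])
    }, numeric(6)))
    stats
  })
  avg <- Reduce(`+`, perFold) / length(perFold)
  out <- data.frame(landmark = 1:7, name = LANDMARK_NAMES, avg)
  names(out)[3:8] <- c("meanDisp", "sdDisp", "interobserver",
                       "biasZ", "biasY", "biasX")
  out$ratio <- ifelse(!is.na(out$interobserver) & out$interobserver > 0,
                      out$meanDisp / out$interobserver, NA_real_)
  out
}

#' Bland-Altman agreement analysis for one spatial component
#'
#' Differences a - b against pairwise means: bias (mean difference), SD of
#' the differences, 95% limits of agreement (bias +/- 1.96 SD), and the
#' proportional-bias slope from the least-squares regression of the
#' difference on the pairwise mean.
#'
#' @param a,b paired numeric vectors (n >= 3).
#' @return A list with \code{bias}, \code{sd}, \code{lower}, \code{upper},
#'   \code{slope}, and the per-pair \code{differences} and \code{means}.
#' @export
blandAltman <- function(a, b) {
  if (length(a) != length(b))
    lmnError("paired samples must have equal length",
             "landmarknetValidationError")
  if (length(a) < 3L)
    lmnError("Bland-Altman needs n >= 3 pairs", "landmarknetValidationError")
  d <- a - b
  m <- (a + b) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  slope <- if (stats::sd(m) == 0) 0 else unname(stats::coef(
    stats::lm(d ~ m))[2])
  list(bias = bias, sd = s, lower = bias - 1.96 * s, upper = bias + 1.96 * s,
       slope = slope, differences = d, means = m)
}

#' Classification accuracy
#'
#' @param truth,predicted equal-length label vectors.
#' @return Fraction of correct classifications in [0, 1].
#' @export
classificationAccuracy <- function(truth, predicted) {
  if (length(truth) == 0L)
    lmnError("empty input", "landmarknetValidationError")
  if (length(truth) != length(predicted))
    lmnError("label vectors must have equal length",
             "landmarknetValidationError")
  mean(as.character(truth) == as.character(predicted))
}

#' Stratified k-fold assignment
#'
#' Subjects are shuffled within each class and dealt round-robin to the k
#' validation folds, so folds are disjoint, cover the cohort exactly once,
#' and the per-fold class counts match the cohort proportions within one
#' subject.
#'
#' @param labels character vector of class labels, one per subject.
#' @param k number of folds (default 5).
#' @param seed RNG seed; fixed seed reproduces identical folds.
#' @return A \linkS4class{FoldAssignment}.
#' @export
stratifiedKFold <- function(labels, k = 5L, seed = 1L) {
  k <- as.integer(k)
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < k))
    lmnError(sprintf("every class needs at least k = %d members", k),
             "landmarknetValidationError")
  set.seed(seed)
  fold <- integer(length(labels))
  offset <- 0L
  for (cl in names(counts)) {
    idx <- sample(which(labels == cl))
    # round-robin deal, rotating the starting fold between classes so
    # remainders do not pile up in fold 1
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  new("FoldAssignment", fold = fold, labels = labels, k = k)
}

#' Cross-validated pipeline evaluation
#'
#' For each fold: train the detection network on the training split (from
#' scratch, freshly initialised weights), predict heatmaps on the
#' validation split, extract landmark positions and convert them to mm
#' point clouds; fit the linear SVM on the (optionally augmented) centred
#' annotation clouds of the training split; classify the validation
#' subjects; and accumulate per-landmark displacement statistics and the
#' classification accuracy.  With \code{useAnnotations = TRUE} the network
#' stage is skipped and the annotated landmarks feed the classifier
#' directly (upper bound of the pipeline: classification of manually
#' annotated landmarks).
#'
#' @param stacks list of preprocessed \linkS4class{ImageStack}s (may be
#'   NULL when \code{useAnnotations = TRUE}).
#' @param annotations list of \linkS4class{AnnotationSet}s on the
#'   preprocessed grid, with labels.
#' @param geometry \linkS4class{VoxelGeometry} of the preprocessed stacks
#'   (defaults to the first stack's).
#' @param modelCfg a \linkS4class{ModelConfig}.
#' @param trainCfg a \linkS4class{TrainConfig}.
#' @param k number of folds.
#' @param seed seed for the fold assignment and per-fold model seeds.
#' @param useAnnotations skip the network, classify annotated landmarks.
#' @param svmAugment number of jittered point-cloud replicas for SVM
#'   training (0 = none).
#' @param heatmapCfg a \code{\link{heatmapConfig}} for the training
#'   targets.
#' @param verbose print per-fold progress.
#' @return A list: \code{accuracy} (overall), \code{foldAccuracy},
#'   \code{folds} (the \linkS4class{FoldAssignment}), \code{landmarkStats}
#'   (per-landmark report, network mode only), \code{predictions} (per
#'   subject predicted labels), \code{weights} (per-fold
#'   \code{\link{weightSummary}} tables).
#' @export
runCrossval <- function(stacks, annotations, geometry = NULL,
                        modelCfg = modelConfig(), trainCfg = trainConfig(),
                        k = 5L, seed = 1L, useAnnotations = FALSE,
                        svmAugment = 0L, heatmapCfg = heatmapConfig(),
                        verbose = FALSE) {
  n <- length(annotations)
  labels <- vapply(annotations, subjectLabel, character(1))
  if (is.null(geometry))
    geometry <- if (!is.null(stacks) && length(stacks))
      stacks[[1]]@geometry else voxelGeometry()
  fa <- stratifiedKFold(labels, k = k, seed = seed)
  annClouds <- lapply(annotations, function(a)
    centerPointCloud(toPointCloud(a, geometry)))

  predLabel <- character(n)
  foldAcc <- numeric(fa@k)
  allPredClouds <- vector("list", n)
  weights <- vector("list", fa@k)
  outShape <- headOutputShape(modelCfg)
  coarseGeom <- coarseGeometry(geometry, modelCfg@finalPool)

  for (f in seq_len(fa@k)) {
    vi <- which(fa@fold == f)
    ti <- setdiff(seq_len(n), vi)
    if (verbose) message(sprintf("fold %d/%d: %d train / %d validation",
                                 f, fa@k, length(ti), length(vi)))
    trainClouds <- annClouds[ti]
    if (svmAugment > 0L) {
      set.seed(seed + 1000L * f)
      trainClouds <- augmentPointClouds(trainClouds, nCopies = svmAugment)
    }
    svmFit <- fitClassifier(trainClouds)
    weights[[f]] <- weightSummary(svmFit)

    if (useAnnotations) {
      valClouds <- annClouds[vi]
    } else {
      model <- buildModel(modelCfg, seed = seed + f)
      targets <- lapply(annotations[ti], annotationToHeatmaps,
                        stackGeometry = geometry, gridShape = outShape,
                        factor = modelCfg@finalPool, config = heatmapCfg)
      model <- trainModel(model, stacks[ti], targets,
                          trainConfig(trainCfg@learningRate,
                                      trainCfg@batchSize, trainCfg@epochs,
                                      seed = seed + f),
                          verbose = verbose)
      valClouds <- lapply(vi, function(i) {
        hm <- predictHeatmaps(model, stacks[[i]])
        coarse <- t(vapply(hm, extractLandmark, numeric(3)))
        pc <- toPointCloud(coarse, coarseGeom,
                           subjectId = annotations[[i]]@subjectId,
                           label = annotations[[i]]@label)
        centerPointCloud(pc)
      })
    }
    pl <- classifyCloud(svmFit, valClouds)
    predLabel[vi] <- pl
    foldAcc[f] <- classificationAccuracy(labels[vi], pl)
    allPredClouds[vi] <- valClouds
  }

  stats <- NULL
  if (!useAnnotations) {
    toPc <- function(cl) pointCloud(
      sweep(cl@points, 2L, -cl@centre), cl@subjectId, cl@label)
    stats <- cohortLandmarkStats(
      lapply(allPredClouds, toPc),
      lapply(annClouds, toPc),
      folds = fa@fold)
  }
  list(accuracy = classificationAccuracy(labels, predLabel),
       foldAccuracy = foldAcc, folds = fa, landmarkStats = stats,
       predictions = predLabel, weights = weights)
}
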