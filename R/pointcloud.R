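#' Convert landmark voxel positions to a millimetre point cloud
#'
#' @param landmarks 7 x 3 matrix of (slice, row, col) voxel positions
#'   (0-based, possibly fractional) or an \linkS4class{AnnotationSet}.
#' @param geometry the \linkS4class{VoxelGeometry} of the grid the
#'   positions live on.
#' @param subjectId,label metadata (taken from the annotation when one is
#'   given).
#' @return A \linkS4class{PointCloud} with points in mm (z, y, x).
#' @export
toPointCloud <- function(landmarks, geometry, subjectId = "subject",
                         label = NA_character_) {
  if (is(landmarks, "AnnotationSet")) {
    subjectId <- landmarks@subjectId
    label <- landmarks@label
    landmarks <- landmarks@landmarks
  }
  landmarks <- as.matrix(landmarks)
  if (nrow(landmarks) != 7L || ncol(landmarks) != 3L)
    lmnError("exactly 7 landmark positions are required",
             "landmarknetValidationError")
  pointCloud(voxelToMm(geometry, landmarks), subjectId, label)
}

#' Centre a point cloud at its landmark centroid
#'
#' Subtracts the mean of the seven landmark positions, making downstream
#' classification invariant to any global translation of the anatomy.
#'
#' @param pc a \linkS4class{PointCloud}.
#' @return A \linkS4class{CenteredPointCloud} (points average to zero; the
#'   removed centroid is retained for provenance).
#' @export
centerPointCloud <- function(pc) {
  stopifnot(is(pc, "PointCloud"))
  ctr <- colMeans(pc@points)
  new("CenteredPointCloud", points = sweep(pc@points, 2L, ctr),
      centre = unname(ctr), subjectId = pc@subjectId, label = pc@label)
}

#' Augment centred point clouds with uniform jitter
#'
#' Training-set augmentation for the classifier: each cloud is included
#' once unchanged plus \code{nCopies} replicas whose landmark positions are
#' shifted by independent uniform random values in
#' [-\code{shiftRange}, +\code{shiftRange}] mm per landmark and per spatial
#' coordinate.  Replicas are re-centred so they remain valid centred
#' clouds, and inherit the original's label.
#'
#' @param clouds list of \linkS4class{CenteredPointCloud} objects.
#' @param nCopies jittered replicas per cloud (default 400).
#' @param shiftRange half-width of the uniform jitter in mm (default 10).
#' @return A list of centred point clouds of length
#'   \code{length(clouds) * (1 + nCopies)}.
#' @export
augmentPointClouds <- function(clouds, nCopies = 400L, shiftRange = 10) {
  if (nCopies < 0L)
    lmnError("nCopies must be >= 0", "landmarknetConfigError")
  out <- vector("list", length(clouds) * (1L + nCopies))
  k <- 0L
  for (cl in clouds) {
    stopifnot(is(cl, "CenteredPointCloud"))
    out[[k <- k + 1L]] <- cl
    for (r in seq_len(nCopies)) {
      jit <- matrix(stats::runif(21L, -shiftRange, shiftRange), 7L, 3L)
      out[[k <- k + 1L]] <- centerPointCloud(
        pointCloud(cl@points + jit,
                   subjectId = sprintf("%s_aug%d", cl@subjectId, r),
                   label = cl@label))
    }
  }
  out
}

# 21-coordinate feature vector, landmark-major: L1z, L1y, L1x, L2z, ..., L7x.
cloudFeatures <- function(clouds) {
  m <- t(vapply(clouds, function(cl) as.numeric(t(cl@points)), numeric(21L)))
  colnames(m) <- as.vector(t(outer(1:7, c("z", "y", "x"),
                                   function(j, a) paste0("L", j, a))))
  m
}

#' Fit the linear SVM on centred point clouds
#'
#' Soft-margin support vector classification with a linear kernel and the
#' library default regularisation constant (cost 1), on the 21 centred
#' coordinates in landmark-major order.  No feature scaling is applied
#' beyond the centring: all coordinates share millimetre units.
#'
#' @param clouds list of labelled \linkS4class{CenteredPointCloud} objects.
#' @param cost soft-margin regularisation constant (default 1).
#' @return A \linkS4class{LandmarkSVM}.
#' @export
fitClassifier <- function(clouds, cost = 1) {
  labels <- vapply(clouds, function(cl) cl@label, character(1))
  if (anyNA(labels))
    lmnError("all training clouds must carry a label",
             "landmarknetValidationError")
  if (length(unique(labels)) < 2L)
    lmnError("training data must contain both classes",
             "landmarknetValidationError")
  x <- cloudFeatures(clouds)
  y <- factor(labels, levels = intersect(CLASS_LABELS, labels))
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients the decision function by first occurrence in the data;
  # normalise so a positive decision value always means the first level
  if (fit$levels[fit$labels[1]] != levels(y)[1]) {
    w <- -w
    b <- -b
  }
  new("LandmarkSVM", fit = fit, coefficients = w, intercept = b,
      levels = levels(y))
}

#' Classify a centred point cloud
#'
#' The label follows the sign of the linear decision value
#' \code{w . features + b} (positive decision value = first level of the
#' fitted model; a decision value of exactly zero is assigned to the
#' second level, following the underlying library's strict-inequality
#' convention).
#'
#' @param model a fitted \linkS4class{LandmarkSVM}.
#' @param clouds a \linkS4class{CenteredPointCloud} or a list of them.
#' @return A character vector of predicted labels with the numeric
#'   decision values in \code{attr(, "decision")}.
#' @export
classifyCloud <- function(model, clouds) {
  if (!is(model, "LandmarkSVM"))
    lmnError("model must be a fitted LandmarkSVM",
             "landmarknetValidationError")
  if (is(clouds, "CenteredPointCloud")) clouds <- list(clouds)
  x <- cloudFeatures(clouds)
  dec <- as.numeric(x %*% model@coefficients + model@intercept)
  labels <- ifelse(dec > 0, model@levels[1], model@levels[2])
  attr(labels, "decision") <- dec
  labels
}

#' Per-landmark summary of the classifier weights
#'
#' For each landmark, the signed maximum and the root mean square of its
#' three hyperplane coefficients, plus which landmark carries the largest
#' RMS weight (the landmark most informative for the classification).
#'
#' @param model a fitted \linkS4class{LandmarkSVM}.
#' @return A data.frame with columns \code{landmark}, \code{name},
#'   \code{max}, \code{rms}; the landmark with the largest RMS is given in
#'   \code{attr(, "strongest")}.
#' @export
weightSummary <- function(model) {
  stopifnot(is(model, "LandmarkSVM"))
  w <- matrix(model@coefficients, nrow = 7L, byrow = TRUE)  # 7 x (z,y,x)
  out <- data.frame(
    landmark = 1:7,
    name = LANDMARK_NAMES,
    max = apply(w, 1L, max),
    rms = sqrt(rowMeans(w^2)))
  attr(out, "strongest") <- which.max(out$rms)
  out
}
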