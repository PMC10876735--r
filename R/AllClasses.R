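#' @useDynLib landmarknet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

LANDMARK_NAMES <- c(
  "left common carotid artery origin",
  "aortic isthmus",
  "tricuspid valve",
  "aortic / neo-aortic valve",
  "mitral valve",
  "right ventricular apex",
  "descending aorta at diaphragm"
)

CLASS_LABELS <- c("HLHS", "control")
OBSERVER_IDS <- c("observer1", "observer2", "ground_truth")

#' Voxel geometry of an axial image stack
#'
#' Maps 0-based voxel indices (slice, row, column) to physical millimetre
#' coordinates.  The position of a voxel is the position of its centre;
#' voxel (0,0,0) sits at \code{origin}.  Millimetre axes are ordered
#' (z, y, x) = (slice direction, row direction, column direction); in an
#' axial cardiac stack these correspond to the foot-head (FH),
#' anterior-posterior (AP) and right-left (RL) directions.
#'
#' @slot inPlaneSpacing numeric(2), mm per pixel along (row, column).
#' @slot sliceSpacing numeric(1), mm between slice centres.
#' @slot origin numeric(3), mm position (z, y, x) of voxel (0,0,0).
#' @export
setClass("VoxelGeometry",
  representation(inPlaneSpacing = "numeric", sliceSpacing = "numeric",
                 origin = "numeric"),
  validity = function(object) {
    if (length(object@inPlaneSpacing) != 2L)
      return("inPlaneSpacing must have length 2 (row, column)")
    if (length(object@sliceSpacing) != 1L)
      return("sliceSpacing must have length 1")
    if (length(object@origin) != 3L)
      return("origin must have length 3 (z, y, x)")
    if (!all(is.finite(c(object@inPlaneSpacing, object@sliceSpacing))))
      return("spacings must be finite")
    if (any(c(object@inPlaneSpacing, object@sliceSpacing) <= 0))
      return("all spacings must be strictly positive")
    TRUE
  })

#' Construct a VoxelGeometry
#'
#' @param inPlaneSpacing mm per pixel along (row, column); a scalar is
#'   recycled to both axes.
#' @param sliceSpacing mm between slice centres.
#' @param origin mm position (z, y, x) of the centre of voxel (0,0,0).
#' @return A \linkS4class{VoxelGeometry}.
#' @examples
#' voxelGeometry(1.5, 6)
#' @export
voxelGeometry <- function(inPlaneSpacing = c(1.5, 1.5), sliceSpacing = 6,
                          origin = c(0, 0, 0)) {
  if (length(inPlaneSpacing) == 1L)
    inPlaneSpacing <- rep(inPlaneSpacing, 2L)
  new("VoxelGeometry", inPlaneSpacing = as.numeric(inPlaneSpacing),
      sliceSpacing = as.numeric(sliceSpacing), origin = as.numeric(origin))
}

#' A 3D axial image stack
#'
#' Intensities are stored as a numeric array indexed
#' \code{[slice, row, column]} (1-based in R; the coordinate convention used
#' throughout the package counts voxels from 0).
#'
#' @slot values numeric 3D array, dim = (slices, rows, columns).
#' @slot geometry a \linkS4class{VoxelGeometry}.
#' @slot subjectId character scalar.
#' @export
setClass("ImageStack",
  representation(values = "array", geometry = "VoxelGeometry",
                 subjectId = "character"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3L) return("values must be a 3D array")
    if (d[1] < 1L) return("stack must contain at least one slice")
    if (!all(is.finite(object@values))) return("intensities must be finite")
    TRUE
  })

#' @rdname ImageStack-class
#' @param values numeric 3D array (slice, row, column).
#' @param geometry a \linkS4class{VoxelGeometry}.
#' @param subjectId character identifier.
#' @return An \linkS4class{ImageStack}.
#' @export
imageStack <- function(values, geometry = voxelGeometry(),
                       subjectId = "subject") {
  storage.mode(values) <- "double"
  new("ImageStack", values = values, geometry = geometry,
      subjectId = subjectId)
}

#' Landmark annotations for one subject
#'
#' Holds the seven landmark voxel positions in the fixed anatomical order:
#' (1) origin of the left common carotid artery, (2) aortic isthmus,
#' (3) tricuspid valve, (4) aortic / neo-aortic valve, (5) mitral valve,
#' (6) right ventricular apex, (7) descending aorta at diaphragm level.
#'
#' @slot landmarks numeric 7 x 3 matrix of 0-based voxel indices, columns
#'   (slice, row, col), rows ordered by landmark number.
#' @slot label either \code{"HLHS"} or \code{"control"}.
#' @slot observerId one of \code{"observer1"}, \code{"observer2"},
#'   \code{"ground_truth"}.
#' @slot subjectId character scalar.
#' @export
setClass("AnnotationSet",
  representation(landmarks = "matrix", label = "character",
                 observerId = "character", subjectId = "character"),
  validity = function(object) {
    lm <- object@landmarks
    if (!is.numeric(lm) || nrow(lm) != 7L || ncol(lm) != 3L)
      return("landmarks must be a numeric 7 x 3 matrix")
    if (!all(is.finite(lm))) return("landmark positions must be finite")
    if (any(lm < 0)) return("voxel indices must be non-negative (0-based)")
    if (!object@label %in% CLASS_LABELS)
      return(sprintf("label must be one of: %s",
                     paste(CLASS_LABELS, collapse = ", ")))
    if (!object@observerId %in% OBSERVER_IDS)
      return(sprintf("observerId must be one of: %s",
                     paste(OBSERVER_IDS, collapse = ", ")))
    TRUE
  })

#' @rdname AnnotationSet-class
#' @param landmarks 7 x 3 matrix of 0-based (slice, row, col) voxel indices.
#' @param label \code{"HLHS"} or \code{"control"}.
#' @param observerId annotating observer identity.
#' @param subjectId character identifier.
#' @return An \linkS4class{AnnotationSet}.
#' @export
annotationSet <- function(landmarks, label, observerId = "ground_truth",
                          subjectId = "subject") {
  landmarks <- as.matrix(landmarks)
  dimnames(landmarks) <- list(NULL, c("slice", "row", "col"))
  new("AnnotationSet", landmarks = landmarks, label = label,
      observerId = observerId, subjectId = subjectId)
}

#' Per-landmark heatmap volume
#'
#' The regression target (and network prediction) for one landmark: a
#' temperature field on the coarse head-output grid, shaped as a Gaussian
#' with peak value k at the landmark voxel.
#'
#' @slot values numeric 3D array (slice, row, col) on the coarse grid.
#' @slot landmarkId integer 1-7.
#' @slot geometry \linkS4class{VoxelGeometry} of the coarse grid.
#' @export
setClass("HeatmapVolume",
  representation(values = "array", landmarkId = "integer",
                 geometry = "VoxelGeometry"),
  validity = function(object) {
    if (length(dim(object@values)) != 3L)
      return("values must be a 3D array")
    if (!all(is.finite(object@values))) return("temperatures must be finite")
    if (any(object@values < 0)) return("temperatures must be non-negative")
    if (!(object@landmarkId %in% 1:7)) return("landmarkId must be in 1..7")
    TRUE
  })

heatmapVolume <- function(values, landmarkId, geometry) {
  new("HeatmapVolume", values = values, landmarkId = as.integer(landmarkId),
      geometry = geometry)
}

#' Landmark point cloud in millimetre coordinates
#'
#' @slot points numeric 7 x 3 matrix, mm coordinates (z, y, x), one row per
#'   landmark 1-7.
#' @slot subjectId character scalar.
#' @slot label \code{"HLHS"}, \code{"control"}, or \code{NA} when unknown.
#' @export
setClass("PointCloud",
  representation(points = "matrix", subjectId = "character",
                 label = "character"),
  validity = function(object) {
    p <- object@points
    if (!is.numeric(p) || nrow(p) != 7L || ncol(p) != 3L)
      return("points must be a numeric 7 x 3 matrix")
    if (!all(is.finite(p))) return("coordinates must be finite")
    if (!is.na(object@label) && !object@label %in% CLASS_LABELS)
      return("label must be HLHS, control, or NA")
    TRUE
  })

#' @rdname PointCloud-class
#' @param points 7 x 3 mm matrix (z, y, x).
#' @param subjectId character identifier.
#' @param label class label or \code{NA}.
#' @return A \linkS4class{PointCloud}.
#' @export
pointCloud <- function(points, subjectId = "subject", label = NA_character_) {
  points <- as.matrix(points)
  dimnames(points) <- list(NULL, c("z", "y", "x"))
  new("PointCloud", points = points, subjectId = subjectId,
      label = as.character(label))
}

#' Centred landmark point cloud
#'
#' Landmark positions expressed relative to the centroid of the seven
#' landmarks, making the downstream classification invariant to global
#' translation of the anatomy within the scanner.
#'
#' @slot points numeric 7 x 3 matrix of centred mm coordinates (mean zero).
#' @slot centre numeric(3), the subtracted centroid in mm.
#' @slot subjectId character scalar.
#' @slot label class label or \code{NA}.
#' @export
setClass("CenteredPointCloud",
  representation(points = "matrix", centre = "numeric",
                 subjectId = "character", label = "character"),
  validity = function(object) {
    p <- object@points
    if (!is.numeric(p) || nrow(p) != 7L || ncol(p) != 3L)
      return("points must be a numeric 7 x 3 matrix")
    if (!all(is.finite(p))) return("coordinates must be finite")
    if (max(abs(colMeans(p))) > 1e-9)
      return("centred points must average to zero (within 1e-9 mm)")
    if (length(object@centre) != 3L) return("centre must have length 3")
    TRUE
  })

#' Fitted linear SVM over centred landmark coordinates
#'
#' Wraps a fitted soft-margin linear support vector machine on the 21
#' centred coordinates (landmark-major order: L1z, L1y, L1x, L2z, ...,
#' L7x).  The decision hyperplane coefficients are exposed for the
#' per-landmark weight summary.
#'
#' @slot fit the underlying \code{e1071::svm} object.
#' @slot coefficients numeric(21) hyperplane coefficients.
#' @slot intercept numeric(1).
#' @slot levels character(2), class labels; the decision value is positive
#'   for the first level.
#' @export
setClass("LandmarkSVM",
  representation(fit = "ANY", coefficients = "numeric",
                 intercept = "numeric", levels = "character"),
  validity = function(object) {
    if (length(object@coefficients) != 21L)
      return("coefficient vector must have length 21")
    if (length(object@levels) != 2L) return("exactly two class levels")
    TRUE
  })

#' Stratified cross-validation fold assignment
#'
#' @slot fold integer vector, validation fold number (1..k) per subject.
#' @slot labels character vector of class labels per subject.
#' @slot k integer, number of folds.
#' @export
setClass("FoldAssignment",
  representation(fold = "integer", labels = "character", k = "integer"),
  validity = function(object) {
    if (length(object@fold) != length(object@labels))
      return("fold and labels must have equal length")
    if (any(is.na(object@fold)) || any(object@fold < 1L) ||
        any(object@fold > object@k))
      return("fold numbers must lie in 1..k")
    if (!setequal(unique(object@fold), seq_len(object@k)))
      return("every fold must receive at least one subject")
    TRUE
  })
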