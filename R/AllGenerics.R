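#' Accessors for landmarknet data objects
#'
#' @param object a landmarknet S4 object.
#' @return The slot value: intensity array, geometry, identifier, label,
#'   landmark matrix, point matrix or centroid, depending on the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("stackValues", function(object) standardGeneric("stackValues"))
#' @rdname accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("subjectLabel", function(object) standardGeneric("subjectLabel"))
#' @rdname accessors
#' @export
setGeneric("observerId", function(object) standardGeneric("observerId"))
#' @rdname accessors
#' @export
setGeneric("landmarkVoxels", function(object) standardGeneric("landmarkVoxels"))
#' @rdname accessors
#' @export
setGeneric("cloudPoints", function(object) standardGeneric("cloudPoints"))
#' @rdname accessors
#' @export
setGeneric("cloudCentre", function(object) standardGeneric("cloudCentre"))
#' @rdname accessors
#' @export
setGeneric("landmarkId", function(object) standardGeneric("landmarkId"))
#' @rdname accessors
#' @export
setGeneric("foldOf", function(object) standardGeneric("foldOf"))

setMethod("stackValues", "ImageStack", function(object) object@values)
setMethod("stackValues", "HeatmapVolume", function(object) object@values)
setMethod("geometry", "ImageStack", function(object) object@geometry)
setMethod("geometry", "HeatmapVolume", function(object) object@geometry)
setMethod("subjectId", "ImageStack", function(object) object@subjectId)
setMethod("subjectId", "AnnotationSet", function(object) object@subjectId)
setMethod("subjectId", "PointCloud", function(object) object@subjectId)
setMethod("subjectId", "CenteredPointCloud", function(object) object@subjectId)
setMethod("subjectLabel", "AnnotationSet", function(object) object@label)
setMethod("subjectLabel", "PointCloud", function(object) object@label)
setMethod("subjectLabel", "CenteredPointCloud", function(object) object@label)
setMethod("observerId", "AnnotationSet", function(object) object@observerId)
setMethod("landmarkVoxels", "AnnotationSet", function(object) object@landmarks)
setMethod("cloudPoints", "PointCloud", function(object) object@points)
setMethod("cloudPoints", "CenteredPointCloud", function(object) object@points)
setMethod("cloudCentre", "CenteredPointCloud", function(object) object@centre)
setMethod("landmarkId", "HeatmapVolume", function(object) object@landmarkId)
setMethod("foldOf", "FoldAssignment", function(object) object@fold)

setMethod("show", "VoxelGeometry", function(object) {
  cat("VoxelGeometry: in-plane",
      paste(format(object@inPlaneSpacing, digits = 4), collapse = " x "),
      "mm, slice", format(object@sliceSpacing, digits = 4), "mm, origin (",
      paste(format(object@origin, digits = 4), collapse = ", "), ") mm\n")
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("ImageStack '%s': %d slices x %d x %d, intensities [%.3g, %.3g]\n",
              object@subjectId, d[1], d[2], d[3],
              min(object@values), max(object@values)))
  show(object@geometry)
})

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet '%s' (%s, %s): 7 landmarks (slice,row,col)\n",
              object@subjectId, object@label, object@observerId))
  m <- cbind(landmark = 1:7, object@landmarks)
  print(m)
})

setMethod("show", "HeatmapVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("HeatmapVolume landmark %d (%s): %d x %d x %d, peak %.4g\n",
              object@landmarkId, LANDMARK_NAMES[object@landmarkId],
              d[1], d[2], d[3], max(object@values)))
})

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud '%s' (label %s), mm (z,y,x):\n",
              object@subjectId, object@label))
  print(round(object@points, 2))
})

setMethod("show", "CenteredPointCloud", function(object) {
  cat(sprintf("CenteredPointCloud '%s' (label %s), centre (%s) mm:\n",
              object@subjectId, object@label,
              paste(round(object@centre, 2), collapse = ", ")))
  print(round(object@points, 2))
})

setMethod("show", "LandmarkSVM", function(object) {
  cat("LandmarkSVM: linear SVM on 21 centred landmark coordinates\n")
  cat("  levels:", paste(object@levels, collapse = " vs "),
      " intercept:", format(object@intercept, digits = 4), "\n")
})

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment: %d subjects in %d stratified folds\n",
              length(object@fold), object@k))
  print(table(fold = object@fold, label = object@labels))
})
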