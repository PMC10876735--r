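#' @importFrom RNifti readNifti writeNifti pixdim
#' @importFrom jsonlite fromJSON toJSON read_json write_json
#' @importFrom stats rnorm runif sd lm coef predict setNames
#' @importFrom utils write.csv read.csv
NULL

lmnError <- function(message, class) {
  stop(errorCondition(message, class = c(class, "landmarknetError")))
}

CANONICAL_SLICES <- 33L
CANONICAL_INPLANE <- c(256L, 256L)

## ---- voxel <-> mm -----------------------------------------------------

#' Convert voxel indices to millimetre coordinates
#'
#' Position = origin + index * spacing per axis, with the slice axis using
#' the slice spacing; indices are 0-based and refer to voxel centres.
#'
#' @param geometry a \linkS4class{VoxelGeometry}.
#' @param index numeric(3) voxel index (slice, row, col) or an n x 3 matrix.
#' @return mm coordinates (z, y, x), same shape as the input.
#' @examples
#' g <- voxelGeometry(1.5, 6)
#' voxelToMm(g, c(2, 10, 10))  # (12, 15, 15) mm
#' @export
voxelToMm <- function(geometry, index) {
  stopifnot(is(geometry, "VoxelGeometry"))
  scale <- c(geometry@sliceSpacing, geometry@inPlaneSpacing)
  if (is.matrix(index)) {
    out <- sweep(sweep(index, 2L, scale, "*"), 2L, geometry@origin, "+")
    dimnames(out) <- list(rownames(index), c("z", "y", "x"))
    out
  } else {
    unname(geometry@origin + as.numeric(index) * scale)
  }
}

#' Convert millimetre coordinates back to (fractional) voxel indices
#'
#' Exact inverse of \code{\link{voxelToMm}}; integer voxel indices round-trip
#' exactly.
#'
#' @inheritParams voxelToMm
#' @param mm numeric(3) mm position (z, y, x) or an n x 3 matrix.
#' @return Voxel indices (slice, row, col), possibly fractional.
#' @export
mmToVoxel <- function(geometry, mm) {
  stopifnot(is(geometry, "VoxelGeometry"))
  scale <- c(geometry@sliceSpacing, geometry@inPlaneSpacing)
  if (is.matrix(mm)) {
    out <- sweep(sweep(mm, 2L, geometry@origin, "-"), 2L, scale, "/")
    dimnames(out) <- list(rownames(mm), c("slice", "row", "col"))
    out
  } else {
    unname((as.numeric(mm) - geometry@origin) / scale)
  }
}

## ---- preprocessing ----------------------------------------------------

# Dense 1D bilinear interpolation matrix (nout x nin), centre-aligned:
# input coordinate of output sample j (0-based) is (j + 0.5) * nin/nout - 0.5.
# Identity (exactly) when nout == nin.
interpMatrix <- function(nout, nin) {
  zoom <- nin / nout
  pos <- (seq_len(nout) - 0.5) * zoom - 0.5
  lo <- floor(pos)
  w <- pos - lo
  lo <- pmin(pmax(lo, 0), nin - 1L)
  hi <- pmin(lo + 1L, nin - 1L)
  A <- matrix(0, nout, nin)
  A[cbind(seq_len(nout), lo + 1L)] <- A[cbind(seq_len(nout), lo + 1L)] + (1 - w)
  A[cbind(seq_len(nout), hi + 1L)] <- A[cbind(seq_len(nout), hi + 1L)] + w
  A
}

#' Preprocess a stack to the canonical network input shape
#'
#' Crops the stack to the first \code{targetSlices} slices (counting from the
#' top of the stack), appends zero-valued slices if there are fewer, and
#' bilinearly resamples every slice to the target in-plane resolution.  The
#' in-plane voxel spacings (and the origin) are rescaled accordingly, so that
#' \code{\link{voxelToMm}} keeps addressing the same physical positions.
#' Non-square inputs are resampled anisotropically, one factor per axis.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param targetSlices number of output slices (default 33).
#' @param targetInPlane numeric(2) output (rows, cols), default c(256, 256).
#' @return The preprocessed \linkS4class{ImageStack} with dimensions
#'   \code{targetSlices x targetInPlane}.
#' @export
preprocessStack <- function(stack, targetSlices = CANONICAL_SLICES,
                            targetInPlane = CANONICAL_INPLANE) {
  stopifnot(is(stack, "ImageStack"))
  targetSlices <- as.integer(targetSlices)
  targetInPlane <- as.integer(targetInPlane)
  if (targetSlices < 1L || any(targetInPlane < 1L))
    lmnError("target dimensions must be positive", "landmarknetConfigError")
  v <- stack@values
  d <- dim(v)
  # slice crop / zero-pad
  if (d[1] >= targetSlices) {
    v <- v[seq_len(targetSlices), , , drop = FALSE]
  } else {
    pad <- array(0, c(targetSlices - d[1], d[2], d[3]))
    v <- array(c(aperm(v, c(2, 3, 1)), aperm(pad, c(2, 3, 1))),
               c(d[2], d[3], targetSlices))
    v <- aperm(v, c(3, 1, 2))
  }
  # in-plane bilinear resampling via interpolation matrices
  Ar <- interpMatrix(targetInPlane[1], d[2])
  Ac <- interpMatrix(targetInPlane[2], d[3])
  out <- array(0, c(targetSlices, targetInPlane))
  for (z in seq_len(targetSlices))
    out[z, , ] <- Ar %*% v[z, , ] %*% t(Ac)
  zoom <- c(d[2], d[3]) / targetInPlane
  g <- stack@geometry
  newGeom <- voxelGeometry(
    inPlaneSpacing = g@inPlaneSpacing * zoom,
    sliceSpacing = g@sliceSpacing,
    origin = g@origin + c(0, (zoom - 1) / 2 * g@inPlaneSpacing))
  imageStack(out, newGeom, stack@subjectId)
}

## ---- stack I/O --------------------------------------------------------

#' Read an image stack from disk
#'
#' Supported formats: a NIfTI-1 volume, a DICOM series directory (one
#' single-frame file per slice, explicit VR little endian), or the package's
#' internal RDS serialisation.  Geometry is populated from header metadata
#' (pixel spacing and slice spacing).  Patient-orientation matrices are not
#' interpreted: the array axes are taken as (slice, row, column) directly.
#'
#' @param path file (nifti, internal) or directory (dicom_series).
#' @param format one of \code{"nifti"}, \code{"dicom_series"},
#'   \code{"internal"}.
#' @return An \linkS4class{ImageStack}.
#' @export
readStack <- function(path, format = c("nifti", "dicom_series", "internal")) {
  format <- match.arg(format)
  if (!file.exists(path))
    lmnError(sprintf("path does not exist: %s", path), "landmarknetFormatError")
  switch(format,
    nifti = {
      img <- tryCatch(RNifti::readNifti(path), error = function(e)
        lmnError(sprintf("cannot read NIfTI '%s': %s", path,
                         conditionMessage(e)), "landmarknetFormatError"))
      pd <- attr(img, "pixdim")
      if (is.null(pd)) pd <- RNifti::pixdim(img)
      if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
        lmnError("NIfTI header lacks positive voxel spacings",
                 "landmarknetMetadataError")
      # NIfTI arrays are (x, y, z); the stack convention is (slice, row, col)
      vals <- aperm(as.array(img), c(3, 2, 1))
      geom <- voxelGeometry(inPlaneSpacing = c(pd[2], pd[1]),
                            sliceSpacing = pd[3])
      imageStack(vals, geom,
                 subjectId = sub("\\.nii(\\.gz)?$", "", basename(path)))
    },
    dicom_series = readDicomSeries(path),
    internal = {
      obj <- readRDS(path)
      if (!is(obj, "ImageStack"))
        lmnError("internal file does not contain an ImageStack",
                 "landmarknetFormatError")
      obj
    })
}

#' Write an image stack as a NIfTI-1 volume
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path output filename (.nii or .nii.gz).
#' @return Invisibly, \code{path}.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  g <- stack@geometry
  arr <- aperm(stack@values, c(3, 2, 1))  # back to (x, y, z)
  img <- RNifti::asNifti(arr, reference = NULL)
  RNifti::pixdim(img) <- c(g@inPlaneSpacing[2], g@inPlaneSpacing[1],
                           g@sliceSpacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

## ---- annotation I/O ---------------------------------------------------

annotationToList <- function(a) {
  list(subject_id = a@subjectId, label = a@label, observer_id = a@observerId,
       landmarks = lapply(1:7, function(j) list(
         id = j, name = LANDMARK_NAMES[j],
         slice = a@landmarks[j, 1], row = a@landmarks[j, 2],
         col = a@landmarks[j, 3])))
}

annotationFromList <- function(x, stackDim = NULL) {
  lms <- x$landmarks
  if (is.null(lms) || length(lms) != 7L)
    lmnError(sprintf("subject '%s': expected exactly 7 landmarks, found %d",
                     x$subject_id %||% "?", length(lms)),
             "landmarknetSchemaError")
  ids <- vapply(lms, function(l) as.integer(l$id), integer(1))
  if (!identical(sort(ids), 1:7))
    lmnError("landmark ids must be exactly 1..7", "landmarknetSchemaError")
  m <- matrix(NA_real_, 7, 3)
  for (l in lms)
    m[as.integer(l$id), ] <- c(l$slice, l$row, l$col)
  if (!is.null(x$label) && !x$label %in% CLASS_LABELS)
    lmnError(sprintf("label '%s' is not one of: %s", x$label,
                     paste(CLASS_LABELS, collapse = ", ")),
             "landmarknetValidationError")
  if (!is.null(stackDim)) {
    if (any(m < 0) || any(sweep(m, 2L, stackDim, ">=")))
      lmnError(sprintf("subject '%s': landmark outside the stack bounds",
                       x$subject_id %||% "?"), "landmarknetValidationError")
  }
  ann <- tryCatch(
    annotationSet(m, label = x$label,
                  observerId = x$observer_id %||% "ground_truth",
                  subjectId = x$subject_id %||% "subject"),
    error = function(e)
      lmnError(conditionMessage(e), "landmarknetValidationError"))
  ann
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write annotation sets to a JSON file
#'
#' Schema (version 1.0): \code{{"version", "annotations": [{"subject_id",
#' "label", "observer_id", "landmarks": [{"id","name","slice","row","col"}
#' x 7]}]}}.  Landmark order and numbering are preserved.
#'
#' @param sets a list of \linkS4class{AnnotationSet} objects.
#' @param path output JSON filename.
#' @return Invisibly, \code{path}.
#' @export
writeAnnotations <- function(sets, path) {
  if (is(sets, "AnnotationSet")) sets <- list(sets)
  payload <- list(version = "1.0",
                  annotations = lapply(sets, annotationToList))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read annotation sets from a JSON file
#'
#' @param path JSON file written by \code{\link{writeAnnotations}} (or
#'   conforming to its schema).
#' @param stackDim optional integer(3) stack dimensions (slices, rows, cols)
#'   against which landmark positions are bounds-checked.
#' @return A list of \linkS4class{AnnotationSet} objects.
#' @export
readAnnotations <- function(path, stackDim = NULL) {
  if (!file.exists(path))
    lmnError(sprintf("path does not exist: %s", path),
             "landmarknetFormatError")
  x <- tryCatch(jsonlite::read_json(path), error = function(e)
    lmnError(sprintf("cannot parse JSON '%s': %s", path,
                     conditionMessage(e)), "landmarknetFormatError"))
  if (is.null(x$annotations))
    lmnError("missing 'annotations' element", "landmarknetSchemaError")
  lapply(x$annotations, annotationFromList, stackDim = stackDim)
}

#' Check that annotations fall inside a stack and its slice crop
#'
#' Annotations whose slice index would be discarded by the canonical crop
#' (slice index >= \code{targetSlices}) are rejected.
#'
#' @param ann an \linkS4class{AnnotationSet}.
#' @param stack the \linkS4class{ImageStack} the annotation refers to.
#' @param targetSlices the slice-crop length (default 33).
#' @return Invisibly \code{TRUE}; throws a validation error otherwise.
#' @export
validateAnnotation <- function(ann, stack, targetSlices = CANONICAL_SLICES) {
  d <- dim(stack@values)
  m <- ann@landmarks
  if (any(m < 0) || any(sweep(m, 2L, d, ">=")))
    lmnError("landmark outside the stack bounds", "landmarknetValidationError")
  if (any(m[, 1] >= targetSlices))
    lmnError(sprintf("landmark beyond the %d-slice crop", targetSlices),
             "landmarknetValidationError")
  invisible(TRUE)
}
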