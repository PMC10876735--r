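#' Heatmap configuration
#'
#' Parameters of the Gaussian target heatmaps: peak temperature \code{k}
#' (dimensionless; a large value stabilises early training) and the per-axis
#' standard deviation \code{sigma}, expressed in voxel extents of the target
#' grid, so the Gaussian exponent is \code{-sum(dIndex^2) / (2 sigma^2)} in
#' index units.
#'
#' @param k peak temperature, > 0 (default 1e3).
#' @param sigma per-axis standard deviation in voxels, > 0; a scalar is
#'   recycled to the three axes.
#' @return A list with elements \code{k} and \code{sigma} (length 3).
#' @export
heatmapConfig <- function(k = 1e3, sigma = 1) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  if (k <= 0 || any(sigma <= 0))
    lmnError("k and sigma must be strictly positive",
             "landmarknetConfigError")
  list(k = as.numeric(k), sigma = as.numeric(sigma))
}

#' Build a Gaussian target heatmap for one landmark
#'
#' The temperature at voxel v is
#' \code{k * exp(-sum_d (v_d - p_d)^2 / (2 sigma_d^2))}: maximal (= k)
#' exactly at the landmark voxel p and monotonically decreasing with
#' distance along every axis.
#'
#' @param landmark numeric(3), 0-based voxel position (slice, row, col) on
#'   the target grid.
#' @param gridShape integer(3), target grid dimensions (slices, rows, cols).
#' @param config a \code{\link{heatmapConfig}}.
#' @param landmarkId integer 1-7 carried as metadata.
#' @param geometry optional \linkS4class{VoxelGeometry} of the target grid.
#' @return A \linkS4class{HeatmapVolume}.
#' @export
makeHeatmap <- function(landmark, gridShape, config = heatmapConfig(),
                        landmarkId = 1L, geometry = voxelGeometry()) {
  landmark <- as.numeric(landmark)
  if (any(landmark < 0) || any(landmark > gridShape - 1L))
    lmnError("landmark lies outside the target grid",
             "landmarknetValidationError")
  q <- lapply(1:3, function(d)
    exp(-((seq_len(gridShape[d]) - 1 - landmark[d])^2) /
          (2 * config$sigma[d]^2)))
  vals <- config$k * (q[[1]] %o% q[[2]] %o% q[[3]])
  heatmapVolume(vals, landmarkId, geometry)
}

# 7x7x7 neighbourhood sum around a 0-based position, window clipped at the
# volume boundary (equivalent to zero padding for non-negative heatmaps).
neighbourhoodScore <- function(values, pos) {
  d <- dim(values)
  rng <- lapply(1:3, function(a)
    max(0L, pos[a] - 3L):min(d[a] - 1L, pos[a] + 3L) + 1L)
  sum(values[rng[[1]], rng[[2]], rng[[3]]])
}

#' Recover the landmark position from a (predicted) heatmap
#'
#' Returns the position of the maximum temperature.  If the maximum is
#' attained at several voxels, the position maximising the 7x7x7
#' neighbourhood sum S of the heatmap around it is chosen (the window is
#' clipped at the volume boundary); any remaining tie is broken by the
#' lexicographically smallest (slice, row, col) index.
#'
#' @param heatmap a \linkS4class{HeatmapVolume} or a 3D numeric array.
#' @return numeric(3), the 0-based (slice, row, col) voxel position.
#' @export
extractLandmark <- function(heatmap) {
  values <- if (is(heatmap, "HeatmapVolume")) heatmap@values else heatmap
  if (length(values) == 0L)
    lmnError("empty heatmap", "landmarknetValidationError")
  if (all(is.na(values)))
    lmnError("all-NaN heatmap", "landmarknetValidationError")
  m <- max(values, na.rm = TRUE)
  cand <- which(values == m, arr.ind = TRUE)  # 1-based, lexicographic in
  cand <- cand[, c(1, 2, 3), drop = FALSE] - 1L  # column-major order
  if (nrow(cand) > 1L) {
    s <- apply(cand, 1L, function(p) neighbourhoodScore(values, p))
    cand <- cand[s == max(s), , drop = FALSE]
    if (nrow(cand) > 1L) {
      ord <- do.call(order, lapply(1:3, function(j) cand[, j]))
      cand <- cand[ord, , drop = FALSE]
    }
  }
  unname(cand[1L, ])
}

#' Map a coarse-grid voxel index to the fine grid
#'
#' Head outputs live on a grid downsampled in-plane by an integer factor
#' (4 by default: 256 -> 64).  A coarse in-plane index c maps to the centre
#' of its fine-grid block, \code{factor * c + (factor - 1) / 2}; the slice
#' index is unchanged.
#'
#' @param coarse numeric(3) or n x 3 matrix of 0-based (slice, row, col)
#'   coarse indices.
#' @param factor integer in-plane downsampling factor (>= 1).
#' @return Fine-grid (possibly fractional) voxel indices, same shape.
#' @export
coarseToFine <- function(coarse, factor = 4L) {
  factor <- as.integer(factor)
  if (factor < 1L)
    lmnError("factor must be a positive integer", "landmarknetConfigError")
  off <- (factor - 1) / 2
  if (is.matrix(coarse)) {
    out <- coarse
    out[, 2:3] <- factor * coarse[, 2:3] + off
    out
  } else {
    c(coarse[1], factor * coarse[2:3] + off)
  }
}

#' Map an annotation to the coarse target grid
#'
#' In-plane indices are divided by the downsampling factor and rounded to
#' the nearest coarse voxel; the slice index is kept.  The inverse of
#' \code{\link{coarseToFine}} up to the rounding.
#'
#' @param fine numeric(3) or n x 3 matrix of fine-grid voxel indices.
#' @param factor integer in-plane downsampling factor.
#' @param gridShape integer(3) coarse grid shape used to clamp the result.
#' @return 0-based coarse-grid indices.
#' @export
fineToCoarse <- function(fine, factor = 4L, gridShape = NULL) {
  off <- (factor - 1) / 2
  clamp <- function(m) {
    if (!is.null(gridShape))
      for (j in 1:3) m[, j] <- pmin(pmax(m[, j], 0), gridShape[j] - 1L)
    m
  }
  if (!is.matrix(fine)) fine <- matrix(fine, 1L)
  out <- fine
  out[, 2:3] <- round((fine[, 2:3] - off) / factor)
  out <- clamp(round(out))
  if (nrow(out) == 1L) unname(out[1L, ]) else out
}

#' Target heatmaps for one annotated subject
#'
#' Converts the 7 annotated voxel positions to Gaussian heatmaps on the
#' coarse head-output grid (in-plane indices divided by \code{factor} and
#' rounded; slice index kept).
#'
#' @param ann an \linkS4class{AnnotationSet} (positions on the preprocessed
#'   fine grid).
#' @param stackGeometry \linkS4class{VoxelGeometry} of the preprocessed
#'   stack.
#' @param gridShape coarse grid dimensions (default c(33, 64, 64)).
#' @param factor in-plane downsampling factor between stack and heads.
#' @param config a \code{\link{heatmapConfig}}.
#' @return A list of 7 \linkS4class{HeatmapVolume} objects, landmark order
#'   1-7.
#' @export
annotationToHeatmaps <- function(ann, stackGeometry = voxelGeometry(),
                                 gridShape = c(33L, 64L, 64L), factor = 4L,
                                 config = heatmapConfig()) {
  stopifnot(is(ann, "AnnotationSet"))
  coarseGeom <- coarseGeometry(stackGeometry, factor)
  lapply(1:7, function(j) {
    p <- fineToCoarse(ann@landmarks[j, ], factor, gridShape)
    makeHeatmap(p, gridShape, config, landmarkId = j, geometry = coarseGeom)
  })
}

#' Geometry of the coarse head-output grid
#'
#' The coarse voxel (s, r, c) sits at the centre of its in-plane block of
#' fine voxels, so predictions extracted on the head grid can be mapped to
#' millimetres directly.
#'
#' @param fineGeometry \linkS4class{VoxelGeometry} of the preprocessed
#'   stack.
#' @param factor in-plane downsampling factor between stack and heads.
#' @return A \linkS4class{VoxelGeometry} for the coarse grid.
#' @export
coarseGeometry <- function(fineGeometry, factor = 4L) {
  voxelGeometry(
    inPlaneSpacing = fineGeometry@inPlaneSpacing * factor,
    sliceSpacing = fineGeometry@sliceSpacing,
    origin = fineGeometry@origin +
      c(0, (factor - 1) / 2 * fineGeometry@inPlaneSpacing))
}
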