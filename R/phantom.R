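#' Synthetic two-class phantom cohort specification
#'
#' Describes a cohort of synthetic "anatomies": per class, a template of 7
#' landmark positions in mm; per subject, independent Gaussian jitter of
#' the template; per volume, bright Gaussian blobs rendered at the
#' landmarks (with distinct amplitudes, so landmarks are distinguishable
#' by appearance as well as by position), a tubular connector running
#' through landmarks 1-2-7 as vessel-like context, and Gaussian background
#' noise.  The patient class differs from the control class by a shift of
#' the aortic-valve landmark (landmark 4) plus mild shifts of landmarks 3
#' and 6 -- the geometry the downstream classifier is supposed to pick up.
#'
#' @slot nPatients,nControls cohort sizes (defaults 46 / 33).
#' @slot shape integer(3) volume dimensions (slices, rows, cols).
#' @slot geometry \linkS4class{VoxelGeometry} of the rendered volumes.
#' @slot templateControl 7 x 3 matrix, control-class landmark template in
#'   mm (z, y, x).
#' @slot classShift 7 x 3 matrix, mm offset added to the template for the
#'   patient class.
#' @slot jitterSD within-class per-coordinate jitter SD in mm.
#' @slot renderRadius blob radius in mm (the Gaussian blob is rendered
#'   with sigma = renderRadius / 2, so the bright core spans the radius).
#' @slot blobAmplitude numeric(7) peak intensity per landmark blob.
#' @slot noiseSD background Gaussian noise SD (intensity units).
#' @slot tubeAmplitude,tubeRadius intensity and cross-section sigma (mm)
#'   of the 1-2-7 tubular connector.
#' @slot seed integer; all cohort randomness derives from it.
#' @export
setClass("PhantomSpec",
  representation(nPatients = "integer", nControls = "integer",
                 shape = "integer", geometry = "VoxelGeometry",
                 templateControl = "matrix", classShift = "matrix",
                 jitterSD = "numeric", renderRadius = "numeric",
                 blobAmplitude = "numeric", noiseSD = "numeric",
                 tubeAmplitude = "numeric", tubeRadius = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@nPatients < 0L || object@nControls < 0L)
      return("cohort sizes must be non-negative")
    if (length(object@shape) != 3L || any(object@shape < 1L))
      return("shape must be 3 positive integers")
    for (m in list(object@templateControl,
                   object@templateControl + object@classShift)) {
      if (nrow(m) != 7L || ncol(m) != 3L)
        return("landmark templates must be 7 x 3")
      ext <- voxelToMm(object@geometry, object@shape - 1L)
      lo <- object@geometry@origin
      margin <- object@renderRadius
      if (any(sweep(m, 2L, lo + margin, "<")) ||
          any(sweep(m, 2L, ext - margin, ">")))
        return("template landmarks must lie inside the volume with a margin of one render radius")
    }
    if (object@jitterSD < 0) return("jitterSD must be >= 0")
    if (object@renderRadius <= 0) return("renderRadius must be positive")
    if (length(object@blobAmplitude) != 7L)
      return("blobAmplitude must have length 7")
    TRUE
  })

#' @rdname PhantomSpec-class
#' @param nPatients,nControls,shape,jitterSD,renderRadius,blobAmplitude,noiseSD,tubeAmplitude,tubeRadius,seed
#'   see the class slots.
#' @param geometry a \linkS4class{VoxelGeometry}; the default uses 1.7 mm
#'   in-plane pixels and 6 mm slices.
#' @param templateControl,classShift landmark templates (mm); when NULL,
#'   anatomically plausible defaults are placed at fixed fractional
#'   positions of the field of view, with the patient class shifted by
#'   40 mm at landmark 4 and mildly at landmarks 3 and 6.
#' @return A \linkS4class{PhantomSpec}.
#' @examples
#' phantomSpec(shape = c(33, 64, 64), geometry = voxelGeometry(2, 6))
#' @export
phantomSpec <- function(nPatients = 46L, nControls = 33L,
                        shape = c(33L, 256L, 256L),
                        geometry = voxelGeometry(c(1.7, 1.7), 6),
                        templateControl = NULL, classShift = NULL,
                        jitterSD = 3, renderRadius = 10,
                        blobAmplitude = 0.4 * 1.45^(0:6),
                        noiseSD = 0.05, tubeAmplitude = 0.25,
                        tubeRadius = 3, seed = 1L) {
  shape <- as.integer(shape)
  if (is.null(templateControl)) {
    # fractional (z, y, x) positions: superior-to-inferior ordering follows
    # the anatomy (carotid origin high, descending aorta at the diaphragm
    # low), with the mediastinal clustering of the real structures kept --
    # valve landmarks sit close together near the volume centre
    frac <- matrix(c(
      0.15, 0.45, 0.48,   # 1 carotid origin (high in the stack)
      0.25, 0.50, 0.45,   # 2 aortic isthmus
      0.55, 0.52, 0.60,   # 3 tricuspid valve
      0.52, 0.46, 0.50,   # 4 aortic / neo-aortic valve
      0.55, 0.50, 0.38,   # 5 mitral valve
      0.72, 0.56, 0.56,   # 6 RV apex (low, lateral)
      0.85, 0.55, 0.42),  # 7 descending aorta at diaphragm
      7, 3, byrow = TRUE)
    ext <- voxelToMm(geometry, shape - 1L) - geometry@origin
    templateControl <- sweep(frac, 2L, ext, "*") +
      matrix(geometry@origin, 7, 3, byrow = TRUE)
  }
  if (is.null(classShift)) {
    classShift <- matrix(0, 7, 3)
    classShift[4, 3] <- 40     # aortic -> neo-aortic valve shift (RL)
    classShift[3, 3] <- 10
    classShift[6, 2] <- 8
  }
  tryCatch(
    new("PhantomSpec", nPatients = as.integer(nPatients),
        nControls = as.integer(nControls), shape = shape,
        geometry = geometry, templateControl = templateControl,
        classShift = classShift, jitterSD = as.numeric(jitterSD),
        renderRadius = as.numeric(renderRadius),
        blobAmplitude = as.numeric(blobAmplitude),
        noiseSD = as.numeric(noiseSD),
        tubeAmplitude = as.numeric(tubeAmplitude),
        tubeRadius = as.numeric(tubeRadius), seed = as.integer(seed)),
    error = function(e) lmnError(conditionMessage(e),
                                 "landmarknetConfigError"))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0(
    "PhantomSpec: %d patients + %d controls, volumes %s\n",
    "  jitter SD %.3g mm, blob radius %.3g mm, noise SD %.3g, seed %d\n"),
    object@nPatients, object@nControls,
    paste(object@shape, collapse = "x"), object@jitterSD,
    object@renderRadius, object@noiseSD, object@seed))
})

subjectSeed <- function(spec, i) {
  as.integer((as.numeric(spec@seed) * 7919 + i * 104729) %% 2147483647)
}

# mm grid coordinates along each axis of the volume
axisMm <- function(spec) {
  g <- spec@geometry
  list(z = g@origin[1] + (seq_len(spec@shape[1]) - 1) * g@sliceSpacing,
       y = g@origin[2] + (seq_len(spec@shape[2]) - 1) * g@inPlaneSpacing[1],
       x = g@origin[3] + (seq_len(spec@shape[3]) - 1) * g@inPlaneSpacing[2])
}

addBlob <- function(vol, ax, centre, amp, sigma) {
  rng <- lapply(1:3, function(d) which(abs(ax[[d]] - centre[d]) <= 3 * sigma))
  if (any(lengths(rng) == 0L)) return(vol)
  qz <- exp(-(ax$z[rng[[1]]] - centre[1])^2 / (2 * sigma^2))
  qy <- exp(-(ax$y[rng[[2]]] - centre[2])^2 / (2 * sigma^2))
  qx <- exp(-(ax$x[rng[[3]]] - centre[3])^2 / (2 * sigma^2))
  vol[rng[[1]], rng[[2]], rng[[3]]] <-
    vol[rng[[1]], rng[[2]], rng[[3]]] + amp * (qz %o% qy %o% qx)
  vol
}

# Gaussian-cross-section tube along the segment from a to b (mm)
addSegment <- function(vol, ax, a, b, amp, sigma) {
  lo <- pmin(a, b) - 3 * sigma
  hi <- pmax(a, b) + 3 * sigma
  rng <- lapply(1:3, function(d) which(ax[[d]] >= lo[d] & ax[[d]] <= hi[d]))
  if (any(lengths(rng) == 0L)) return(vol)
  gz <- ax$z[rng[[1]]]; gy <- ax$y[rng[[2]]]; gx <- ax$x[rng[[3]]]
  u <- b - a
  len2 <- sum(u^2)
  # distance of every voxel in the box to the segment, vectorised
  pz <- array(gz, c(length(gz), length(gy), length(gx)))
  py <- aperm(array(gy, c(length(gy), length(gz), length(gx))), c(2, 1, 3))
  px <- aperm(array(gx, c(length(gx), length(gz), length(gy))), c(2, 3, 1))
  t <- ((pz - a[1]) * u[1] + (py - a[2]) * u[2] + (px - a[3]) * u[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  d2 <- (pz - (a[1] + t * u[1]))^2 + (py - (a[2] + t * u[2]))^2 +
    (px - (a[3] + t * u[3]))^2
  vol[rng[[1]], rng[[2]], rng[[3]]] <-
    vol[rng[[1]], rng[[2]], rng[[3]]] + amp * exp(-d2 / (2 * sigma^2))
  vol
}

renderSubject <- function(spec, posMm) {
  ax <- axisMm(spec)
  vol <- array(0, spec@shape)
  sigma <- spec@renderRadius / 2
  for (j in 1:7)
    vol <- addBlob(vol, ax, posMm[j, ], spec@blobAmplitude[j], sigma)
  if (spec@tubeAmplitude > 0) {
    vol <- addSegment(vol, ax, posMm[1, ], posMm[2, ], spec@tubeAmplitude,
                      spec@tubeRadius)
    vol <- addSegment(vol, ax, posMm[2, ], posMm[7, ], spec@tubeAmplitude,
                      spec@tubeRadius)
  }
  if (spec@noiseSD > 0)
    vol <- vol + array(stats::rnorm(prod(spec@shape), sd = spec@noiseSD),
                       spec@shape)
  vol
}

#' Sample a phantom cohort
#'
#' Per subject: landmark positions are drawn as class template plus
#' independent Gaussian jitter (resampled, up to 20 tries, if a landmark
#' would leave the volume); the volume is rendered as blobs + tube +
#' noise; the ground-truth annotation is the jittered position quantised
#' to its voxel.  Fully deterministic given the spec seed -- every subject
#' has its own derived sub-seed, so any subject can be regenerated in
#' isolation.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param render logical; \code{FALSE} skips volume rendering and returns
#'   annotations only (fast path for classifier-level studies).
#' @return A list with elements \code{stacks} (list of
#'   \linkS4class{ImageStack} or NULL), \code{annotations} (list of
#'   \linkS4class{AnnotationSet}), \code{labels} (character vector),
#'   \code{truthMm} (list of exact 7 x 3 mm positions) and \code{spec}.
#' @export
sampleCohort <- function(spec, render = TRUE) {
  stopifnot(is(spec, "PhantomSpec"))
  n <- spec@nPatients + spec@nControls
  labels <- c(rep("HLHS", spec@nPatients), rep("control", spec@nControls))
  stacks <- if (render) vector("list", n) else NULL
  annotations <- vector("list", n)
  truthMm <- vector("list", n)
  g <- spec@geometry
  for (i in seq_len(n)) {
    set.seed(subjectSeed(spec, i))
    template <- spec@templateControl +
      if (labels[i] == "HLHS") spec@classShift else 0
    pos <- NULL
    for (try in 1:20) {
      cand <- template + matrix(stats::rnorm(21, sd = spec@jitterSD), 7, 3)
      vox <- round(mmToVoxel(g, cand))
      if (all(vox >= 0) && all(sweep(vox, 2L, spec@shape, "<"))) {
        pos <- cand
        break
      }
    }
    if (is.null(pos))
      lmnError(sprintf("landmarks of subject %d repeatedly left the volume",
                       i), "landmarknetValidationError")
    sid <- sprintf("phantom%03d", i)
    truthMm[[i]] <- pos
    annotations[[i]] <- annotationSet(round(mmToVoxel(g, pos)),
                                      label = labels[i],
                                      observerId = "ground_truth",
                                      subjectId = sid)
    if (render)
      stacks[[i]] <- imageStack(renderSubject(spec, pos), g, sid)
  }
  list(stacks = stacks, annotations = annotations, labels = labels,
       truthMm = truthMm, spec = spec)
}

#' Simulate a second observer by jittering annotations
#'
#' Adds independent per-coordinate Gaussian offsets (in mm) to each
#' landmark and re-quantises to voxels, emulating the annotation
#' variability of an independent human observer.
#'
#' @param annotations list of \linkS4class{AnnotationSet} objects.
#' @param geometry the \linkS4class{VoxelGeometry} the annotations live on.
#' @param sdMm per-coordinate offset SD in mm (>= 0).
#' @param gridShape integer(3) used to clamp offsets at the volume edge.
#' @param seed RNG seed.
#' @return A list of \linkS4class{AnnotationSet} objects with
#'   \code{observerId = "observer2"}.
#' @export
simulateSecondObserver <- function(annotations, geometry, sdMm = 5,
                                   gridShape, seed = 1L) {
  if (sdMm < 0)
    lmnError("sdMm must be >= 0", "landmarknetConfigError")
  set.seed(seed)
  lapply(annotations, function(a) {
    mm <- voxelToMm(geometry, a@landmarks)
    mm <- mm + matrix(stats::rnorm(21, sd = sdMm), 7, 3)
    vox <- round(mmToVoxel(geometry, mm))
    for (d in 1:3) vox[, d] <- pmin(pmax(vox[, d], 0), gridShape[d] - 1L)
    annotationSet(vox, a@label, observerId = "observer2",
                  subjectId = a@subjectId)
  })
}

# order-independent FNV-1a hash of the deparsed spec, for the manifest
specHash <- function(spec) {
  s <- paste(
    spec@nPatients, spec@nControls, paste(spec@shape, collapse = ","),
    paste(spec@geometry@inPlaneSpacing, collapse = ","),
    spec@geometry@sliceSpacing,
    paste(spec@geometry@origin, collapse = ","),
    paste(signif(spec@templateControl, 10), collapse = ","),
    paste(signif(spec@classShift, 10), collapse = ","),
    spec@jitterSD, spec@renderRadius,
    paste(spec@blobAmplitude, collapse = ","), spec@noiseSD,
    spec@tubeAmplitude, spec@tubeRadius, spec@seed, sep = "|")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    # xor on the low byte only (b < 256), keeping h a double mod 2^32
    h <- (h %/% 256) * 256 + bitwXor(as.integer(h %% 256), as.integer(b))
    # 32-bit modular multiply by the FNV prime without double overflow
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Export a phantom cohort to disk
#'
#' Writes one NIfTI volume per subject, a single annotations JSON file and
#' a manifest CSV (subject_id, label, seed, spec hash).
#'
#' @param cohort result of \code{\link{sampleCohort}} (rendered).
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest data.frame.
#' @export
exportCohort <- function(cohort, dir) {
  if (is.null(cohort$stacks))
    lmnError("cohort was sampled with render = FALSE",
             "landmarknetValidationError")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(cohort$annotations)
  for (i in seq_len(n))
    writeStack(cohort$stacks[[i]],
               file.path(dir, paste0(subjectId(cohort$stacks[[i]]), ".nii")))
  writeAnnotations(cohort$annotations, file.path(dir, "annotations.json"))
  manifest <- data.frame(
    subject_id = vapply(cohort$annotations, subjectId, character(1)),
    label = cohort$labels,
    seed = cohort$spec@seed,
    spec_hash = specHash(cohort$spec))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read back an exported phantom cohort
#'
#' @param dir directory written by \code{\link{exportCohort}}.
#' @return A list with \code{stacks}, \code{annotations}, \code{labels}
#'   and \code{manifest}.
#' @export
readCohort <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf))
    lmnError(sprintf("no manifest.csv in '%s'", dir),
             "landmarknetFormatError")
  manifest <- utils::read.csv(mf)
  stacks <- lapply(manifest$subject_id, function(sid)
    readStack(file.path(dir, paste0(sid, ".nii")), "nifti"))
  annotations <- readAnnotations(file.path(dir, "annotations.json"))
  list(stacks = stacks, annotations = annotations,
       labels = manifest$label, manifest = manifest)
}
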