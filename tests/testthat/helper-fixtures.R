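# Shared fixtures: everything is generated in code at test time.

# Independent brute-force oracle for landmark extraction: scan for the
# maximum, enumerate every position attaining it, compute the 7x7x7
# neighbourhood sum by explicit triple loop with window clipping, and break
# remaining ties by (slice, row, col) order.
bruteExtract <- function(v) {
  d <- dim(v)
  mx <- max(v)
  cand <- which(v == mx, arr.ind = TRUE) - 1L
  score <- function(p) {
    s <- 0
    for (i in max(0, p[1] - 3):min(d[1] - 1, p[1] + 3))
      for (j in max(0, p[2] - 3):min(d[2] - 1, p[2] + 3))
        for (k in max(0, p[3] - 3):min(d[3] - 1, p[3] + 3))
          s <- s + v[i + 1, j + 1, k + 1]
    s
  }
  ss <- apply(cand, 1, score)
  cand <- cand[ss == max(ss), , drop = FALSE]
  cand <- cand[order(cand[, 1], cand[, 2], cand[, 3]), , drop = FALSE]
  unname(cand[1, ])
}

# A small deterministic stack with a recognisable intensity pattern.
makeTestStack <- function(nz = 5, ny = 12, nx = 10, spacing = c(1.5, 1.5),
                          slice = 6, subjectId = "t01") {
  vals <- array(seq_len(nz * ny * nx) / (nz * ny * nx), c(nz, ny, nx))
  imageStack(vals, voxelGeometry(spacing, slice), subjectId)
}

# Seven landmark voxels spread inside a given stack shape.
makeTestLandmarks <- function(dims) {
  frac <- matrix(c(0.2, 0.3, 0.4,
                   0.3, 0.5, 0.5,
                   0.4, 0.6, 0.3,
                   0.5, 0.4, 0.6,
                   0.6, 0.5, 0.4,
                   0.7, 0.7, 0.7,
                   0.8, 0.5, 0.5), 7, 3, byrow = TRUE)
  floor(sweep(frac, 2L, dims - 1L, "*"))
}

makeTestAnnotation <- function(dims = c(5, 12, 10), label = "control",
                               subjectId = "t01",
                               observerId = "ground_truth") {
  annotationSet(makeTestLandmarks(dims), label, observerId, subjectId)
}

# Tiny phantom spec used across model-level tests: 33 x 64 x 64 volumes,
# 2 mm pixels, 6 mm slices.
tinyPhantomSpec <- function(nPatients = 4, nControls = 4, seed = 11, ...) {
  phantomSpec(nPatients = nPatients, nControls = nControls,
              shape = c(33, 64, 64), geometry = voxelGeometry(2, 6),
              seed = seed, ...)
}

# A centred cloud with a deterministic offset pattern.
makeCenteredCloud <- function(shiftMm = 0, label = "control",
                              subjectId = "c01", jitter = NULL) {
  base <- matrix(c(10, 20, 30,
                   40, 25, 35,
                   60, 40, 20,
                   55, 30, 50,
                   62, 35, 28,
                   80, 45, 42,
                   95, 38, 30), 7, 3, byrow = TRUE)
  base[4, 3] <- base[4, 3] + shiftMm
  if (!is.null(jitter)) base <- base + jitter
  centerPointCloud(pointCloud(base, subjectId, label))
}

# Two-class cohort of centred clouds, landmark 4 separated by `sep` mm.
makeCloudCohort <- function(nPerClass = 10, sep = 40, sd = 3, seed = 5) {
  set.seed(seed)
  c(lapply(seq_len(nPerClass), function(i)
      makeCenteredCloud(sep, "HLHS", sprintf("p%02d", i),
                        jitter = matrix(rnorm(21, sd = sd), 7, 3))),
    lapply(seq_len(nPerClass), function(i)
      makeCenteredCloud(0, "control", sprintf("c%02d", i),
                        jitter = matrix(rnorm(21, sd = sd), 7, 3))))
}
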