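test_that("phantom cohorts are deterministic and correctly labelled", {
  spec <- tinyPhantomSpec(nPatients = 3, nControls = 2, seed = 4)
  c1 <- sampleCohort(spec)
  c2 <- sampleCohort(spec)
  expect_identical(c1$labels, c(rep("HLHS", 3), rep("control", 2)))
  for (i in seq_along(c1$stacks)) {
    expect_identical(stackValues(c1$stacks[[i]]), stackValues(c2$stacks[[i]]))
    expect_identical(landmarkVoxels(c1$annotations[[i]]),
                     landmarkVoxels(c2$annotations[[i]]))
  }
  # different seed changes the data
  c3 <- sampleCohort(tinyPhantomSpec(nPatients = 3, nControls = 2, seed = 5))
  expect_false(identical(stackValues(c1$stacks[[1]]),
                         stackValues(c3$stacks[[1]])))
})

test_that("zero jitter reproduces the class template exactly", {
  spec <- tinyPhantomSpec(nPatients = 2, nControls = 2, jitterSD = 0)
  cohort <- sampleCohort(spec, render = FALSE)
  g <- spec@geometry
  for (i in 1:2)
    expect_equal(cohort$truthMm[[i]], spec@templateControl + spec@classShift)
  for (i in 3:4)
    expect_equal(cohort$truthMm[[i]], spec@templateControl)
})

test_that("the brightest voxel near each landmark is within one voxel of it", {
  spec <- tinyPhantomSpec(nPatients = 1, nControls = 1, noiseSD = 0.01,
                          seed = 23)
  cohort <- sampleCohort(spec)
  g <- spec@geometry
  for (i in 1:2) {
    v <- stackValues(cohort$stacks[[i]])
    lm <- landmarkVoxels(cohort$annotations[[i]])
    for (j in 1:7) {
      # search one blob sigma (in mm, converted per axis) around the true
      # landmark; adjacent valve landmarks sit closer than a full render
      # radius, so a wider box could legitimately contain a neighbour's
      # brighter peak
      r <- ceiling(spec@renderRadius / 2 /
                     c(g@sliceSpacing, g@inPlaneSpacing))
      rngZ <- max(1, lm[j, 1] + 1 - r[1]):min(dim(v)[1], lm[j, 1] + 1 + r[1])
      rngY <- max(1, lm[j, 2] + 1 - r[2]):min(dim(v)[2], lm[j, 2] + 1 + r[2])
      rngX <- max(1, lm[j, 3] + 1 - r[3]):min(dim(v)[3], lm[j, 3] + 1 + r[3])
      sub <- v[rngZ, rngY, rngX, drop = FALSE]
      w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
      bright <- c(rngZ[w[1]], rngY[w[2]], rngX[w[3]]) - 1
      expect_true(all(abs(bright - lm[j, ]) <= 1))
    }
  }
})

test_that("ground-truth centred clouds are linearly separable at the default class shift", {
  spec <- tinyPhantomSpec(nPatients = 8, nControls = 8, seed = 6)
  # default shift 40 mm on landmark 4 >= 5 x jitter SD 3 mm
  expect_gte(spec@classShift[4, 3], 5 * spec@jitterSD)
  cohort <- sampleCohort(spec, render = FALSE)
  clouds <- lapply(cohort$annotations, function(a)
    centerPointCloud(toPointCloud(a, spec@geometry)))
  fit <- fitClassifier(clouds)
  pred <- classifyCloud(fit, clouds)
  expect_equal(classificationAccuracy(cohort$labels, pred), 1.0)
})

test_that("second observer simulation has the requested offset law", {
  spec <- tinyPhantomSpec(nPatients = 2, nControls = 2, seed = 8)
  cohort <- sampleCohort(spec, render = FALSE)
  g <- spec@geometry
  # SD 0: identical annotations
  same <- simulateSecondObserver(cohort$annotations, g, sdMm = 0,
                                 gridShape = spec@shape, seed = 1)
  for (i in seq_along(same)) {
    expect_equal(landmarkVoxels(same[[i]]), landmarkVoxels(cohort$annotations[[i]]))
    expect_identical(observerId(same[[i]]), "observer2")
  }
  # SD 5 mm: mean 3D offset magnitude ~ 5 * 2 * sqrt(2/pi) ~ 7.98 mm
  big <- sampleCohort(tinyPhantomSpec(nPatients = 150, nControls = 150,
                                      seed = 9), render = FALSE)
  obs2 <- simulateSecondObserver(big$annotations, g, sdMm = 5,
                                 gridShape = spec@shape, seed = 2)
  offs <- unlist(lapply(seq_along(obs2), function(i)
    displacement(voxelToMm(g, landmarkVoxels(big$annotations[[i]])),
                 voxelToMm(g, landmarkVoxels(obs2[[i]])))))
  # voxel re-quantisation adds ~ +/- half-voxel noise on top of the law
  expect_equal(mean(offs), 5 * 2 * sqrt(2 / pi), tolerance = 0.08)
  # offsets are independent across landmarks
  m1 <- vapply(obs2, function(a) landmarkVoxels(a)[1, 3], numeric(1)) -
    vapply(big$annotations, function(a) landmarkVoxels(a)[1, 3], numeric(1))
  m2 <- vapply(obs2, function(a) landmarkVoxels(a)[2, 3], numeric(1)) -
    vapply(big$annotations, function(a) landmarkVoxels(a)[2, 3], numeric(1))
  expect_lt(abs(cor(m1, m2)), 0.15)
})

test_that("export / read round trip preserves the cohort and the manifest contract", {
  spec <- tinyPhantomSpec(nPatients = 2, nControls = 1, seed = 12)
  cohort <- sampleCohort(spec)
  dir <- file.path(tempdir(), "phantomExport")
  manifest <- exportCohort(cohort, dir)
  expect_equal(nrow(manifest), 3)
  rt <- readCohort(dir)
  expect_equal(rt$labels, cohort$labels)
  for (i in 1:3) {
    expect_equal(stackValues(rt$stacks[[i]]), stackValues(cohort$stacks[[i]]),
                 tolerance = 1e-6)
    expect_equal(landmarkVoxels(rt$annotations[[i]]),
                 landmarkVoxels(cohort$annotations[[i]]))
  }
  unlink(dir, recursive = TRUE)
})

test_that("the spec hash responds to any field change", {
  s1 <- tinyPhantomSpec(seed = 1)
  expect_identical(landmarknet:::specHash(s1),
                   landmarknet:::specHash(tinyPhantomSpec(seed = 1)))
  expect_false(landmarknet:::specHash(s1) ==
                 landmarknet:::specHash(tinyPhantomSpec(seed = 2)))
  expect_false(landmarknet:::specHash(s1) ==
                 landmarknet:::specHash(tinyPhantomSpec(seed = 1,
                                                        jitterSD = 4)))
  expect_false(landmarknet:::specHash(s1) ==
                 landmarknet:::specHash(tinyPhantomSpec(seed = 1,
                                                        noiseSD = 0.06)))
})

test_that("templates violating the margin invariant are rejected", {
  g <- voxelGeometry(2, 6)
  bad <- matrix(5, 7, 3)   # hugs the volume corner, inside margin
  expect_error(phantomSpec(shape = c(33, 64, 64), geometry = g,
                           templateControl = bad,
                           classShift = matrix(0, 7, 3)),
               class = "landmarknetConfigError")
})
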