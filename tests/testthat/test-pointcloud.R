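test_that("voxel landmarks map to mm pointwise through the geometry", {
  g <- voxelGeometry(2, 6)
  lm <- makeTestLandmarks(c(33, 64, 64))
  pc <- toPointCloud(lm, g)
  expect_equal(cloudPoints(pc), voxelToMm(g, lm))
  # spacing 2 mm: in-plane index 10 -> 20 mm
  lm0 <- matrix(0, 7, 3); lm0[1, ] <- c(0, 10, 10)
  expect_equal(cloudPoints(toPointCloud(lm0, g))[1, ],
               c(z = 0, y = 20, x = 20))
  expect_equal(unname(cloudPoints(toPointCloud(lm0, g))[2, ]), c(0, 0, 0))
  expect_error(toPointCloud(lm[1:6, ], g), class = "landmarknetValidationError")
})

test_that("centring subtracts the centroid and is translation invariant", {
  pts <- rbind(c(0, 0, 0), c(7, 0, 0), c(0, 7, 0), c(0, 0, 7),
               c(7, 7, 0), c(7, 0, 7), c(0, 7, 7))
  cc <- centerPointCloud(pointCloud(pts))
  expect_equal(cloudCentre(cc), c(3, 3, 3))
  expect_equal(unname(cloudPoints(cc)[1, ]), c(-3, -3, -3))
  expect_equal(unname(colMeans(cloudPoints(cc))), c(0, 0, 0))
  # global translation changes nothing after centring
  shifted <- centerPointCloud(pointCloud(
    sweep(pts, 2L, c(100, -50, 8), "+")))
  expect_equal(cloudPoints(shifted), cloudPoints(cc))
  # already-centred cloud is a fixed point
  again <- centerPointCloud(pointCloud(cloudPoints(cc)))
  expect_equal(cloudPoints(again), cloudPoints(cc))
})

test_that("point-cloud augmentation adds bounded uniform jitter with the originals kept", {
  clouds <- makeCloudCohort(nPerClass = 3, seed = 2)[c(1, 2, 4, 5, 6)]
  set.seed(9)
  aug <- augmentPointClouds(clouds, nCopies = 400, shiftRange = 10)
  expect_length(aug, 5 * 401)
  expect_equal(cloudPoints(aug[[1]]), cloudPoints(clouds[[1]]))
  labs <- vapply(aug, subjectLabel, character(1))
  expect_identical(unique(labs[1:401]), subjectLabel(clouds[[1]]))
  set.seed(9)
  none <- augmentPointClouds(clouds, nCopies = 0)
  expect_length(none, 5)
})

test_that("the uniform jitter law has the stated range and zero mean", {
  base <- makeCenteredCloud()
  set.seed(31)
  aug <- augmentPointClouds(list(base), nCopies = 3000, shiftRange = 10)
  # replicas are re-centred, so their stored points are u - mean(u); the
  # replica's own centroid is mean(u), which recovers the raw draws u
  shifts <- vapply(aug[-1], function(cl)
    as.numeric(cloudPoints(cl) +
                 matrix(cloudCentre(cl), 7, 3, byrow = TRUE) -
                 cloudPoints(base)),
    numeric(21))
  expect_lt(max(abs(shifts)), 10 + 1e-9)
  expect_lt(abs(mean(shifts)), 0.15)
  # a fair share of draws reaches the outer half of the range
  expect_gt(mean(abs(shifts) > 5), 0.4)
})

test_that("linearly separable classes are fit perfectly and weights identify the separated landmark", {
  clouds <- makeCloudCohort(nPerClass = 10, sep = 40, sd = 3)
  fit <- fitClassifier(clouds)
  pred <- classifyCloud(fit, clouds)
  truth <- vapply(clouds, subjectLabel, character(1))
  expect_equal(classificationAccuracy(truth, pred), 1.0)
  ws <- weightSummary(fit)
  expect_equal(attr(ws, "strongest"), 4L)
  expect_equal(which.max(ws$rms), 4L)
  # our linear decision values must agree with the underlying library
  dec <- attr(pred, "decision")
  libPred <- predict(fit@fit, landmarknet:::cloudFeatures(clouds))
  expect_identical(as.character(pred), as.character(libPred))
})

test_that("flipping the labels negates the decision boundary", {
  clouds <- makeCloudCohort(nPerClass = 5, sep = 30, sd = 2, seed = 8)
  flip <- lapply(clouds, function(cl) {
    new("CenteredPointCloud", points = cl@points, centre = cl@centre,
        subjectId = cl@subjectId,
        label = if (cl@label == "HLHS") "control" else "HLHS")
  })
  f1 <- fitClassifier(clouds)
  f2 <- fitClassifier(flip)
  expect_equal(f2@coefficients, -f1@coefficients, tolerance = 1e-6)
  expect_equal(f2@intercept, -f1@intercept, tolerance = 1e-6)
})

test_that("two-point toy problem recovers the analytic max-margin hyperplane", {
  # two mirrored clouds differing only in landmark 4's x by +/- d: the
  # max-margin hyperplane passes through the midpoint with w = 2*delta/|delta|^2
  d <- 8
  a <- makeCenteredCloud(+d, "HLHS", "a")
  b <- makeCenteredCloud(-d, "control", "b")
  fit <- fitClassifier(list(a, b))
  fa <- as.numeric(t(cloudPoints(a)))
  fb <- as.numeric(t(cloudPoints(b)))
  delta <- fa - fb
  wExpect <- 2 * delta / sum(delta^2)
  expect_equal(fit@coefficients, wExpect, tolerance = 1e-4)
  # midpoint sits on the boundary
  mid <- (fa + fb) / 2
  expect_equal(as.numeric(mid %*% fit@coefficients + fit@intercept), 0,
               tolerance = 1e-6)
})

test_that("single-class input and unfitted models are rejected", {
  clouds <- makeCloudCohort(nPerClass = 4)[1:4]   # all HLHS
  expect_error(fitClassifier(clouds), class = "landmarknetValidationError")
  expect_error(classifyCloud("not a model", makeCenteredCloud()),
               class = "landmarknetValidationError")
})

test_that("weight summary computes signed max and RMS per landmark", {
  fit <- fitClassifier(makeCloudCohort(nPerClass = 4, seed = 3))
  fake <- fit
  fake@coefficients <- c(3, 0, 0, rep(0, 18))
  ws <- weightSummary(fake)
  expect_equal(ws$max[1], 3)
  expect_equal(ws$rms[1], sqrt(3))
  expect_equal(ws$max[2:7], rep(0, 6))
  expect_equal(ws$rms[2:7], rep(0, 6))
  # |max| can never exceed sqrt(3) * RMS
  real <- weightSummary(fit)
  expect_true(all(abs(real$max) <= sqrt(3) * real$rms + 1e-12))
})

test_that("classification of a raw cloud is invariant under global translation", {
  clouds <- makeCloudCohort(nPerClass = 6, sep = 25, sd = 2, seed = 4)
  fit <- fitClassifier(clouds)
  raw <- sweep(cloudPoints(clouds[[1]]), 2L, c(37, -12, 90), "+")
  p1 <- classifyCloud(fit, centerPointCloud(pointCloud(raw, label = "HLHS")))
  p2 <- classifyCloud(fit, clouds[[1]])
  expect_identical(as.character(p1), as.character(p2))
  expect_equal(attr(p1, "decision"), attr(p2, "decision"), tolerance = 1e-9)
})
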