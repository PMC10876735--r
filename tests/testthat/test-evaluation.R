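test_that("displacement is the Euclidean norm", {
  expect_equal(displacement(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(displacement(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(13)
  for (i in 1:100) {
    g <- rnorm(3); l <- rnorm(3)
    # independent componentwise recomputation
    expect_equal(displacement(g, l),
                 sqrt((g[1] - l[1])^2 + (g[2] - l[2])^2 + (g[3] - l[3])^2))
  }
})

test_that("cohort landmark statistics reduce to forced arithmetic", {
  g <- voxelGeometry(1, 1)
  mk <- function(pts, id) pointCloud(pts, id, "control")
  base <- matrix(rep(c(5, 5, 5), 7), 7, 3, byrow = TRUE)
  ann <- list(mk(base, "s1"), mk(base, "s2"))
  # identical predictions: everything zero
  st0 <- cohortLandmarkStats(ann, ann)
  expect_equal(st0$meanDisp, rep(0, 7))
  expect_equal(st0$sdDisp, rep(0, 7))
  # landmark 1 displaced by 3 mm and 5 mm -> mean 4
  p1 <- base; p1[1, ] <- p1[1, ] + c(3, 0, 0)
  p2 <- base; p2[1, ] <- p2[1, ] + c(0, 5, 0)
  st <- cohortLandmarkStats(list(mk(p1, "s1"), mk(p2, "s2")), ann)
  expect_equal(st$meanDisp[1], 4)
  expect_equal(st$meanDisp[2:7], rep(0, 6))
  expect_true(all(st$meanDisp >= 0))
  # subject mismatch is an error
  expect_error(cohortLandmarkStats(list(mk(p1, "sX"), mk(p2, "s2")), ann),
               class = "landmarknetValidationError")
})

test_that("interobserver variability matches the 3D chi-distribution mean", {
  # offsets ~ N(0, sd^2) per coordinate: E||offset|| = sd * 2 * sqrt(2/pi)
  sd <- 5
  set.seed(77)
  n <- 4000
  base <- matrix(rep(c(50, 50, 50), 7), 7, 3, byrow = TRUE)
  ann <- lapply(seq_len(n), function(i)
    pointCloud(base, sprintf("s%04d", i), "control"))
  obs2 <- lapply(seq_len(n), function(i)
    pointCloud(base + matrix(rnorm(21, sd = sd), 7, 3),
               sprintf("s%04d", i), "control"))
  st <- cohortLandmarkStats(ann, ann, secondObserver = obs2)
  expected <- sd * 2 * sqrt(2 / pi)   # ~7.98 mm for sd = 5
  expect_equal(mean(st$interobserver), expected, tolerance = 0.03)
  expect_true(all(abs(st$interobserver - expected) / expected < 0.05))
})

test_that("Bland-Altman recovers bias, limits and a planted proportional bias", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(blandAltman(a, a)$bias, 0)
  expect_equal(blandAltman(a, a)$sd, 0)
  expect_equal(blandAltman(a, a)$slope, 0)
  ba <- blandAltman(a + 2, a)
  expect_equal(ba$bias, 2)
  expect_equal(ba$sd, 0)
  expect_equal(ba$lower, 2)
  expect_equal(ba$upper, 2)
  # planted proportional bias of 0.1 at n = 500
  set.seed(21)
  b <- rnorm(500, 50, 20)
  a2 <- b + 0.1 * b + rnorm(500, 0, 1)
  slope <- blandAltman(a2, b)$slope
  expect_equal(slope, 0.1, tolerance = 0.2)   # within 20 % relative
  expect_error(blandAltman(1:2, 1:2), class = "landmarknetValidationError")
})

test_that("limits of agreement bracket ~95% of differences for Gaussian noise", {
  set.seed(3)
  b <- rnorm(2000, 100, 10)
  a <- b + rnorm(2000, 1, 2)
  ba <- blandAltman(a, b)
  inside <- mean(ba$differences > ba$lower & ba$differences < ba$upper)
  expect_gt(inside, 0.93)
  expect_lt(inside, 0.97)
})

test_that("classification accuracy counts correct fractions and rejects empty input", {
  expect_equal(classificationAccuracy(rep("a", 4), rep("a", 4)), 1.0)
  expect_equal(classificationAccuracy(c(rep("HLHS", 78), "control"),
                                      rep("HLHS", 79)), 78 / 79)
  expect_equal(classificationAccuracy(c("a", "a"), c("a", "b")), 0.5)
  expect_error(classificationAccuracy(character(0), character(0)),
               class = "landmarknetValidationError")
  # invariance under consistent relabelling
  truth <- c("HLHS", "control", "HLHS", "control")
  pred <- c("HLHS", "HLHS", "HLHS", "control")
  swap <- function(x) ifelse(x == "HLHS", "control", "HLHS")
  expect_equal(classificationAccuracy(truth, pred),
               classificationAccuracy(swap(truth), swap(pred)))
})

test_that("stratified folds partition the 46+33 cohort with preserved ratios", {
  labels <- c(rep("HLHS", 46), rep("control", 33))
  fa <- stratifiedKFold(labels, k = 5, seed = 3)
  fold <- foldOf(fa)
  sizes <- table(fold)
  expect_true(all(sizes %in% c(15, 16)))
  expect_equal(sum(sizes), 79)
  # every subject validates exactly once by construction of the vector
  expect_length(fold, 79)
  # class counts per fold within one of the proportional share
  for (f in 1:5) {
    expect_true(abs(sum(fold == f & labels == "HLHS") - 46 / 5) < 1)
    expect_true(abs(sum(fold == f & labels == "control") - 33 / 5) < 1)
  }
  # determinism
  fa2 <- stratifiedKFold(labels, k = 5, seed = 3)
  expect_identical(foldOf(fa2), fold)
  expect_false(identical(foldOf(stratifiedKFold(labels, k = 5, seed = 4)),
                         fold))
  expect_error(stratifiedKFold(c(rep("a", 3), rep("b", 9)), k = 5),
               class = "landmarknetValidationError")
})

test_that("stratification bound holds across cohort shapes", {
  set.seed(10)
  for (trial in 1:20) {
    k <- sample(2:6, 1)
    npos <- sample(k:40, 1); nneg <- sample(k:40, 1)
    labels <- sample(c(rep("HLHS", npos), rep("control", nneg)))
    fold <- foldOf(stratifiedKFold(labels, k = k, seed = trial))
    for (f in seq_len(k)) {
      expect_lt(abs(sum(fold == f & labels == "HLHS") - npos / k), 1)
      expect_lt(abs(sum(fold == f & labels == "control") - nneg / k), 1)
    }
  }
})

test_that("network-based cross-validation produces the full report shape on a micro cohort", {
  spec <- phantomSpec(nPatients = 3, nControls = 3, shape = c(8, 32, 32),
                      geometry = voxelGeometry(4, 6),
                      templateControl = matrix(
                        c(12, 30, 30, 15, 60, 40, 18, 50, 80, 21, 64, 64,
                          24, 80, 50, 27, 90, 90, 30, 64, 100), 7, 3,
                        byrow = TRUE),
                      jitterSD = 2, renderRadius = 12, seed = 9)
  cohort <- sampleCohort(spec)
  res <- runCrossval(cohort$stacks, cohort$annotations,
                     modelCfg = modelConfig(firstLayerFilters = 3,
                                            maxDepth = 3,
                                            headSplitDepth = 2,
                                            inputShape = c(8, 32, 32)),
                     trainCfg = trainConfig(5e-3, 2L, 1L),
                     k = 2, seed = 5)
  expect_true(is.numeric(res$accuracy) && res$accuracy >= 0 &&
                res$accuracy <= 1)
  expect_length(res$foldAccuracy, 2)
  expect_s4_class(res$folds, "FoldAssignment")
  expect_equal(nrow(res$landmarkStats), 7)
  expect_true(all(res$landmarkStats$meanDisp >= 0))
  expect_length(res$predictions, 6)
  # validation folds partition the cohort
  expect_equal(sort(unlist(lapply(1:2, function(f)
    which(foldOf(res$folds) == f)))), 1:6)
})

test_that("annotation-only cross-validation achieves perfect accuracy on separable phantoms", {
  spec <- tinyPhantomSpec(nPatients = 10, nControls = 10, seed = 19)
  cohort <- sampleCohort(spec, render = FALSE)
  res <- runCrossval(NULL, cohort$annotations, geometry = spec@geometry,
                     k = 5, seed = 2, useAnnotations = TRUE)
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$foldAccuracy, rep(1, 5))
  # per-fold validation sets reconstruct the cohort exactly once
  expect_equal(sort(unlist(lapply(1:5, function(f)
    which(foldOf(res$folds) == f)))), 1:20)
  # the shifted aortic-valve landmark dominates the weights in every fold
  for (w in res$weights)
    expect_equal(attr(w, "strongest"), 4L)
})
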