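# Model-level tests run on a reduced input shape (33 x 32 x 32 or smaller)
# so the architecture contracts can be exercised quickly on one CPU; the
# full-size 33 x 256 x 256 path is covered by the acceptance suite.

test_that("config validation enforces the hyper-parameter search ranges", {
  expect_s4_class(modelConfig(firstLayerFilters = 3), "ModelConfig")
  expect_s4_class(modelConfig(firstLayerFilters = 9), "ModelConfig")
  expect_error(modelConfig(firstLayerFilters = 10),
               class = "landmarknetConfigError")
  expect_error(modelConfig(firstLayerFilters = 2),
               class = "landmarknetConfigError")
  expect_error(modelConfig(headSplitDepth = 1),
               class = "landmarknetConfigError")
  expect_error(modelConfig(headSplitDepth = 7),
               class = "landmarknetConfigError")
  expect_error(modelConfig(headSplitDepth = 3, maxDepth = 3),
               class = "landmarknetConfigError")
  # in-plane size must survive maxDepth halvings
  expect_error(modelConfig(inputShape = c(33, 48, 48), maxDepth = 7),
               class = "landmarknetConfigError")
})

test_that("encoder filter counts follow the additive +4 rule", {
  expect_equal(encoderFilters(modelConfig()), c(6, 10, 14, 18, 22, 26, 30))
  expect_equal(encoderFilters(modelConfig(firstLayerFilters = 3,
                                          maxDepth = 4,
                                          inputShape = c(33, 64, 64),
                                          headSplitDepth = 2)),
               c(3, 7, 11, 15))
})

smallCfg <- function(f0 = 3)
  modelConfig(firstLayerFilters = f0, maxDepth = 3, headSplitDepth = 2,
              inputShape = c(8, 32, 32))

test_that("the network emits 7 volumes at the pooled head resolution", {
  model <- buildModel(smallCfg(), seed = 1)
  st <- imageStack(array(rnorm(8 * 32 * 32), c(8, 32, 32)))
  out <- predictHeatmaps(model, st)
  expect_length(out, 7)
  for (h in 1:7) {
    expect_identical(dim(stackValues(out[[h]])), c(8L, 8L, 8L))
    expect_identical(landmarkId(out[[h]]), h)
  }
  expect_error(predictHeatmaps(model, makeTestStack()),
               class = "landmarknetValidationError")
})

test_that("parameter count grows with first-layer filters and head depth", {
  n3 <- numParameters(buildModel(smallCfg(3), seed = 1))
  n4 <- numParameters(buildModel(smallCfg(4), seed = 1))
  n5 <- numParameters(buildModel(smallCfg(5), seed = 1))
  expect_true(n3 < n4 && n4 < n5)
  cfgDeep <- modelConfig(firstLayerFilters = 3, maxDepth = 4,
                         headSplitDepth = 3, inputShape = c(8, 32, 32))
  cfgShallow <- modelConfig(firstLayerFilters = 3, maxDepth = 4,
                            headSplitDepth = 2, inputShape = c(8, 32, 32))
  expect_gt(numParameters(buildModel(cfgDeep, seed = 1)),
            numParameters(buildModel(cfgShallow, seed = 1)))
})

test_that("the head loss is zero for perfect predictions and positive otherwise", {
  set.seed(2)
  targets <- lapply(1:7, function(j) array(runif(4 * 6 * 6), c(1, 6, 6, 4)))
  perfect <- landmarknet:::headLoss(targets, targets)
  expect_equal(perfect$loss, 0)
  for (g in perfect$grads) expect_true(all(g == 0))
  off <- targets
  off[[3]] <- off[[3]] + 1
  worse <- landmarknet:::headLoss(off, targets)
  expect_equal(worse$loss, 1 / 7)
})

test_that("training reduces the loss on a small separable phantom set and is seed-reproducible", {
  spec <- phantomSpec(nPatients = 4, nControls = 4, shape = c(8, 32, 32),
                      geometry = voxelGeometry(4, 6),
                      templateControl = matrix(
                        c(12, 30, 30, 15, 60, 40, 18, 50, 80, 21, 64, 64,
                          24, 80, 50, 27, 90, 90, 30, 64, 100), 7, 3,
                        byrow = TRUE),
                      jitterSD = 2, renderRadius = 12, seed = 3)
  cohort <- sampleCohort(spec)
  cfg <- smallCfg()
  targets <- lapply(cohort$annotations, annotationToHeatmaps,
                    stackGeometry = spec@geometry,
                    gridShape = headOutputShape(cfg), factor = 4)
  m0 <- buildModel(cfg, seed = 5)
  tc <- trainConfig(learningRate = 5e-3, batchSize = 2, epochs = 5, seed = 5)
  m1 <- trainModel(m0, cohort$stacks, targets, tc)
  expect_length(m1@history, 5)
  expect_lt(m1@history[5], m1@history[1])
  # identical seeds give identical loss histories
  m2 <- trainModel(buildModel(cfg, seed = 5), cohort$stacks, targets, tc)
  expect_identical(m1@history, m2@history)
  # epochs = 0 returns the initial model untouched
  m3 <- trainModel(m0, cohort$stacks, targets,
                   trainConfig(epochs = 0, seed = 5))
  expect_identical(m3@params, m0@params)
  expect_length(m3@history, 0)
})

test_that("shape mismatches are rejected before any training happens", {
  model <- buildModel(smallCfg(), seed = 1)
  st <- imageStack(array(0, c(8, 32, 32)))
  good <- lapply(1:7, function(j) array(0, c(8, 8, 8)))
  bad <- lapply(1:7, function(j) array(0, c(8, 16, 16)))
  expect_error(trainModel(model, list(st), list(bad), trainConfig(epochs = 1)),
               class = "landmarknetValidationError")
  expect_error(trainModel(model, list(makeTestStack()), list(good),
                          trainConfig(epochs = 1)),
               class = "landmarknetValidationError")
  expect_error(trainModel(model, list(), list(), trainConfig(epochs = 1)),
               class = "landmarknetValidationError")
})

test_that("model save / load round trips through disk", {
  model <- buildModel(smallCfg(), seed = 4)
  path <- tempfile(fileext = ".rds")
  saveModel(model, path)
  back <- loadModel(path)
  expect_identical(back@params, model@params)
  expect_identical(back@config@inputShape, model@config@inputShape)
})

test_that("augmentation with zero limits is the identity and respects geometry", {
  st <- makeTestStack(nz = 4, ny = 24, nx = 24)
  ann <- makeTestAnnotation(c(4, 24, 24))
  cfg0 <- augmentationConfig(shiftLimit = 0, rotateLimit = 0, scaleLimit = 0,
                             blurLimit = 0, distortLimit = 0, enabled = TRUE)
  set.seed(1)
  out <- augmentPair(st, ann, cfg0)
  expect_true(out$valid)
  expect_equal(stackValues(out$stack), stackValues(st))
  expect_equal(landmarkVoxels(out$annotation), landmarkVoxels(ann))
  # augmentation must be explicitly enabled
  expect_error(augmentPair(st, ann, augmentationConfig()),
               class = "landmarknetConfigError")
})

test_that("augmentation shift stays within the configured fraction of the image", {
  st <- makeTestStack(nz = 3, ny = 64, nx = 64)
  ann <- makeTestAnnotation(c(3, 64, 64))
  cfg <- augmentationConfig(shiftLimit = 0.02, rotateLimit = 0,
                            scaleLimit = 0, blurLimit = 0, distortLimit = 0,
                            enabled = TRUE)
  set.seed(7)
  for (i in 1:20) {
    out <- augmentPair(st, ann, cfg)
    if (!out$valid) next
    d <- landmarkVoxels(out$annotation) - landmarkVoxels(ann)
    expect_true(all(abs(d[, 2:3]) <= 0.02 * 64 + 1e-9))  # <= ~1.28 px
    expect_true(all(d[, 1] == 0))
  }
})

test_that("pure rotation preserves landmark distance to the image centre", {
  st <- makeTestStack(nz = 3, ny = 48, nx = 48)
  ann <- makeTestAnnotation(c(3, 48, 48))
  cfg <- augmentationConfig(shiftLimit = 0, rotateLimit = 10, scaleLimit = 0,
                            blurLimit = 0, distortLimit = 0, enabled = TRUE)
  ctr <- (c(48, 48) - 1) / 2
  set.seed(9)
  out <- augmentPair(st, ann, cfg)
  r0 <- sqrt(rowSums(sweep(landmarkVoxels(ann)[, 2:3], 2L, ctr)^2))
  r1 <- sqrt(rowSums(sweep(landmarkVoxels(out$annotation)[, 2:3], 2L,
                           ctr)^2))
  expect_equal(r1, r0, tolerance = 1e-9)
})
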