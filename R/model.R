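#' Network architecture configuration
#'
#' Hyper-parameters of the shared-backbone, multi-head heatmap-regression
#' network.  The encoder halves the in-plane resolution \code{maxDepth}
#' times (the slice axis is never strided) while the number of filters
#' grows additively by \code{filterIncrement} per downsampling step, from
#' \code{firstLayerFilters} at full resolution.  The decoder mirrors this;
#' levels at depths greater than \code{headSplitDepth} are shared, levels at
#' depths up to \code{headSplitDepth} are replicated in each of the
#' \code{nHeads} segmentation heads.  Every head ends with in-plane max
#' pooling by \code{finalPool} and a linear-activation convolution, so a
#' (33, 256, 256) input yields seven (33, 64, 64) heatmap volumes.
#'
#' @slot firstLayerFilters integer in 3..9 (the hyper-parameter search
#'   range), default 6.
#' @slot headSplitDepth integer in 2..6, default 3: number of decoder
#'   levels owned by each head.
#' @slot maxDepth integer, number of downsampling steps, default 7.
#' @slot filterIncrement filters added per downsampling step, default 4.
#' @slot inputShape integer(3) (slices, rows, cols), default (33, 256, 256).
#' @slot nHeads number of landmarks/heads, default 7.
#' @slot finalPool in-plane pooling factor of the head output, default 4.
#' @export
setClass("ModelConfig",
  representation(firstLayerFilters = "integer", headSplitDepth = "integer",
                 maxDepth = "integer", filterIncrement = "integer",
                 inputShape = "integer", nHeads = "integer",
                 finalPool = "integer"),
  validity = function(object) {
    if (object@firstLayerFilters < 3L || object@firstLayerFilters > 9L)
      return("firstLayerFilters must lie in 3..9")
    if (object@headSplitDepth < 2L || object@headSplitDepth > 6L)
      return("headSplitDepth must lie in 2..6")
    if (object@headSplitDepth >= object@maxDepth)
      return("headSplitDepth must be smaller than maxDepth")
    if (length(object@inputShape) != 3L || any(object@inputShape < 1L))
      return("inputShape must be 3 positive integers")
    ip <- object@inputShape[2:3]
    if (any(ip %% 2L^object@maxDepth != 0L))
      return("in-plane input size must be divisible by 2^maxDepth")
    if (any(ip %% object@finalPool != 0L))
      return("in-plane input size must be divisible by finalPool")
    TRUE
  })

#' @rdname ModelConfig-class
#' @param firstLayerFilters,headSplitDepth,maxDepth,filterIncrement,inputShape,nHeads,finalPool
#'   see the class slots.
#' @return A \linkS4class{ModelConfig}.
#' @examples
#' modelConfig()                                   # the full-size network
#' modelConfig(firstLayerFilters = 3, maxDepth = 4,
#'             headSplitDepth = 2, inputShape = c(33, 64, 64))
#' @export
modelConfig <- function(firstLayerFilters = 6L, headSplitDepth = 3L,
                        maxDepth = 7L, filterIncrement = 4L,
                        inputShape = c(33L, 256L, 256L), nHeads = 7L,
                        finalPool = 4L) {
  cfg <- tryCatch(
    new("ModelConfig", firstLayerFilters = as.integer(firstLayerFilters),
        headSplitDepth = as.integer(headSplitDepth),
        maxDepth = as.integer(maxDepth),
        filterIncrement = as.integer(filterIncrement),
        inputShape = as.integer(inputShape), nHeads = as.integer(nHeads),
        finalPool = as.integer(finalPool)),
    error = function(e) lmnError(conditionMessage(e),
                                 "landmarknetConfigError"))
  cfg
}

#' Training configuration
#'
#' @slot learningRate Adam learning rate, default 5e-4; may be a vector of
#'   per-epoch rates (recycled to the epoch count), e.g. a short warmup
#'   followed by a larger rate for few-epoch desk-scale runs.
#' @slot batchSize samples per gradient step, default 2.
#' @slot epochs passes over the training set, default 32.
#' @slot seed RNG seed controlling shuffling (and, via
#'   \code{\link{buildModel}}, weight initialisation).
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", batchSize = "integer",
                 epochs = "integer", seed = "integer"),
  validity = function(object) {
    if (length(object@learningRate) < 1L || any(object@learningRate <= 0))
      return("learningRate must be positive")
    if (object@batchSize < 1L) return("batchSize must be >= 1")
    if (object@epochs < 0L) return("epochs must be >= 0")
    TRUE
  })

#' @rdname TrainConfig-class
#' @param learningRate,batchSize,epochs,seed see the class slots.
#' @return A \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(learningRate = 5e-4, batchSize = 2L, epochs = 32L,
                        seed = 1L) {
  tryCatch(
    new("TrainConfig", learningRate = as.numeric(learningRate),
        batchSize = as.integer(batchSize), epochs = as.integer(epochs),
        seed = as.integer(seed)),
    error = function(e) lmnError(conditionMessage(e),
                                 "landmarknetConfigError"))
}

#' The multi-head heatmap-regression network
#'
#' @slot config the \linkS4class{ModelConfig} the graph was built from.
#' @slot layers internal layer graph.
#' @slot params list of per-convolution weights and biases.
#' @slot outputNodes graph indices of the head outputs.
#' @slot history numeric per-epoch training loss (empty before training).
#' @export
setClass("LandmarkNet",
  representation(config = "ModelConfig", layers = "list", params = "list",
                 outputNodes = "integer", history = "numeric"))

setMethod("show", "LandmarkNet", function(object) {
  cfg <- object@config
  cat(sprintf(paste0(
    "LandmarkNet: %d-head 3D heatmap-regression network\n",
    "  input %s, depth %d, first-layer filters %d, head split depth %d\n",
    "  %d convolutions, %d parameters%s\n"),
    cfg@nHeads, paste(cfg@inputShape, collapse = "x"), cfg@maxDepth,
    cfg@firstLayerFilters, cfg@headSplitDepth, length(object@params),
    numParameters(object),
    if (length(object@history))
      sprintf(", trained %d epochs (final loss %.4g)",
              length(object@history), object@history[length(object@history)])
    else ", untrained"))
})

#' Build the network
#'
#' Constructs the layer graph and He-initialises all convolution weights
#' (ReLU hidden activations, linear output convolutions, zero-padded
#' 3x3x3 kernels throughout).
#'
#' @param config a \linkS4class{ModelConfig}.
#' @param seed RNG seed for the weight initialisation.
#' @return A \linkS4class{LandmarkNet}.
#' @export
buildModel <- function(config = modelConfig(), seed = 1L) {
  stopifnot(is(config, "ModelConfig"))
  set.seed(seed)
  g <- buildGraph(config@firstLayerFilters, config@maxDepth,
                  config@headSplitDepth, config@nHeads, config@finalPool,
                  config@filterIncrement)
  new("LandmarkNet", config = config, layers = g$layers, params = g$params,
      outputNodes = g$outputNodes, history = numeric(0))
}

#' Number of trainable parameters
#'
#' @param model a \linkS4class{LandmarkNet}.
#' @return Integer count of weights plus biases.
#' @export
numParameters <- function(model) {
  sum(vapply(model@params, function(p) length(p$W) + length(p$b), numeric(1)))
}

#' Encoder filter counts per resolution level
#'
#' @param config a \linkS4class{ModelConfig}.
#' @return Integer vector: filters at levels 0..maxDepth-1 (the bottleneck
#'   level carries one further increment).
#' @export
encoderFilters <- function(config = modelConfig()) {
  config@firstLayerFilters +
    config@filterIncrement * (seq_len(config@maxDepth) - 1L)
}

asGraph <- function(model)
  list(layers = model@layers, params = model@params,
       outputNodes = model@outputNodes)

checkCanonical <- function(stack, config) {
  d <- if (is(stack, "ImageStack")) dim(stack@values) else dim(stack)
  if (!identical(as.integer(d), config@inputShape))
    lmnError(sprintf("stack is %s but the model expects %s",
                     paste(d, collapse = "x"),
                     paste(config@inputShape, collapse = "x")),
             "landmarknetValidationError")
  invisible(TRUE)
}

targetTensors <- function(heatmaps, config) {
  lapply(heatmaps, function(h) {
    v <- if (is(h, "HeatmapVolume")) h@values else h
    stackToTensor(v)
  })
}

#' Train the network
#'
#' Minimises the mean over heads of the per-voxel mean squared error
#' between predicted and target heatmaps with Adam, shuffling the sample
#' order every epoch.  All randomness (shuffling) is driven by the seed in
#' \code{config}, so repeated runs on the same data give identical loss
#' histories.
#'
#' @param model a \linkS4class{LandmarkNet}.
#' @param stacks list of preprocessed \linkS4class{ImageStack} objects
#'   matching the model's input shape.
#' @param targets list (one element per stack) of lists of 7
#'   \linkS4class{HeatmapVolume} targets at the head output shape.
#' @param config a \linkS4class{TrainConfig}.
#' @param verbose print the per-epoch loss.
#' @return The trained \linkS4class{LandmarkNet} with the per-epoch loss in
#'   \code{@history}.
#' @export
trainModel <- function(model, stacks, targets, config = trainConfig(),
                       verbose = FALSE) {
  stopifnot(is(model, "LandmarkNet"), is(config, "TrainConfig"))
  n <- length(stacks)
  if (n == 0L || length(targets) != n)
    lmnError("stacks and targets must be non-empty and aligned",
             "landmarknetValidationError")
  outShape <- headOutputShape(model@config)
  for (i in seq_len(n)) {
    checkCanonical(stacks[[i]], model@config)
    if (length(targets[[i]]) != model@config@nHeads)
      lmnError("one target heatmap per head is required",
               "landmarknetValidationError")
    for (h in targets[[i]]) {
      hv <- if (is(h, "HeatmapVolume")) h@values else h
      if (!identical(as.integer(dim(hv)), outShape))
        lmnError(sprintf("target heatmap is %s but heads emit %s",
                         paste(dim(hv), collapse = "x"),
                         paste(outShape, collapse = "x")),
                 "landmarknetValidationError")
    }
  }
  if (config@epochs == 0L) return(model)
  epochLr <- rep(config@learningRate, length.out = config@epochs)

  xs <- lapply(stacks, function(s) stackToTensor(s@values))
  ts <- lapply(targets, targetTensors, config = model@config)
  graph <- asGraph(model)
  np <- length(graph$params)
  adamM <- lapply(graph$params, function(p)
    list(W = array(0, dim(p$W)), b = numeric(length(p$b))))
  adamV <- adamM
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  history <- numeric(config@epochs)

  set.seed(config@seed)
  for (epoch in seq_len(config@epochs)) {
    lr <- epochLr[epoch]
    ord <- sample.int(n)
    epochLoss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = config@batchSize)) {
      batch <- ord[start:min(start + config@batchSize - 1L, n)]
      gW <- vector("list", np)
      gb <- vector("list", np)
      batchLoss <- 0
      for (i in batch) {
        fw <- graphForward(graph, xs[[i]], keepActs = TRUE)
        lg <- headLoss(fw$outputs, ts[[i]])
        batchLoss <- batchLoss + lg$loss / length(batch)
        bw <- graphBackward(graph, fw, lg$grads)
        for (p in seq_len(np)) {
          w <- bw$gW[[p]]
          if (is.null(w)) next
          gW[[p]] <- if (is.null(gW[[p]])) w / length(batch) else
            gW[[p]] + w / length(batch)
          gb[[p]] <- if (is.null(gb[[p]])) bw$gb[[p]] / length(batch) else
            gb[[p]] + bw$gb[[p]] / length(batch)
        }
      }
      step <- step + 1L
      corr <- sqrt(1 - b2^step) / (1 - b1^step)
      for (p in seq_len(np)) {
        if (is.null(gW[[p]])) next
        adamM[[p]]$W <- b1 * adamM[[p]]$W + (1 - b1) * gW[[p]]
        adamV[[p]]$W <- b2 * adamV[[p]]$W + (1 - b2) * gW[[p]]^2
        adamM[[p]]$b <- b1 * adamM[[p]]$b + (1 - b1) * gb[[p]]
        adamV[[p]]$b <- b2 * adamV[[p]]$b + (1 - b2) * gb[[p]]^2
        graph$params[[p]]$W <- graph$params[[p]]$W -
          lr * corr * adamM[[p]]$W / (sqrt(adamV[[p]]$W) + eps)
        graph$params[[p]]$b <- graph$params[[p]]$b -
          lr * corr * adamM[[p]]$b / (sqrt(adamV[[p]]$b) + eps)
      }
      epochLoss <- epochLoss + batchLoss
      nb <- nb + 1L
    }
    history[epoch] <- epochLoss / nb
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.5g", epoch, config@epochs,
                      history[epoch]))
  }
  model@params <- graph$params
  model@history <- c(model@history, history)
  model
}

#' Shape of each head's output volume
#'
#' @param config a \linkS4class{ModelConfig}.
#' @return integer(3): (slices, rows, cols) of every predicted heatmap.
#' @export
headOutputShape <- function(config) {
  as.integer(c(config@inputShape[1],
               config@inputShape[2:3] %/% config@finalPool))
}

#' Predict the 7 landmark heatmaps for one stack
#'
#' @param model a \linkS4class{LandmarkNet}.
#' @param stack a preprocessed \linkS4class{ImageStack} matching the
#'   model's input shape.
#' @return A list of \linkS4class{HeatmapVolume} objects, one per landmark
#'   in order 1..7, on the coarse head-output grid (geometry derived from
#'   the stack's by the in-plane pooling factor).
#' @export
predictHeatmaps <- function(model, stack) {
  stopifnot(is(model, "LandmarkNet"), is(stack, "ImageStack"))
  checkCanonical(stack, model@config)
  fw <- graphForward(asGraph(model), stackToTensor(stack@values),
                     keepActs = FALSE)
  geom <- coarseGeometry(stack@geometry, model@config@finalPool)
  lapply(seq_along(fw$outputs), function(h) {
    v <- tensorToVolume(fw$outputs[[h]])
    heatmapVolume(pmax(v, 0), h, geom)
  })
}

#' Save / load a model
#'
#' Serialises the full network (graph, weights, config, loss history) with
#' R's native serialisation.
#'
#' @param model a \linkS4class{LandmarkNet}.
#' @param path file path.
#' @return \code{saveModel} returns \code{path} invisibly;
#'   \code{loadModel} returns the \linkS4class{LandmarkNet}.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  m <- readRDS(path)
  if (!is(m, "LandmarkNet"))
    lmnError("file does not contain a LandmarkNet", "landmarknetFormatError")
  m
}
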