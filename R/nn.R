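# Static computation graph for the multi-head heatmap-regression network.
#
# A model is a list of layer descriptors evaluated in order; every layer
# names the node(s) it consumes, so the U-net skip connexions and the
# per-head decoder branches are plain graph edges.  Tensors use the C++
# kernel layout (C, X, Y, Z) with X = column, Y = row, Z = slice; the
# conversion from an ImageStack's (slice, row, col) array happens at the
# model boundary.

newLayer <- function(op, input, name, pidx = NA_integer_, stride = 1L,
                     relu = TRUE, poolFactor = NA_integer_, c1 = NA_integer_) {
  list(op = op, input = input, name = name, pidx = pidx, stride = stride,
       relu = relu, poolFactor = poolFactor, c1 = c1)
}

heConvParams <- function(cin, cout, scale = 1) {
  k <- cin * 27L
  list(W = matrix(stats::rnorm(cout * k, sd = scale * sqrt(2 / k)), cout, k),
       b = numeric(cout))
}

stackToTensor <- function(values) {
  x <- aperm(values, c(3, 2, 1))          # (col, row, slice) = (X, Y, Z)
  dim(x) <- c(1L, dim(x))
  x
}

tensorToVolume <- function(x) {
  d <- dim(x)                              # (1, X, Y, Z)
  dim(x) <- d[2:4]
  aperm(x, c(3, 2, 1))                     # (slice, row, col)
}

# Build the layer graph for a given ModelConfig; params are He-initialised
# using the current RNG state.
buildGraph <- function(f0, maxDepth, headSplitDepth, nHeads, finalPool,
                       filterIncrement = 4L) {
  layers <- list()
  params <- list()
  addParam <- function(cin, cout, scale = 1) {
    params[[length(params) + 1L]] <<- heConvParams(cin, cout, scale)
    length(params)
  }
  addLayer <- function(...) {
    layers[[length(layers) + 1L]] <<- newLayer(...)
    length(layers)
  }
  filters <- function(d) f0 + filterIncrement * d

  inputNode <- addLayer("input", NA_integer_, "input")
  # encoder: first conv at full resolution, then maxDepth downsampling
  # steps (stride 1x2x2) with a non-strided conv between consecutive steps
  node <- addLayer("conv", inputNode, "enc0",
                   pidx = addParam(1L, f0), stride = 1L)
  skip <- integer(maxDepth)                # skip source per level 0..D-1
  skip[1] <- node
  for (d in seq_len(maxDepth)) {
    node <- addLayer("conv", node, sprintf("down%d", d),
                     pidx = addParam(filters(d - 1L), filters(d)),
                     stride = 2L)
    if (d < maxDepth) {
      node <- addLayer("conv", node, sprintf("enc%d", d),
                       pidx = addParam(filters(d), filters(d)), stride = 1L)
      skip[d + 1L] <- node
    }
  }

  # one decoder level: upsample (zero-stuff + conv), concatenate the
  # same-size encoder feature map, then a non-strided conv
  decoderLevel <- function(node, d, tag) {
    fin <- filters(d)
    fout <- filters(d - 1L)
    up <- addLayer("upconv", node, sprintf("up%d%s", d, tag),
                   pidx = addParam(fin, fout))
    cc <- addLayer("concat", c(skip[d], up), sprintf("cat%d%s", d, tag),
                   c1 = fout)
    addLayer("conv", cc, sprintf("dec%d%s", d, tag),
             pidx = addParam(2L * fout, fout), stride = 1L)
  }

  node <- length(layers)                   # bottleneck
  for (d in seq(maxDepth, headSplitDepth + 1L))
    node <- decoderLevel(node, d, "")

  outputNodes <- integer(nHeads)
  for (h in seq_len(nHeads)) {
    hn <- node
    for (d in seq(headSplitDepth, 1L))
      hn <- decoderLevel(hn, d, sprintf("h%d", h))
    pool <- addLayer("pool", hn, sprintf("pool_h%d", h),
                     poolFactor = finalPool)
    outputNodes[h] <- addLayer("conv", pool, sprintf("out_h%d", h),
                               pidx = addParam(f0, 1L), stride = 1L,
                               relu = FALSE)
  }
  list(layers = layers, params = params, outputNodes = outputNodes)
}

graphForward <- function(graph, x, keepActs = TRUE) {
  layers <- graph$layers
  n <- length(layers)
  acts <- vector("list", n)
  poolIdx <- vector("list", n)
  # last layer reading each node, so prediction mode can free activations
  lastUse <- integer(n)
  for (i in seq_len(n)) {
    ins <- layers[[i]]$input
    lastUse[ins[!is.na(ins)]] <- i
  }
  for (i in seq_len(n)) {
    ly <- layers[[i]]
    acts[[i]] <- switch(ly$op,
      input = x,
      conv = {
        a <- acts[[ly$input]]
        cpp_conv3d_fwd(a, dim(a), graph$params[[ly$pidx]]$W,
                       graph$params[[ly$pidx]]$b, ly$stride, ly$relu)
      },
      upconv = {
        a <- acts[[ly$input]]
        z <- cpp_zerostuff(a, dim(a))
        cpp_conv3d_fwd(z, dim(z), graph$params[[ly$pidx]]$W,
                       graph$params[[ly$pidx]]$b, 1L, ly$relu)
      },
      concat = {
        a <- acts[[ly$input[1]]]
        b <- acts[[ly$input[2]]]
        cpp_concat(a, dim(a), b, dim(b))
      },
      pool = {
        a <- acts[[ly$input]]
        r <- cpp_maxpool_fwd(a, dim(a), ly$poolFactor)
        poolIdx[[i]] <- r$idx
        r$y
      })
    if (!keepActs) {
      for (j in ly$input[!is.na(ly$input)])
        if (lastUse[j] <= i && !(j %in% graph$outputNodes))
          acts[j] <- list(NULL)
    }
  }
  list(acts = acts, poolIdx = poolIdx,
       outputs = acts[graph$outputNodes])
}

# Backward pass: douts is a list of gradients, one per head output node,
# in the same (1, ox, oy, z) layout as the outputs.
graphBackward <- function(graph, fw, douts) {
  layers <- graph$layers
  n <- length(layers)
  acts <- fw$acts
  dacc <- vector("list", n)
  gW <- vector("list", length(graph$params))
  gb <- vector("list", length(graph$params))
  addTo <- function(lst, i, v) {
    if (is.null(lst[[i]])) lst[[i]] <- v else lst[[i]] <- lst[[i]] + v
    lst
  }
  for (h in seq_along(graph$outputNodes))
    dacc <- addTo(dacc, graph$outputNodes[h], douts[[h]])
  for (i in rev(seq_len(n))) {
    dy <- dacc[[i]]
    if (is.null(dy)) next
    ly <- layers[[i]]
    if (ly$op %in% c("conv", "upconv") && ly$relu)
      dy <- dy * (acts[[i]] > 0)
    switch(ly$op,
      conv = {
        a <- acts[[ly$input]]
        needDx <- layers[[ly$input]]$op != "input"
        bw <- cpp_conv3d_bwd(a, dim(a), graph$params[[ly$pidx]]$W, dy,
                             ly$stride, needDx)
        gW <- addTo(gW, ly$pidx, bw$dW)
        gb <- addTo(gb, ly$pidx, bw$db)
        if (needDx) dacc <- addTo(dacc, ly$input, bw$dx)
      },
      upconv = {
        a <- acts[[ly$input]]
        z <- cpp_zerostuff(a, dim(a))
        bw <- cpp_conv3d_bwd(z, dim(z), graph$params[[ly$pidx]]$W, dy, 1L,
                             TRUE)
        gW <- addTo(gW, ly$pidx, bw$dW)
        gb <- addTo(gb, ly$pidx, bw$db)
        dacc <- addTo(dacc, ly$input, cpp_unstuff(bw$dx, dim(z)))
      },
      concat = {
        parts <- cpp_split(dy, dim(dy), dim(acts[[ly$input[1]]])[1])
        dacc <- addTo(dacc, ly$input[1], parts$a)
        dacc <- addTo(dacc, ly$input[2], parts$b)
      },
      pool = {
        a <- acts[[ly$input]]
        dacc <- addTo(dacc, ly$input,
                      cpp_maxpool_bwd(dy, fw$poolIdx[[i]], dim(a)))
      },
      input = NULL)
    dacc[i] <- list(NULL)                  # release memory as we go
  }
  list(gW = gW, gb = gb)
}

# Mean over heads of the per-head voxel MSE, and its gradient per head.
headLoss <- function(outputs, targets) {
  nh <- length(outputs)
  loss <- 0
  grads <- vector("list", nh)
  for (h in seq_len(nh)) {
    d <- outputs[[h]] - targets[[h]]
    loss <- loss + mean(d * d) / nh
    grads[[h]] <- (2 / (length(d) * nh)) * d
  }
  list(loss = loss, grads = grads)
}
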