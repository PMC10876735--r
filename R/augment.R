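#' Image-level augmentation configuration
#'
#' Random in-plane shift/rotation/scaling applied identically to every
#' slice and to the annotation's in-plane coordinates, plus Gaussian blur
#' and a mild radial (optical) distortion applied to the intensities only.
#' Limits follow the usual image-augmentation conventions: shift as a
#' fraction of the image size, rotation in degrees, scale as a fractional
#' change, blur as a kernel radius in pixels.  Disabled by default: the
#' final detection model is trained without augmentation.
#'
#' @slot shiftLimit fraction of the in-plane size, default 0.02.
#' @slot rotateLimit degrees, default 4.
#' @slot scaleLimit fractional scale change, default 0.15.
#' @slot blurLimit maximum blur kernel radius in pixels, default 4.
#' @slot distortLimit radial distortion strength, default 3.
#' @slot prob probability of applying the transform, default 1.
#' @slot enabled logical, default FALSE.
#' @export
setClass("AugmentationConfig",
  representation(shiftLimit = "numeric", rotateLimit = "numeric",
                 scaleLimit = "numeric", blurLimit = "numeric",
                 distortLimit = "numeric", prob = "numeric",
                 enabled = "logical"),
  validity = function(object) {
    if (object@prob < 0 || object@prob > 1)
      return("prob must lie in [0, 1]")
    if (any(c(object@shiftLimit, object@rotateLimit, object@scaleLimit,
              object@blurLimit, object@distortLimit) < 0))
      return("limits must be non-negative")
    TRUE
  })

#' @rdname AugmentationConfig-class
#' @param shiftLimit,rotateLimit,scaleLimit,blurLimit,distortLimit,prob,enabled
#'   see the class slots.
#' @return An \linkS4class{AugmentationConfig}.
#' @export
augmentationConfig <- function(shiftLimit = 0.02, rotateLimit = 4,
                               scaleLimit = 0.15, blurLimit = 4,
                               distortLimit = 3, prob = 1,
                               enabled = FALSE) {
  tryCatch(
    new("AugmentationConfig", shiftLimit = shiftLimit,
        rotateLimit = rotateLimit, scaleLimit = scaleLimit,
        blurLimit = blurLimit, distortLimit = distortLimit, prob = prob,
        enabled = enabled),
    error = function(e) lmnError(conditionMessage(e),
                                 "landmarknetConfigError"))
}

# Bilinear sample of a 2D matrix at (possibly fractional) 0-based
# coordinates; outside the image the value is 0.
bilinearSample <- function(m, rows, cols) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  pick <- function(r, c) {
    ok <- r >= 0 & r <= nr - 1 & c >= 0 & c <= nc - 1
    v <- numeric(length(r))
    v[ok] <- m[cbind(r[ok] + 1L, c[ok] + 1L)]
    v
  }
  (1 - fr) * (1 - fc) * pick(r0, c0) + (1 - fr) * fc * pick(r0, c0 + 1) +
    fr * (1 - fc) * pick(r0 + 1, c0) + fr * fc * pick(r0 + 1, c0 + 1)
}

# Separable in-plane Gaussian blur.
blurSlices <- function(v, sigma) {
  if (sigma <= 0) return(v)
  half <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-half):half)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  smooth1 <- function(m) {
    # convolve each column with replication padding
    n <- nrow(m)
    idx <- pmin(pmax(outer(seq_len(n), (-half):half, "+"), 1L), n)
    out <- 0
    for (j in seq_along(kern)) out <- out + kern[j] * m[idx[, j], ,
                                                        drop = FALSE]
    out
  }
  for (z in seq_len(dim(v)[1]))
    v[z, , ] <- t(smooth1(t(smooth1(v[z, , ]))))
  v
}

#' Augment a stack / annotation pair
#'
#' Draws one random in-plane similarity transform (shift, rotation about
#' the image centre, isotropic scale) from the configured limits and
#' applies it to every slice and to the annotation's in-plane landmark
#' coordinates; then blurs and radially distorts the intensities only.
#' With all limits zero the pair is returned unchanged.  Randomness is
#' taken from the current RNG state; seed before calling for
#' reproducibility.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param ann the matching \linkS4class{AnnotationSet}.
#' @param config an \linkS4class{AugmentationConfig} with
#'   \code{enabled = TRUE}.
#' @return A list \code{(stack, annotation, valid)}; \code{valid} is FALSE
#'   (and the pair should be skipped) when a transformed landmark leaves
#'   the field of view.
#' @export
augmentPair <- function(stack, ann, config = augmentationConfig(enabled = TRUE)) {
  stopifnot(is(stack, "ImageStack"), is(ann, "AnnotationSet"))
  if (!config@enabled)
    lmnError("augmentation is disabled in this configuration",
             "landmarknetConfigError")
  if (stats::runif(1) > config@prob)
    return(list(stack = stack, annotation = ann, valid = TRUE))
  d <- dim(stack@values)
  ctr <- (d[2:3] - 1) / 2
  shift <- stats::runif(2, -config@shiftLimit, config@shiftLimit) * d[2:3]
  theta <- stats::runif(1, -config@rotateLimit, config@rotateLimit) * pi / 180
  scl <- 1 + stats::runif(1, -config@scaleLimit, config@scaleLimit)
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)

  # forward map (row, col): p' = ctr + scl * R (p - ctr) + shift
  lm <- ann@landmarks
  rc <- t(ctr + scl * R %*% (t(lm[, 2:3]) - ctr) + shift)
  newLm <- cbind(lm[, 1], rc)
  if (any(newLm[, 2] < 0) || any(newLm[, 2] > d[2] - 1) ||
      any(newLm[, 3] < 0) || any(newLm[, 3] > d[3] - 1))
    return(list(stack = stack, annotation = ann, valid = FALSE))

  # inverse map for image resampling
  grid <- expand.grid(row = seq_len(d[2]) - 1, col = seq_len(d[3]) - 1)
  q <- rbind(grid$row, grid$col) - ctr - shift
  p <- (t(R) %*% q) / scl + ctr
  v <- stack@values
  warped <- array(0, d)
  for (z in seq_len(d[1]))
    warped[z, , ] <- matrix(bilinearSample(v[z, , ], p[1, ], p[2, ]),
                            d[2], d[3])

  if (config@blurLimit > 0) {
    sigma <- stats::runif(1, 0, config@blurLimit / 3)
    warped <- blurSlices(warped, sigma)
  }
  if (config@distortLimit > 0) {
    # barrel/pincushion distortion of the intensities about the centre
    kd <- stats::runif(1, -config@distortLimit, config@distortLimit) * 0.01
    rn2 <- ((grid$row - ctr[1]) / d[2])^2 + ((grid$col - ctr[2]) / d[3])^2
    f <- 1 + kd * rn2
    pr <- ctr[1] + (grid$row - ctr[1]) * f
    pc <- ctr[2] + (grid$col - ctr[2]) * f
    for (z in seq_len(d[1]))
      warped[z, , ] <- matrix(bilinearSample(warped[z, , ], pr, pc),
                              d[2], d[3])
  }
  newAnn <- annotationSet(newLm, ann@label, ann@observerId, ann@subjectId)
  list(stack = imageStack(warped, stack@geometry, stack@subjectId),
       annotation = newAnn, valid = TRUE)
}
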