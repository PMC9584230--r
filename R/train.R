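#' Training configuration
#'
#' Mirrors the full-scale recipe (Adam, per-pixel cross-entropy, batch size 6,
#' flip/rotation/contrast augmentation); `steps` and the learning rate are
#' configurable for desk-scale runs. The learning rate was not part of the
#' published recipe; the default is 1e-4.
#'
#' @param scheme A [BatchScheme-class].
#' @param steps Gradient steps.
#' @param lr Adam learning rate.
#' @param seed Integer seed covering initialization, sampling and augmentation.
#' @param augment An [AugmentConfig-class].
#' @param optimizer,loss Names; only `"adam"` and `"bce"` are implemented.
#' @return A [TrainConfig-class].
#' @export
trainConfig <- function(scheme, steps = 60000, lr = 1e-4, seed = 1,
                        augment = augmentConfig(), optimizer = "adam",
                        loss = "bce") {
  new("TrainConfig", optimizer = optimizer, lr = lr, loss = loss,
      steps = as.integer(steps), scheme = scheme, seed = as.integer(seed),
      augment = augment)
}

#' Render boxes as a filled binary mask
#'
#' The reference masks used for training are the label boxes filled in, under
#' half-open box semantics (`[x, x + w) x [y, y + h)`).
#'
#' @param boxes A [boxFrame()] table.
#' @param height,width Mask dimensions in pixels.
#' @return Binary matrix.
#' @export
boxesToMask <- function(boxes, height, width) {
  m <- matrix(0L, height, width)
  if (nrow(boxes) == 0) return(m)
  for (i in seq_len(nrow(boxes))) {
    r0 <- max(1, floor(boxes$y[i]) + 1)
    r1 <- min(height, ceiling(boxes$y[i] + boxes$h[i]))
    c0 <- max(1, floor(boxes$x[i]) + 1)
    c1 <- min(width, ceiling(boxes$x[i] + boxes$w[i]))
    if (r1 >= r0 && c1 >= c0) m[r0:r1, c0:c1] <- 1L
  }
  m
}

# (raster, mask) pair for one training case, resized to side s.
# PhantomCase uses its pixel-true mask; a plain CaseRecord renders its boxes.
.trainPair <- function(case, s, rasterFor = NULL) {
  if (is(case, "PhantomCase")) {
    px <- case@raster@pixels  # phantoms are generated on the unit scale
    mk <- case@mask
  } else {
    if (is.null(rasterFor))
      stop("plain CaseRecords need a rasterFor(id) accessor", call. = FALSE)
    px <- normalizeRaster(rasterFor(caseId(case)))@pixels
    mk <- boxesToMask(caseBoxes(case), nrow(px), ncol(px))
  }
  list(x = resizeMatrix(px, s, s, "bilinear"),
       y = resizeMatrix(mk, s, s, "none"))
}

# mean binary cross-entropy and its gradient w.r.t. the logits
.bceLoss <- function(prob, y) {
  eps <- 1e-7
  pc <- pmin(pmax(prob, eps), 1 - eps)
  loss <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  grad <- (prob - y) / length(y)
  list(loss = loss, grad = grad)
}

.adamInit <- function(params)
  list(m = lapply(params, function(p) p * 0), v = lapply(params, function(p) p * 0), t = 0)

.adamStep <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  b1t <- 1 - beta1^st$t
  b2t <- 1 - beta2^st$t
  for (nm in names(params)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] - lr * (st$m[[nm]] / b1t) /
      (sqrt(st$v[[nm]] / b2t) + eps)
  }
  list(params = params, state = st)
}

#' Train a UNet under a batch scheme
#'
#' Runs `cfg@steps` gradient steps. Each step draws one minibatch under the
#' scheme (see [drawBatch()]), augments every member ([augmentPair()]),
#' computes mean per-pixel binary cross-entropy against the reference masks
#' (all-background masks for negative cases) and applies one Adam update.
#' The returned model is the final-step model with the full loss trace
#' attached. Fully reproducible from `cfg@seed`.
#'
#' @param split A [DatasetSplit-class] whose train cases are
#'   [PhantomCase-class] objects (or [CaseRecord-class] plus `rasterFor`).
#' @param cfg A [TrainConfig-class].
#' @param net A [NetConfig-class].
#' @param rasterFor Optional function `id -> ImageRaster` for plain records.
#' @param lossFn Optional loss seam: `function(prob, y)` returning
#'   `list(loss, grad)` with `grad = dL/dlogits * dsigmoid` folded in (the
#'   default is binary cross-entropy, whose logit gradient is `prob - y`
#'   scaled by the pixel count).
#' @param trial Optional trial index recorded in the provenance.
#' @return A trained [UNetModel-class].
#' @export
trainModel <- function(split, cfg, net, rasterFor = NULL, lossFn = NULL,
                       trial = NA_integer_) {
  scheme <- cfg@scheme
  train <- trainCases(split)
  tg <- vapply(train, caseTarget, 0L)
  posPool <- train[tg == 1L]
  negPool <- train[tg == 0L]
  needsPos <- scheme@name == "RAND" || scheme@nPos > 0
  needsNeg <- scheme@name == "RAND" || scheme@nPos < scheme@batchSize
  if (needsPos && length(posPool) == 0 && scheme@name != "RAND")
    stop("training set has no positive cases", call. = FALSE)
  if (needsNeg && length(negPool) == 0 && scheme@name != "RAND")
    stop("training set has no negative cases", call. = FALSE)
  if (is.null(lossFn)) lossFn <- .bceLoss

  s <- net@inSize
  B <- scheme@batchSize
  posPairs <- lapply(posPool, .trainPair, s = s, rasterFor = rasterFor)
  negPairs <- lapply(negPool, .trainPair, s = s, rasterFor = rasterFor)

  withSeed(cfg@seed, {
    model <- buildUnet(net)
    adam <- .adamInit(model@params)
    trace <- numeric(cfg@steps)
    for (step in seq_len(cfg@steps)) {
      idx <- drawBatchIndices(scheme, length(posPairs), length(negPairs))
      x <- array(0, c(s, s, B))
      y <- array(0, c(s, s, B))
      for (i in seq_len(B)) {
        pr <- if (idx$pool[i] == 1L) posPairs[[idx$index[i]]] else negPairs[[idx$index[i]]]
        ag <- augmentPair(pr$x, pr$y, cfg@augment)
        x[, , i] <- ag$image
        y[, , i] <- ag$mask
      }
      fw <- unetForward(model, x, B, keepCache = TRUE)
      ls <- lossFn(fw$prob, y)
      if (!is.finite(ls$loss))
        stop(sprintf("non-finite loss at step %d", step), call. = FALSE)
      trace[step] <- ls$loss
      if (cfg@lr > 0) {
        grads <- unetBackward(model, fw$cache, ls$grad, B)
        upd <- .adamStep(model@params, grads, adam, cfg@lr)
        model@params <- upd$params
        adam <- upd$state
      }
    }
    new("UNetModel", params = model@params, netConfig = net,
        provenance = list(scheme = scheme@name, steps = cfg@steps,
                          lr = cfg@lr, seed = cfg@seed, trial = trial),
        lossTrace = trace)
  })
}

#' @describeIn predictMask Resizes the image to the network input size
#'   (bilinear), runs a forward pass, returns the probability map upscaled
#'   back to the original resolution and the thresholded binary mask.
#' @export
setMethod("predictMask", "UNetModel", function(model, image, threshold = 0.5, ...) {
  px <- rasterPixels(image)
  s <- model@netConfig@inSize
  xr <- resizeMatrix(px, s, s, "bilinear")
  fw <- unetForward(model, array(xr, c(s, s, 1)), 1, keepCache = FALSE)
  prob <- resizeMatrix(matrix(fw$prob[, , 1], s, s), nrow(px), ncol(px), "bilinear")
  prob <- pmin(pmax(prob, 0), 1)
  list(mask = (prob >= threshold) + 0L, prob = prob)
})

#' @describeIn predictMask Fixed-intensity oracle: the "probability" map is the
#'   raw intensity and the mask is `intensity >= model@threshold` (the
#'   `threshold` argument is ignored).
#' @export
setMethod("predictMask", "ThresholdSegmenter", function(model, image, threshold = 0.5, ...) {
  px <- rasterPixels(image)
  prob <- pmin(pmax(px, 0), 1)
  list(mask = (px >= model@threshold) + 0L, prob = prob)
})
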