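#' @import methods
NULL

KLASS_LEVELS <- c("lung_opacity", "normal", "no_opacity_not_normal")

#' Construct a bounding-box table
#'
#' Boxes use 0-based, top-left-origin pixel coordinates; a box occupies the
#' half-open region `[x, x + w) x [y, y + h)`, so its area is exactly `w * h`.
#'
#' @param x,y Top-left corner (0-based pixels).
#' @param w,h Width and height in pixels; must be positive.
#' @return A `data.frame` with columns `x`, `y`, `w`, `h`.
#' @examples
#' boxFrame(x = 3, y = 5, w = 4, h = 2)
#' @export
boxFrame <- function(x = numeric(), y = numeric(), w = numeric(), h = numeric()) {
  df <- data.frame(x = as.numeric(x), y = as.numeric(y),
                   w = as.numeric(w), h = as.numeric(h))
  validateBoxes(df)
  df
}

validateBoxes <- function(boxes, width = NULL, height = NULL) {
  stopifnot(is.data.frame(boxes))
  if (!all(c("x", "y", "w", "h") %in% names(boxes)))
    stop("boxes must have columns x, y, w, h", call. = FALSE)
  if (nrow(boxes) == 0) return(invisible(boxes))
  if (any(!is.finite(as.matrix(boxes[, c("x", "y", "w", "h")]))))
    stop("box coordinates must be finite", call. = FALSE)
  if (any(boxes$w <= 0) || any(boxes$h <= 0))
    stop("box width and height must be positive", call. = FALSE)
  if (any(boxes$x < 0) || any(boxes$y < 0))
    stop("box corners must be non-negative", call. = FALSE)
  if (!is.null(width) && any(boxes$x + boxes$w > width))
    stop("box exceeds image width", call. = FALSE)
  if (!is.null(height) && any(boxes$y + boxes$h > height))
    stop("box exceeds image height", call. = FALSE)
  invisible(boxes)
}

#' ImageRaster: a single grayscale image
#'
#' A 2-D grayscale intensity grid with a case identifier. Pixels are stored as
#' a numeric matrix indexed `[row = y + 1, col = x + 1]` with the origin at the
#' top-left.
#'
#' @slot pixels Numeric matrix of intensities (all finite).
#' @slot id Case identifier.
#' @export
setClass("ImageRaster", representation(pixels = "matrix", id = "character"),
         validity = function(object) {
  if (nrow(object@pixels) < 1 || ncol(object@pixels) < 1)
    return("pixels must be at least 1x1")
  if (!all(is.finite(object@pixels)))
    return("all intensities must be finite")
  if (length(object@id) != 1) return("id must be a single string")
  TRUE
})

#' @param pixels Numeric matrix.
#' @param id Case identifier string.
#' @rdname ImageRaster-class
#' @export
imageRaster <- function(pixels, id = "case") {
  new("ImageRaster", pixels = as.matrix(pixels), id = as.character(id))
}

#' CaseRecord: one radiograph's identity, class and reference boxes
#'
#' @slot id Case identifier.
#' @slot klass One of `"lung_opacity"`, `"normal"`, `"no_opacity_not_normal"`.
#' @slot target Binary target: 1 iff `klass == "lung_opacity"`.
#' @slot boxes Reference opacity boxes ([boxFrame()]); empty iff `target == 0`.
#' @export
setClass("CaseRecord",
         representation(id = "character", klass = "character",
                        target = "integer", boxes = "data.frame"),
         validity = function(object) {
  if (!object@klass %in% KLASS_LEVELS)
    return(sprintf("klass must be one of: %s", paste(KLASS_LEVELS, collapse = ", ")))
  if (!object@target %in% c(0L, 1L)) return("target must be 0 or 1")
  if ((object@target == 1L) != (object@klass == "lung_opacity"))
    return("target must be 1 exactly when klass is lung_opacity")
  if ((object@target == 1L) != (nrow(object@boxes) > 0))
    return("target = 1 exactly when boxes are present")
  tryCatch({ validateBoxes(object@boxes); TRUE }, error = function(e) conditionMessage(e))
})

#' @param id,klass,boxes See slots.
#' @rdname CaseRecord-class
#' @export
caseRecord <- function(id, klass, boxes = boxFrame()) {
  new("CaseRecord", id = as.character(id), klass = klass,
      target = as.integer(klass == "lung_opacity"), boxes = boxes)
}

#' DatasetSplit: disjoint train/test case lists
#'
#' @slot train,test Lists of [CaseRecord-class] objects with disjoint ids;
#'   the test list is class-balanced (equal positive and negative counts).
#' @export
setClass("DatasetSplit", representation(train = "list", test = "list"),
         validity = function(object) {
  getId <- function(r) if (is(r, "PhantomCase")) r@record@id else r@id
  getTg <- function(r) if (is(r, "PhantomCase")) r@record@target else r@target
  ids <- c(vapply(object@train, getId, ""), vapply(object@test, getId, ""))
  if (anyDuplicated(ids)) return("train and test ids must be disjoint")
  tt <- vapply(object@test, getTg, 0L)
  if (length(tt) && sum(tt == 1L) != sum(tt == 0L))
    return("test set must be class-balanced")
  TRUE
})

#' BatchScheme: a named positive:negative batch composition
#'
#' P-schemes fix the number of positive cases per minibatch (`nPos`); `RAND`
#' draws the whole batch uniformly from the pooled training set.
#'
#' @slot name Scheme name (`"P100"`, `"P83"`, ..., `"P17"`, or `"RAND"`).
#' @slot batchSize Cases per minibatch.
#' @slot nPos Positives per batch (`NA` for RAND).
#' @export
setClass("BatchScheme",
         representation(name = "character", batchSize = "integer", nPos = "integer"),
         validity = function(object) {
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@name == "RAND") {
    if (!is.na(object@nPos)) return("RAND has no fixed nPos")
  } else {
    if (is.na(object@nPos)) return("P-schemes need nPos")
    if (object@nPos < 1L || object@nPos > object@batchSize)
      return("nPos must lie in [1, batchSize]")
    canonical <- object@name %in% names(.P_SCHEME_PCT) &&
      schemeComposition(object@name, object@batchSize)[["nPos"]] == object@nPos
    derived <- object@name ==
      paste0("P", roundHalfAway(100 * object@nPos / object@batchSize))
    if (!canonical && !derived)
      return(sprintf("name %s does not match composition nPos = %d",
                     object@name, object@nPos))
  }
  TRUE
})

#' Batch: one drawn minibatch
#'
#' @slot cases List of [CaseRecord-class]; for P-schemes exactly `nPos` members
#'   have `target == 1`.
#' @slot scheme The [BatchScheme-class] that produced it.
#' @export
setClass("Batch", representation(cases = "list", scheme = "BatchScheme"),
         validity = function(object) {
  if (length(object@cases) != object@scheme@batchSize)
    return("batch length must equal scheme batchSize")
  if (object@scheme@name != "RAND") {
    np <- sum(vapply(object@cases, function(r) r@target, 0L))
    if (np != object@scheme@nPos)
      return("positive count must equal scheme nPos")
  }
  TRUE
})

#' PhantomConfig: parameters of the synthetic chest-phantom population
#'
#' @slot imageSize Pixels per side (>= 32).
#' @slot nCases Number of cases to generate.
#' @slot prevalence Fraction of lung-opacity cases, in (0, 1).
#' @slot fracNotNormal Fraction of negatives that are
#'   no-opacity-not-normal (carry a non-opacity distractor), in `[0, 1]`.
#' @slot blobCountRange Min/max opacity blobs per positive case.
#' @slot blobContrast Additive intensity of opacity blobs (> 0).
#' @slot noiseSd Gaussian pixel-noise standard deviation.
#' @slot seed Integer seed; the dataset is fully reproducible from it.
#' @export
setClass("PhantomConfig",
         representation(imageSize = "integer", nCases = "integer",
                        prevalence = "numeric", fracNotNormal = "numeric",
                        blobCountRange = "integer", blobContrast = "numeric",
                        noiseSd = "numeric", seed = "integer"),
         validity = function(object) {
  if (object@imageSize < 32L) return("imageSize must be >= 32")
  if (object@nCases < 1L) return("nCases must be >= 1")
  if (object@prevalence <= 0 || object@prevalence >= 1)
    return("prevalence must lie in (0, 1)")
  if (object@fracNotNormal < 0 || object@fracNotNormal > 1)
    return("fracNotNormal must lie in [0, 1]")
  if (length(object@blobCountRange) != 2L ||
      object@blobCountRange[1] < 1L ||
      object@blobCountRange[2] < object@blobCountRange[1])
    return("blobCountRange must be c(min, max) with 1 <= min <= max")
  if (object@blobContrast <= 0) return("blobContrast must be positive")
  if (object@noiseSd < 0) return("noiseSd must be non-negative")
  TRUE
})

#' PhantomCase: a synthetic case with ground truth
#'
#' @slot record The [CaseRecord-class] (boxes are the tight bounding boxes of
#'   the mask components).
#' @slot raster The [ImageRaster-class] in `[0, 1]`.
#' @slot mask Binary ground-truth opacity mask (0/1 matrix); has foreground
#'   pixels exactly when the record is positive.
#' @export
setClass("PhantomCase",
         representation(record = "CaseRecord", raster = "ImageRaster", mask = "matrix"),
         validity = function(object) {
  if (!identical(dim(object@mask), dim(object@raster@pixels)))
    return("mask and raster must share dimensions")
  if ((sum(object@mask) > 0) != (object@record@target == 1L))
    return("mask has foreground pixels exactly when target = 1")
  TRUE
})

#' NetConfig: UNet architecture parameters
#'
#' The contracting path has `depth` stages of two 3x3 convolutions + ReLU;
#' 2x2 max-pooling (stride 2) follows each stage but the deepest. Filter
#' counts double per stage: stage k holds `baseFilters * 2^(k-1)` filters.
#'
#' @slot depth Number of stages.
#' @slot baseFilters Filters at the first stage.
#' @slot inSize Input side length; must be divisible by `2^depth`.
#' @export
setClass("NetConfig",
         representation(depth = "integer", baseFilters = "integer", inSize = "integer"),
         validity = function(object) {
  if (object@depth < 1L) return("depth must be >= 1")
  if (object@baseFilters < 1L) return("baseFilters must be >= 1")
  if (object@inSize %% (2^object@depth) != 0)
    return("inSize must be divisible by 2^depth")
  TRUE
})

#' AugmentConfig: training-time augmentation policy
#'
#' @slot flipProb Probability of a horizontal flip.
#' @slot rotRangeDeg Symmetric rotation bound in degrees (angle drawn
#'   uniformly in `[-rotRangeDeg, rotRangeDeg]`).
#' @slot contrastRange Multiplicative contrast factors `(low, high)`; the
#'   factor scales deviation from the image mean.
#' @export
setClass("AugmentConfig",
         representation(flipProb = "numeric", rotRangeDeg = "numeric",
                        contrastRange = "numeric"),
         validity = function(object) {
  if (object@flipProb < 0 || object@flipProb > 1) return("flipProb must lie in [0, 1]")
  if (object@rotRangeDeg < 0) return("rotRangeDeg must be >= 0")
  if (length(object@contrastRange) != 2 || object@contrastRange[1] <= 0 ||
      object@contrastRange[2] < object@contrastRange[1])
    return("contrastRange must be (low, high) with 0 < low <= high")
  TRUE
})

#' TrainConfig: optimizer, loss and batch-scheme settings for one training run
#'
#' @slot optimizer Optimizer name (only `"adam"` is implemented).
#' @slot lr Learning rate.
#' @slot loss Per-pixel loss name (only `"bce"`, binary cross-entropy).
#' @slot steps Number of gradient steps.
#' @slot scheme The [BatchScheme-class] controlling batch composition.
#' @slot seed Integer seed for initialization, sampling and augmentation.
#' @slot augment The [AugmentConfig-class].
#' @export
setClass("TrainConfig",
         representation(optimizer = "character", lr = "numeric", loss = "character",
                        steps = "integer", scheme = "BatchScheme", seed = "integer",
                        augment = "AugmentConfig"),
         validity = function(object) {
  if (object@steps < 1L) return("steps must be >= 1")
  if (object@lr < 0) return("lr must be non-negative")
  if (!identical(object@optimizer, "adam")) return("only the adam optimizer is implemented")
  if (!identical(object@loss, "bce")) return("only the bce loss is implemented")
  TRUE
})

#' UNetModel: a (possibly trained) UNet with provenance
#'
#' @slot params Named list of weight arrays.
#' @slot netConfig The [NetConfig-class].
#' @slot provenance List recording the training configuration and trial index
#'   (empty for an untrained network).
#' @slot lossTrace Per-step training loss (length 0 for untrained).
#' @export
setClass("UNetModel",
         representation(params = "list", netConfig = "NetConfig",
                        provenance = "list", lossTrace = "numeric"))

#' ThresholdSegmenter: a fixed-intensity-threshold segmenter
#'
#' Predicts foreground wherever pixel intensity is at least `threshold`.
#' It honors the same prediction contract as [UNetModel-class] and serves as
#' a pipeline oracle on noise-free phantoms.
#'
#' @slot threshold Intensity cut in `[0, 1]`.
#' @export
setClass("ThresholdSegmenter", representation(threshold = "numeric"),
         validity = function(object) {
  if (length(object@threshold) != 1 || !is.finite(object@threshold))
    return("threshold must be a single finite number")
  TRUE
})

#' @param threshold Intensity cut.
#' @rdname ThresholdSegmenter-class
#' @export
thresholdSegmenter <- function(threshold) new("ThresholdSegmenter", threshold = threshold)

#' CaseOutcome: adjudicated status of one test case
#'
#' @slot id Case identifier.
#' @slot outcome One of `"TP"`, `"FP"`, `"TN"`, `"FN"`.
#' @slot predBoxes,trueBoxes Box tables ([boxFrame()]).
#' @export
setClass("CaseOutcome",
         representation(id = "character", outcome = "character",
                        predBoxes = "data.frame", trueBoxes = "data.frame"),
         validity = function(object) {
  if (!object@outcome %in% c("TP", "FP", "TN", "FN")) return("invalid outcome")
  if (object@outcome %in% c("TN", "FN") && nrow(object@predBoxes) > 0)
    return("TN/FN imply no predicted boxes")
  if (object@outcome %in% c("TP", "FP") && nrow(object@predBoxes) == 0)
    return("TP/FP imply predicted boxes")
  TRUE
})
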