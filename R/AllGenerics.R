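#' @rdname accessors
#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))
#' @rdname accessors
#' @export
setGeneric("caseClass", function(x) standardGeneric("caseClass"))
#' @rdname accessors
#' @export
setGeneric("caseTarget", function(x) standardGeneric("caseTarget"))
#' @rdname accessors
#' @export
setGeneric("caseBoxes", function(x) standardGeneric("caseBoxes"))
#' @rdname accessors
#' @export
setGeneric("trainCases", function(x) standardGeneric("trainCases"))
#' @rdname accessors
#' @export
setGeneric("testCases", function(x) standardGeneric("testCases"))
#' @rdname accessors
#' @export
setGeneric("schemeName", function(x) standardGeneric("schemeName"))
#' @rdname accessors
#' @export
setGeneric("batchSize", function(x) standardGeneric("batchSize"))
#' @rdname accessors
#' @export
setGeneric("nPositives", function(x) standardGeneric("nPositives"))
#' @rdname accessors
#' @export
setGeneric("lossTrace", function(x) standardGeneric("lossTrace"))
#' @rdname accessors
#' @export
setGeneric("caseOutcome", function(x) standardGeneric("caseOutcome"))

#' Predict an opacity mask for one image
#'
#' @param model A segmenter ([UNetModel-class] or [ThresholdSegmenter-class]).
#' @param image An [ImageRaster-class] (or plain matrix) with intensities in
#'   `[0, 1]`.
#' @param threshold Probability cut applied to the probability map.
#' @param ... Method-specific arguments.
#' @return A list with `mask` (binary matrix at the original image resolution)
#'   and `prob` (probability map at the original resolution, values in `[0, 1]`).
#' @export
setGeneric("predictMask", function(model, image, threshold = 0.5, ...)
  standardGeneric("predictMask"))

#' Accessors for bcmseg classes
#'
#' `caseId`, `caseClass`, `caseTarget` and `caseBoxes` read the slots of a
#' [CaseRecord-class] (or of the record inside a [PhantomCase-class]);
#' `trainCases`/`testCases` read a [DatasetSplit-class]; `schemeName`,
#' `batchSize` and `nPositives` read a [BatchScheme-class]; `lossTrace` reads
#' the per-step training loss of a [UNetModel-class]; `caseOutcome` reads the
#' adjudicated status of a [CaseOutcome-class].
#'
#' @param x The object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("caseId", "CaseRecord", function(x) x@id)
#' @rdname accessors
setMethod("caseClass", "CaseRecord", function(x) x@klass)
#' @rdname accessors
setMethod("caseTarget", "CaseRecord", function(x) x@target)
#' @rdname accessors
setMethod("caseBoxes", "CaseRecord", function(x) x@boxes)
#' @rdname accessors
setMethod("caseId", "PhantomCase", function(x) x@record@id)
#' @rdname accessors
setMethod("caseClass", "PhantomCase", function(x) x@record@klass)
#' @rdname accessors
setMethod("caseTarget", "PhantomCase", function(x) x@record@target)
#' @rdname accessors
setMethod("caseBoxes", "PhantomCase", function(x) x@record@boxes)
#' @rdname accessors
setMethod("caseId", "ImageRaster", function(x) x@id)
#' @rdname accessors
setMethod("trainCases", "DatasetSplit", function(x) x@train)
#' @rdname accessors
setMethod("testCases", "DatasetSplit", function(x) x@test)
#' @rdname accessors
setMethod("schemeName", "BatchScheme", function(x) x@name)
#' @rdname accessors
setMethod("batchSize", "BatchScheme", function(x) x@batchSize)
#' @rdname accessors
setMethod("nPositives", "BatchScheme", function(x) x@nPos)
#' @rdname accessors
setMethod("lossTrace", "UNetModel", function(x) x@lossTrace)
#' @rdname accessors
setMethod("caseOutcome", "CaseOutcome", function(x) x@outcome)

setMethod("show", "CaseRecord", function(object) {
  cat(sprintf("CaseRecord %s [%s] target=%d, %d box(es)\n",
              object@id, object@klass, object@target, nrow(object@boxes)))
})

setMethod("show", "ImageRaster", function(object) {
  cat(sprintf("ImageRaster %s: %d x %d, intensity range [%.3g, %.3g]\n",
              object@id, nrow(object@pixels), ncol(object@pixels),
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "DatasetSplit", function(object) {
  tt <- vapply(object@test, function(r) r@target, 0L)
  cat(sprintf("DatasetSplit: %d train, %d test (%d pos / %d neg)\n",
              length(object@train), length(object@test), sum(tt == 1L), sum(tt == 0L)))
})

setMethod("show", "BatchScheme", function(object) {
  if (object@name == "RAND")
    cat(sprintf("BatchScheme RAND (B = %d, unconstrained)\n", object@batchSize))
  else
    cat(sprintf("BatchScheme %s (B = %d: %d positive + %d negative)\n",
                object@name, object@batchSize, object@nPos,
                object@batchSize - object@nPos))
})

setMethod("show", "UNetModel", function(object) {
  nc <- object@netConfig
  np <- sum(vapply(object@params, length, 0L))
  state <- if (length(object@lossTrace)) sprintf("trained %d steps", length(object@lossTrace)) else "untrained"
  cat(sprintf("UNetModel: depth %d, base filters %d, input %dx%d, %d parameters (%s)\n",
              nc@depth, nc@baseFilters, nc@inSize, nc@inSize, np, state))
})

setMethod("show", "PhantomCase", function(object) {
  cat(sprintf("PhantomCase %s [%s]: %dx%d raster, %d mask pixel(s), %d box(es)\n",
              object@record@id, object@record@klass, nrow(object@mask),
              ncol(object@mask), sum(object@mask), nrow(object@record@boxes)))
})

setMethod("show", "CaseOutcome", function(object) {
  cat(sprintf("CaseOutcome %s: %s (%d true / %d predicted box(es))\n",
              object@id, object@outcome, nrow(object@trueBoxes), nrow(object@predBoxes)))
})
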