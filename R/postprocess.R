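#' Extract bounding boxes from a binary mask
#'
#' One box per 8-connected foreground component with at least `minArea`
#' pixels; each box is the tight axis-aligned bounding rectangle of its
#' component, in 0-based half-open coordinates.
#'
#' The default `minArea` of 0.1% of the image area suppresses the scattered
#' spurious specks that unstable models produce; pass `minArea = 1` to keep
#' every component.
#'
#' @param mask Binary matrix.
#' @param minArea Minimum component pixel count.
#' @return A [boxFrame()] table (zero rows for an empty mask).
#' @export
maskToBoxes <- function(mask, minArea = NULL) {
  mask <- as.matrix(mask)
  if (is.null(minArea)) minArea <- max(1, round(0.001 * length(mask)))
  lab <- .labelComponents8(mask > 0)
  n <- max(lab)
  if (n == 0) return(boxFrame())
  out <- lapply(seq_len(n), function(i) {
    w <- which(lab == i, arr.ind = TRUE)
    if (nrow(w) < minArea) return(NULL)
    data.frame(x = min(w[, 2]) - 1, y = min(w[, 1]) - 1,
               w = max(w[, 2]) - min(w[, 2]) + 1,
               h = max(w[, 1]) - min(w[, 1]) + 1)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) boxFrame() else boxFrame(out$x, out$y, out$w, out$h)
}

#' Do two boxes overlap?
#'
#' True iff the intersection area is positive under half-open semantics:
#' boxes sharing only an edge or corner line do not overlap.
#'
#' @param a,b Single-row [boxFrame()] tables (or lists with `x`, `y`, `w`, `h`).
#' @return Logical.
#' @export
boxesOverlap <- function(a, b) {
  (a$x < b$x + b$w) && (b$x < a$x + a$w) &&
    (a$y < b$y + b$h) && (b$y < a$y + a$h)
}

.anyOverlap <- function(trueBoxes, predBoxes) {
  for (i in seq_len(nrow(trueBoxes)))
    for (j in seq_len(nrow(predBoxes)))
      if (boxesOverlap(trueBoxes[i, ], predBoxes[j, ])) return(TRUE)
  FALSE
}

#' Adjudicate one case from its true and predicted boxes
#'
#' Case-level rule of the analogous ROC evaluation: the prediction is positive
#' iff any box was predicted, the case is positive iff it has reference boxes,
#' and a positive prediction on a positive case counts as TP only when at
#' least one predicted box overlaps at least one reference box — extra
#' non-overlapping predicted boxes do not revoke a TP, while a positive case
#' whose predicted boxes all miss the reference boxes is an FP.
#'
#' @param trueBoxes,predBoxes [boxFrame()] tables.
#' @param id Case identifier.
#' @return A [CaseOutcome-class].
#' @export
adjudicateCase <- function(trueBoxes, predBoxes, id = "case") {
  validateBoxes(trueBoxes); validateBoxes(predBoxes)
  truePos <- nrow(trueBoxes) > 0
  predPos <- nrow(predBoxes) > 0
  outcome <- if (predPos) {
    if (truePos && .anyOverlap(trueBoxes, predBoxes)) "TP" else "FP"
  } else {
    if (truePos) "FN" else "TN"
  }
  new("CaseOutcome", id = as.character(id), outcome = outcome,
      predBoxes = predBoxes, trueBoxes = trueBoxes)
}

#' Adjudicate a set of cases into an outcome table
#'
#' @param records List of [CaseRecord-class]/[PhantomCase-class] (the truth).
#' @param predBoxes Named list (by id) or list parallel to `records` of
#'   predicted [boxFrame()] tables.
#' @return Data frame with columns `id`, `outcome`, `n_true_boxes`,
#'   `n_pred_boxes`.
#' @export
adjudicateCases <- function(records, predBoxes) {
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    pb <- if (!is.null(names(predBoxes))) predBoxes[[caseId(r)]] else predBoxes[[i]]
    if (is.null(pb)) pb <- boxFrame()
    oc <- adjudicateCase(caseBoxes(r), pb, caseId(r))
    data.frame(id = oc@id, outcome = oc@outcome,
               n_true_boxes = nrow(oc@trueBoxes),
               n_pred_boxes = nrow(oc@predBoxes),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Predict and adjudicate a test set
#'
#' Runs [predictMask()] on every test case, extracts boxes at the original
#' image resolution ([maskToBoxes()]) and adjudicates against the reference
#' boxes.
#'
#' @param model Any segmenter honoring the [predictMask()] contract.
#' @param cases List of [PhantomCase-class] (or records, with `rasterFor`).
#' @param threshold Probability cut for the mask.
#' @param minArea Minimum component area for [maskToBoxes()].
#' @param rasterFor Optional `id -> ImageRaster` accessor for plain records.
#' @return Outcome table as in [adjudicateCases()].
#' @export
evaluateCases <- function(model, cases, threshold = 0.5, minArea = NULL,
                          rasterFor = NULL) {
  preds <- lapply(cases, function(cs) {
    # phantom rasters are already unit-scale; external rasters are rescaled
    img <- if (is(cs, "PhantomCase")) cs@raster
    else normalizeRaster(rasterFor(caseId(cs)))
    pm <- predictMask(model, img, threshold)
    maskToBoxes(pm$mask, minArea)
  })
  adjudicateCases(cases, preds)
}
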