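#' Read a challenge-style label table
#'
#' Parses a CSV with columns `patientId, x, y, width, height, Target`
#' (multiple rows per patient, one per box; coordinates blank when
#' `Target = 0`) into one [CaseRecord-class] per distinct patient.
#'
#' The CSV carries no three-way class column, so negatives default to
#' `"no_opacity_not_normal"`; pass `classMap` (named character vector,
#' id -> class) to restore the three-way label, e.g. from a phantom manifest.
#'
#' @param path CSV file path.
#' @param classMap Optional named character vector mapping ids to classes.
#' @return List of [CaseRecord-class], in first-appearance order.
#' @export
readLabelTable <- function(path, classMap = NULL) {
  if (!file.exists(path)) stop("label table not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patientId", "x", "y", "width", "height", "Target")
  if (!all(need %in% names(df)))
    stop("label table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  ids <- unique(df$patientId)
  lapply(ids, function(id) {
    rows <- df[df$patientId == id, , drop = FALSE]
    tg <- unique(rows$Target)
    if (length(tg) != 1)
      stop("conflicting Target values for id ", id, call. = FALSE)
    if (tg == 1L) {
      if (any(!is.finite(rows$x) | !is.finite(rows$width)))
        stop("Target = 1 with no parseable box for id ", id, call. = FALSE)
      boxes <- boxFrame(rows$x, rows$y, rows$width, rows$height)
      klass <- "lung_opacity"
    } else {
      boxes <- boxFrame()
      klass <- if (!is.null(classMap) && id %in% names(classMap))
        unname(classMap[id]) else "no_opacity_not_normal"
    }
    if (!is.null(classMap) && id %in% names(classMap) && tg == 1L)
      klass <- unname(classMap[id])
    caseRecord(id, klass, boxes)
  })
}

#' Write a label table in the challenge CSV dialect
#'
#' One row per box for positive cases; a single row with blank coordinates for
#' negatives.
#'
#' @param records List of [CaseRecord-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeLabelTable <- function(records, path) {
  rows <- lapply(records, function(r) {
    if (r@target == 1L) {
      data.frame(patientId = r@id, x = r@boxes$x, y = r@boxes$y,
                 width = r@boxes$w, height = r@boxes$h, Target = 1L)
    } else {
      data.frame(patientId = r@id, x = NA_real_, y = NA_real_,
                 width = NA_real_, height = NA_real_, Target = 0L)
    }
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Build a class-balanced test split
#'
#' Draws `nPerClass` positive and `nPerClass` negative cases without
#' replacement for the test set; the remainder forms the training set
#' (optionally truncated to `trainSize` by a further seeded draw, discarding
#' the rest — both behaviors of the published split arithmetic are reachable).
#' Deterministic for a fixed seed.
#'
#' @param records List of [CaseRecord-class].
#' @param nPerClass Test cases per class.
#' @param seed Integer seed.
#' @param trainSize Optional training-set size; `NULL` keeps all remaining.
#' @return A [DatasetSplit-class].
#' @export
splitBalancedTest <- function(records, nPerClass, seed, trainSize = NULL) {
  tg <- recordTargets(records)
  posIdx <- which(tg == 1L)
  negIdx <- which(tg == 0L)
  if (length(posIdx) < nPerClass || length(negIdx) < nPerClass)
    stop(sprintf("need >= %d cases per class (have %d positive, %d negative)",
                 nPerClass, length(posIdx), length(negIdx)), call. = FALSE)
  withSeed(seed, {
    testIdx <- c(sample(posIdx, nPerClass), sample(negIdx, nPerClass))
    trainIdx <- setdiff(seq_along(records), testIdx)
    if (!is.null(trainSize)) {
      if (trainSize > length(trainIdx))
        stop("trainSize exceeds available non-test cases", call. = FALSE)
      trainIdx <- sort(sample(trainIdx, trainSize))
    }
    new("DatasetSplit", train = records[trainIdx], test = records[testIdx])
  })
}

#' Write a prediction table
#'
#' Challenge submission dialect: columns `patientId, PredictionString`, where
#' the prediction string is a space-separated sequence `conf x y w h` repeated
#' per box and empty for negative predictions.
#'
#' @param ids Character vector of unique case ids.
#' @param boxes List (parallel to `ids`) of box tables ([boxFrame()]).
#' @param conf List/vector of per-box confidences, parallel to `boxes`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writePredictionTable <- function(ids, boxes, conf, path) {
  if (anyDuplicated(ids)) stop("duplicate ids in prediction table", call. = FALSE)
  stopifnot(length(boxes) == length(ids), length(conf) == length(ids))
  ps <- vapply(seq_along(ids), function(i) {
    b <- boxes[[i]]
    if (is.null(b) || nrow(b) == 0) return("")
    cf <- conf[[i]]
    if (length(cf) != nrow(b)) stop("confidence length must match box count", call. = FALSE)
    paste(vapply(seq_len(nrow(b)), function(j)
      paste(vapply(c(cf[j], b$x[j], b$y[j], b$w[j], b$h[j]),
                   format, "", trim = TRUE, scientific = FALSE),
            collapse = " "), ""),
      collapse = " ")
  }, "")
  write.csv(data.frame(patientId = ids, PredictionString = ps), path,
            row.names = FALSE)
  invisible(path)
}

#' Read a prediction table
#'
#' Inverse of [writePredictionTable()].
#'
#' @param path CSV path.
#' @return Named list (by id) with elements `boxes` and `conf`.
#' @export
readPredictionTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  out <- lapply(seq_len(nrow(df)), function(i) {
    s <- trimws(df$PredictionString[i])
    if (is.na(s) || s == "")
      return(list(boxes = boxFrame(), conf = numeric()))
    v <- as.numeric(strsplit(s, "\\s+")[[1]])
    if (length(v) %% 5 != 0)
      stop("malformed PredictionString for id ", df$patientId[i], call. = FALSE)
    m <- matrix(v, ncol = 5, byrow = TRUE)
    list(boxes = boxFrame(m[, 2], m[, 3], m[, 4], m[, 5]), conf = m[, 1])
  })
  names(out) <- df$patientId
  out
}

#' Read a PNG raster
#'
#' Accepted as the phantom raster source; grayscale only.
#'
#' @param path PNG path.
#' @param id Case identifier (defaults to the file stem).
#' @return An [ImageRaster-class] with intensities in `[0, 1]`.
#' @export
readPngImage <- function(path, id = sub("\\.png$", "", basename(path))) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) {
    if (dim(px)[3] > 2) stop("color PNG payloads are unsupported", call. = FALSE)
    px <- px[, , 1]
  }
  imageRaster(px, id)
}
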