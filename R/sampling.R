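.P_SCHEME_PCT <- c(P100 = 100, P83 = 83, P66 = 66, P50 = 50, P33 = 33, P17 = 17)

#' Construct a batch scheme
#'
#' A scheme is given either by name (`"P83"`, `"RAND"`, ...) or by an explicit
#' positives-per-batch count `nPos`, from which the percent name is derived
#' (rounding half away from zero). The canonical schemes are attached to batch
#' size 6; other batch sizes are supported through `nPos`.
#'
#' @param name Scheme name, or `NULL` when `nPos` is given.
#' @param batchSize Cases per minibatch (default 6).
#' @param nPos Positives per batch (P-schemes only).
#' @return A [BatchScheme-class].
#' @examples
#' batchScheme("P83")            # 5 positives + 1 negative at batch size 6
#' batchScheme(nPos = 6, batchSize = 9)  # derived name "P67"
#' @export
batchScheme <- function(name = NULL, batchSize = 6, nPos = NULL) {
  batchSize <- as.integer(batchSize)
  if (!is.null(nPos)) {
    nPos <- as.integer(nPos)
    name <- paste0("P", roundHalfAway(100 * nPos / batchSize))
    return(new("BatchScheme", name = name, batchSize = batchSize, nPos = nPos))
  }
  if (is.null(name)) stop("give a scheme name or nPos", call. = FALSE)
  if (name == "RAND")
    return(new("BatchScheme", name = "RAND", batchSize = batchSize, nPos = NA_integer_))
  comp <- schemeComposition(name, batchSize)
  new("BatchScheme", name = name, batchSize = batchSize, nPos = comp[["nPos"]])
}

#' Positive/negative composition of a P-scheme
#'
#' `nPos = round(batchSize * pct / 100)` (half away from zero), clamped so that
#' every P-scheme draws at least one positive and every scheme other than P100
#' at least one negative.
#'
#' @param name P-scheme name (`"P100"` ... `"P17"`); `"RAND"` is rejected
#'   because it has no fixed composition.
#' @param batchSize Cases per minibatch.
#' @return Named integer vector `c(nPos, nNeg)`.
#' @examples
#' schemeComposition("P83", 6)  # 5 positives, 1 negative
#' @export
schemeComposition <- function(name, batchSize = 6) {
  if (identical(name, "RAND"))
    stop("RAND has no fixed composition", call. = FALSE)
  if (!name %in% names(.P_SCHEME_PCT))
    stop("unknown scheme name: ", name, call. = FALSE)
  batchSize <- as.integer(batchSize)
  if (batchSize < 1) stop("batchSize must be >= 1", call. = FALSE)
  pct <- .P_SCHEME_PCT[[name]]
  hi <- if (name == "P100") batchSize else batchSize - 1L
  nPos <- as.integer(min(max(roundHalfAway(batchSize * pct / 100), 1L), hi))
  c(nPos = nPos, nNeg = batchSize - nPos)
}

#' Draw one minibatch under a scheme
#'
#' P-schemes draw `nPos` cases with replacement from the positive pool and the
#' rest from the negative pool, then shuffle within-batch order; RAND draws the
#' whole batch with replacement from the concatenated pools. Uses the current
#' RNG stream.
#'
#' @param scheme A [BatchScheme-class].
#' @param posPool,negPool Lists of [CaseRecord-class] (or [PhantomCase-class]).
#' @return A [Batch-class].
#' @export
drawBatch <- function(scheme, posPool, negPool) {
  idx <- drawBatchIndices(scheme, length(posPool), length(negPool))
  cases <- lapply(seq_along(idx$pool), function(i)
    if (idx$pool[i] == 1L) posPool[[idx$index[i]]] else negPool[[idx$index[i]]])
  cases <- lapply(cases, function(x) if (is(x, "PhantomCase")) x@record else x)
  new("Batch", cases = cases, scheme = scheme)
}

#' Draw minibatch indices under a scheme
#'
#' Lower-level companion of [drawBatch()] used by the training loop: returns
#' pool membership and within-pool indices instead of copying case objects.
#'
#' @param scheme A [BatchScheme-class].
#' @param nPos,nNeg Pool sizes.
#' @return List with `pool` (1 = positive pool, 2 = negative pool) and `index`
#'   (position within that pool), both of length `batchSize`, in shuffled order.
#' @export
drawBatchIndices <- function(scheme, nPos, nNeg) {
  B <- scheme@batchSize
  if (scheme@name == "RAND") {
    if (nPos + nNeg == 0) stop("empty training pool", call. = FALSE)
    k <- sample.int(nPos + nNeg, B, replace = TRUE)
    pool <- ifelse(k <= nPos, 1L, 2L)
    index <- ifelse(k <= nPos, k, k - nPos)
  } else {
    kp <- scheme@nPos
    kn <- B - kp
    if (kp > 0 && nPos == 0) stop("positive pool is empty", call. = FALSE)
    if (kn > 0 && nNeg == 0) stop("negative pool is empty", call. = FALSE)
    pool <- c(rep(1L, kp), rep(2L, kn))
    index <- c(sample.int(max(nPos, 1L), kp, replace = TRUE),
               sample.int(max(nNeg, 1L), kn, replace = TRUE))
    ord <- sample.int(B)
    pool <- pool[ord]
    index <- index[ord]
  }
  list(pool = pool, index = index)
}

#' Expected positive fraction of RAND batches
#'
#' The long-run positive fraction of unconstrained random minibatches equals
#' the pool prevalence `|{target = 1}| / n`.
#'
#' @param records List of [CaseRecord-class]/[PhantomCase-class], or a binary
#'   target vector.
#' @return The positive fraction.
#' @examples
#' # published training counts: 5430 positives of 24,684 -> 22%
#' randExpectedPositiveFraction(rep(c(1, 0), c(5430, 24684 - 5430)))
#' @export
randExpectedPositiveFraction <- function(records) {
  if (length(records) == 0) stop("empty record list", call. = FALSE)
  tg <- if (is.numeric(records)) records else vapply(records, caseTarget, 0L)
  mean(tg == 1)
}
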