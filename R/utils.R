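# Internal helpers.

# round half away from zero (base round() is banker's rounding)
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# run expr with a temporary RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

recordTargets <- function(records) vapply(records, caseTarget, 0L)
recordIds <- function(records) vapply(records, caseId, "")

# bilinear ("bilinear") or nearest-neighbour ("none") resize of a matrix,
# preserving the [row = y, col = x] convention
resizeMatrix <- function(m, h, w, filter = c("bilinear", "none")) {
  filter <- match.arg(filter)
  if (nrow(m) == h && ncol(m) == w) return(m)
  out <- EBImage::resize(EBImage::Image(m), w = h, h = w, filter = filter)
  matrix(EBImage::imageData(out), nrow = h, ncol = w)
}

rasterPixels <- function(image) {
  if (is(image, "ImageRaster")) image@pixels else as.matrix(image)
}

#' Rescale intensities to the unit interval
#'
#' Divides by the per-image maximum, so mixed 8- and 16-bit sources land on a
#' common `[0, 1]` scale. A constant-zero image is returned unchanged.
#'
#' @param raster An [ImageRaster-class] or numeric matrix.
#' @return Object of the same type with intensities in `[0, 1]`.
#' @export
normalizeRaster <- function(raster) {
  px <- rasterPixels(raster)
  mx <- max(px)
  if (mx > 0) px <- px / mx
  if (is(raster, "ImageRaster")) imageRaster(px, raster@id) else px
}
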