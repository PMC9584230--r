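#' Augmentation configuration
#'
#' Defaults follow the training policy of the full-scale experiment: random
#' horizontal flip, rotation drawn uniformly in +/- 15 degrees, and a
#' multiplicative contrast factor in 0.6-1.4 applied to the deviation from the
#' image mean.
#'
#' @param flipProb Horizontal-flip probability.
#' @param rotRangeDeg Symmetric rotation bound (degrees).
#' @param contrastRange Contrast factor range `(low, high)`.
#' @return An [AugmentConfig-class].
#' @export
augmentConfig <- function(flipProb = 0.5, rotRangeDeg = 15,
                          contrastRange = c(0.6, 1.4)) {
  new("AugmentConfig", flipProb = flipProb, rotRangeDeg = rotRangeDeg,
      contrastRange = contrastRange)
}

# rotate a matrix about its center by thetaDeg; bilinear or nearest-neighbour
# sampling, exposed pixels filled with bg
rotateMatrix <- function(m, thetaDeg, filter = c("bilinear", "none"), bg = 0) {
  filter <- match.arg(filter)
  if (thetaDeg == 0) return(m)
  H <- nrow(m); W <- ncol(m)
  th <- thetaDeg * pi / 180
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  r <- matrix(rep(seq_len(H), times = W), H, W) - cr
  c <- matrix(rep(seq_len(W), each = H), H, W) - cc
  # inverse rotation of output coordinates into the source frame
  sr <- cos(th) * r - sin(th) * c + cr
  sc <- sin(th) * r + cos(th) * c + cc
  if (filter == "none") {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out <- matrix(bg, H, W)
    out[ok] <- m[cbind(ri[ok], ci[ok])]
    return(out)
  }
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  gather <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    v <- matrix(bg, H, W)
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  out <- (1 - fr) * (1 - fc) * gather(r0, c0) +
    (1 - fr) * fc * gather(r0, c0 + 1) +
    fr * (1 - fc) * gather(r0 + 1, c0) +
    fr * fc * gather(r0 + 1, c0 + 1)
  out
}

#' Augment an image/mask pair
#'
#' Applies the same geometric transform to image and mask: a horizontal flip
#' with probability `flipProb`, then rotation by an angle drawn uniformly in
#' `+/- rotRangeDeg` (bilinear for the image with exposed corners filled with
#' the image minimum; nearest-neighbour for the mask, which therefore stays
#' binary). A contrast factor `c ~ Uniform(contrastRange)` is then applied to
#' the image only, as `mean + c * (pixel - mean)`, clipped to `[0, 1]`.
#' Uses the current RNG stream.
#'
#' @param image Numeric matrix (intensities in `[0, 1]`) or [ImageRaster-class].
#' @param mask Binary matrix of the same shape.
#' @param config An [AugmentConfig-class].
#' @return List with transformed `image` and `mask` matrices.
#' @export
augmentPair <- function(image, mask, config = augmentConfig()) {
  img <- rasterPixels(image)
  mask <- as.matrix(mask)
  if (!identical(dim(img), dim(mask)))
    stop("image and mask must have identical shapes", call. = FALSE)
  if (config@flipProb > 0 && runif(1) < config@flipProb) {
    img <- img[, ncol(img):1, drop = FALSE]
    mask <- mask[, ncol(mask):1, drop = FALSE]
  }
  if (config@rotRangeDeg > 0) {
    theta <- runif(1, -config@rotRangeDeg, config@rotRangeDeg)
    img <- rotateMatrix(img, theta, "bilinear", bg = min(img))
    mask <- rotateMatrix(mask, theta, "none", bg = 0)
  }
  lo <- config@contrastRange[1]; hi <- config@contrastRange[2]
  if (!(lo == 1 && hi == 1)) {
    cf <- runif(1, lo, hi)
    mu <- mean(img)
    img <- pmin(pmax(mu + cf * (img - mu), 0), 1)
  }
  list(image = img, mask = mask)
}
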