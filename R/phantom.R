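#' Phantom population configuration
#'
#' Defaults emulate the class mix of the challenge training data: 22%
#' lung-opacity prevalence, negatives split roughly evenly between plain
#' normals and no-opacity-not-normal cases carrying a non-opacity distractor
#' (bright streak or texture patch). Opacity blobs are blurred ellipses of
#' additive contrast `blobContrast` placed inside a lung field; `noiseSd`
#' is i.i.d. Gaussian pixel noise.
#'
#' @param imageSize Pixels per side (default 128, the desk-scale test size).
#' @param nCases Number of cases.
#' @param prevalence Fraction of lung-opacity cases.
#' @param fracNotNormal Fraction of negatives that are no-opacity-not-normal.
#' @param blobCountRange Min/max opacity blobs per positive case.
#' @param blobContrast Additive blob intensity.
#' @param noiseSd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return A [PhantomConfig-class].
#' @export
phantomConfig <- function(imageSize = 128, nCases = 100, prevalence = 0.22,
                          fracNotNormal = 0.5, blobCountRange = c(1, 3),
                          blobContrast = 0.35, noiseSd = 0.05, seed = 1) {
  new("PhantomConfig", imageSize = as.integer(imageSize),
      nCases = as.integer(nCases), prevalence = prevalence,
      fracNotNormal = fracNotNormal,
      blobCountRange = as.integer(blobCountRange),
      blobContrast = blobContrast, noiseSd = noiseSd, seed = as.integer(seed))
}

# logical ellipse on an s x s grid; cx, cy, a, b in pixels (0-based center)
.ellipse <- function(s, cx, cy, a, b) {
  xs <- (seq_len(s) - 1 - cx) / a
  ys <- (seq_len(s) - 1 - cy) / b
  outer(ys^2, xs^2, `+`) <= 1
}

.phantomGeometry <- function(s) {
  j <- function(f) f + runif(1, -0.015, 0.015)
  list(
    thorax = c(cx = j(0.50) * s, cy = j(0.54) * s, a = 0.42 * s, b = 0.44 * s),
    lungs = list(
      c(cx = j(0.31) * s, cy = j(0.46) * s, a = 0.155 * s, b = 0.27 * s),
      c(cx = j(0.69) * s, cy = j(0.46) * s, a = 0.155 * s, b = 0.27 * s))
  )
}

.LUNG_BG <- 0.25
.THORAX_BG <- 0.55
.OUTSIDE_BG <- 0.05
.DISTRACTOR_MAX <- 0.65

#' Generate one synthetic phantom case
#'
#' The background is two darkened elliptical lung fields on a brighter thorax.
#' `lung_opacity` cases add 1+ blurred elliptical blobs of additive intensity
#' `blobContrast` wholly inside a lung field; the ground-truth mask is the
#' blurred blob field at half contrast, so with `noiseSd = 0` thresholding the
#' raster at `lung background + blobContrast / 2` recovers the mask exactly.
#' `no_opacity_not_normal` cases add a non-opacity distractor (bright streak
#' or texture patch, intensity capped at 0.65) with an all-zero mask; `normal`
#' cases add nothing. Uses the current RNG stream; seed it for reproducibility.
#'
#' @param config A [PhantomConfig-class].
#' @param klass Case class.
#' @param id Case identifier.
#' @return A [PhantomCase-class].
#' @export
generatePhantomCase <- function(config, klass, id = "phantom") {
  if (!klass %in% KLASS_LEVELS)
    stop("unknown class: ", klass, call. = FALSE)
  s <- config@imageSize
  geo <- .phantomGeometry(s)
  img <- matrix(.OUTSIDE_BG, s, s)
  th <- geo$thorax
  img[.ellipse(s, th["cx"], th["cy"], th["a"], th["b"])] <- .THORAX_BG
  for (lg in geo$lungs)
    img[.ellipse(s, lg["cx"], lg["cy"], lg["a"], lg["b"])] <- .LUNG_BG
  img <- as.matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                                     sigma = max(1, s / 128))))

  mask <- matrix(0L, s, s)
  if (klass == "lung_opacity") {
    sigma <- s / 64
    margin <- 3 * sigma + 2
    rng <- config@blobCountRange
    nBlob <- if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1)
    field <- matrix(0, s, s)
    for (i in seq_len(nBlob)) {
      lg <- geo$lungs[[sample(2, 1)]]
      a <- runif(1, 0.05, 0.095) * s
      b <- runif(1, 0.05, 0.095) * s
      ea <- max(lg["a"] - a - margin, 1)
      eb <- max(lg["b"] - b - margin, 1)
      cx <- lg["cx"]; cy <- lg["cy"]
      for (try in 1:50) {
        dx <- runif(1, -ea, ea); dy <- runif(1, -eb, eb)
        if ((dx / ea)^2 + (dy / eb)^2 <= 1) { cx <- lg["cx"] + dx; cy <- lg["cy"] + dy; break }
      }
      field <- field + config@blobContrast * .ellipse(s, cx, cy, a, b)
    }
    field <- as.matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(field),
                                                         sigma = sigma)))
    mask <- (field >= config@blobContrast / 2) + 0L
    if (sum(mask) == 0) mask <- (field >= max(field) / 2) + 0L
    img <- img + field
  } else if (klass == "no_opacity_not_normal") {
    img <- .addDistractor(img, geo, s)
  }

  if (config@noiseSd > 0) img <- img + rnorm(s * s, sd = config@noiseSd)
  img <- pmin(pmax(img, 0), 1)

  boxes <- maskToBoxes(mask, minArea = 1)
  record <- caseRecord(id, klass, boxes)
  new("PhantomCase", record = record, raster = imageRaster(img, id), mask = mask)
}

# bright linear streak (tube-like) or textured patch inside the thorax,
# never labeled and capped below .DISTRACTOR_MAX + eps
.addDistractor <- function(img, geo, s) {
  th <- geo$thorax
  if (runif(1) < 0.5) {
    theta <- runif(1, 0, pi)
    cx <- th["cx"] + runif(1, -0.15, 0.15) * s
    cy <- th["cy"] + runif(1, -0.15, 0.15) * s
    len <- 0.55 * s
    halfw <- max(1, s / 96)
    xs <- matrix(rep(seq_len(s) - 1, each = s), s, s)
    ys <- matrix(rep(seq_len(s) - 1, times = s), s, s)
    # distance from the segment through (cx, cy) with direction theta
    dxm <- xs - cx; dym <- ys - cy
    along <- dxm * cos(theta) + dym * sin(theta)
    perp <- abs(-dxm * sin(theta) + dym * cos(theta))
    streak <- perp <= halfw & abs(along) <= len / 2 &
      .ellipse(s, th["cx"], th["cy"], th["a"] * 0.9, th["b"] * 0.9)
    img[streak] <- .DISTRACTOR_MAX
  } else {
    w <- round(0.12 * s)
    x0 <- round(th["cx"] + runif(1, -0.2, 0.2) * s - w / 2)
    y0 <- round(th["cy"] + runif(1, -0.2, 0.2) * s - w / 2)
    rows <- pmax(1, pmin(s, y0:(y0 + w - 1)))
    cols <- pmax(1, pmin(s, x0:(x0 + w - 1)))
    patch <- matrix(runif(length(rows) * length(cols), 0.50,
                          .DISTRACTOR_MAX - 0.02),
                    length(rows), length(cols))
    img[rows, cols] <- patch
  }
  img
}

#' Generate a full phantom dataset
#'
#' Class counts are deterministic, not sampled: exactly
#' `round(nCases * prevalence)` positives (half away from zero), with the
#' negatives split by `fracNotNormal`. Fully reproducible from `config@seed`.
#' When `dir` is given, rasters are written as PNG, the label table in the
#' challenge CSV dialect, and a JSON manifest recording the full configuration
#' (including the seed) and each case's three-way class.
#'
#' @param config A [PhantomConfig-class].
#' @param dir Optional output directory.
#' @return A list with `cases` (list of [PhantomCase-class]), and — when `dir`
#'   is given — `labelTable` and `manifest` file paths.
#' @export
generatePhantomDataset <- function(config, dir = NULL) {
  nPos <- as.integer(roundHalfAway(config@nCases * config@prevalence))
  if (nPos < 1)
    stop("nCases * prevalence must be >= 1", call. = FALSE)
  nNeg <- config@nCases - nPos
  nNN <- as.integer(roundHalfAway(nNeg * config@fracNotNormal))
  klasses <- c(rep("lung_opacity", nPos),
               rep("no_opacity_not_normal", nNN),
               rep("normal", nNeg - nNN))
  ids <- sprintf("phantom-%04d", seq_len(config@nCases))
  cases <- withSeed(config@seed, {
    klasses <- sample(klasses)
    lapply(seq_len(config@nCases), function(i)
      generatePhantomCase(config, klasses[i], ids[i]))
  })

  out <- list(cases = cases, labelTable = NULL, manifest = NULL)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (pc in cases)
      png::writePNG(pc@raster@pixels, file.path(dir, paste0(pc@record@id, ".png")))
    out$labelTable <- writeLabelTable(lapply(cases, function(pc) pc@record),
                                      file.path(dir, "labels.csv"))
    manifest <- list(
      config = list(imageSize = config@imageSize, nCases = config@nCases,
                    prevalence = config@prevalence,
                    fracNotNormal = config@fracNotNormal,
                    blobCountRange = config@blobCountRange,
                    blobContrast = config@blobContrast,
                    noiseSd = config@noiseSd, seed = config@seed),
      classes = as.list(stats::setNames(vapply(cases, caseClass, ""),
                                        vapply(cases, caseId, ""))))
    out$manifest <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, out$manifest, auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
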