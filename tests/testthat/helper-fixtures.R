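# Fixture builders and independent oracles shared across test files.

# --- minimal explicit-VR little-endian DICOM writer (test fixture only) ------

.u16 <- function(x) as.raw(c(x %% 256, x %/% 256))
.u32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                             (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

.dcmElement <- function(group, elem, vr, body) {
  if (length(body) %% 2 == 1) body <- c(body, as.raw(0))  # even length rule
  hdr <- c(.u16(group), .u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    c(hdr, as.raw(c(0, 0)), .u32(length(body)), body)
  } else {
    c(hdr, .u16(length(body)), body)
  }
}

# pixels: integer matrix [row, col]; written row by row as unsigned ints
writeTestDicom <- function(path, pixels, patientId = "TEST001",
                           bits = 16L, frames = NULL, samples = 1L) {
  stopifnot(bits %in% c(8L, 16L))
  vals <- as.integer(t(pixels))  # row-major
  payload <- if (bits == 8L) as.raw(vals) else
    writeBin(vals, raw(), size = 2, endian = "little")
  out <- c(raw(128), charToRaw("DICM"))
  out <- c(out, .dcmElement(0x0010, 0x0020, "LO", charToRaw(patientId)))
  out <- c(out, .dcmElement(0x0028, 0x0002, "US", .u16(samples)))
  if (!is.null(frames))
    out <- c(out, .dcmElement(0x0028, 0x0008, "IS", charToRaw(as.character(frames))))
  out <- c(out, .dcmElement(0x0028, 0x0010, "US", .u16(nrow(pixels))))
  out <- c(out, .dcmElement(0x0028, 0x0011, "US", .u16(ncol(pixels))))
  out <- c(out, .dcmElement(0x0028, 0x0100, "US", .u16(bits)))
  out <- c(out, .dcmElement(0x7FE0, 0x0010, "OW", payload))
  writeBin(out, path)
  invisible(path)
}

# --- brute-force connected-component labeling (flood-fill oracle) ------------

floodLabel <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8)
    expand.grid(dr = -1:1, dc = -1:1) else
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  nxt <- 0L
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (i in seq_len(nrow(nb))) {
        r <- p[1] + nb$dr[i]; c <- p[2] + nb$dc[i]
        if (r >= 1 && r <= H && c >= 1 && c <= W && mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# --- brute-force case adjudication from pairwise rectangle intersection ------

bruteOutcome <- function(trueBoxes, predBoxes) {
  interArea <- function(a, b) {
    w <- min(a$x + a$w, b$x + b$w) - max(a$x, b$x)
    h <- min(a$y + a$h, b$y + b$h) - max(a$y, b$y)
    if (w > 0 && h > 0) w * h else 0
  }
  anyHit <- FALSE
  for (i in seq_len(nrow(trueBoxes))) for (j in seq_len(nrow(predBoxes)))
    if (interArea(trueBoxes[i, ], predBoxes[j, ]) > 0) anyHit <- TRUE
  if (nrow(predBoxes) > 0) {
    if (nrow(trueBoxes) > 0 && anyHit) "TP" else "FP"
  } else {
    if (nrow(trueBoxes) > 0) "FN" else "TN"
  }
}

# --- shared small trained model (memoized across test files) -----------------

.modelCache <- new.env(parent = emptyenv())

easySplit <- function() {
  if (is.null(.modelCache$split)) {
    pc <- phantomConfig(imageSize = 128, nCases = 80, prevalence = 0.25,
                        noiseSd = 0.02, blobContrast = 0.5, seed = 3)
    .modelCache$split <- splitBalancedTest(generatePhantomDataset(pc)$cases,
                                           10, seed = 1)
  }
  .modelCache$split
}

easyTrainedModel <- function() {
  if (is.null(.modelCache$model)) {
    cfg <- trainConfig(batchScheme("P50"), steps = 600, lr = 2e-3, seed = 5)
    net <- netConfig(depth = 2, baseFilters = 4, inSize = 32)
    .modelCache$model <- trainModel(easySplit(), cfg, net)
  }
  .modelCache$model
}
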