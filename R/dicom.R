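# Minimal DICOM ingestion: single-frame grayscale, little endian
# (explicit or implicit VR). Enough for challenge-style radiograph files;
# writing, color, multi-frame and compressed transfer syntaxes are out of scope.

.dcmU16 <- function(raw) sum(as.integer(raw) * c(1L, 256L))
.dcmU32 <- function(raw) sum(as.numeric(raw) * c(1, 256, 65536, 16777216))

#' Read a single-frame grayscale DICOM image
#'
#' Parses the data-set elements of a little-endian DICOM file (explicit or
#' implicit VR, with or without the 128-byte preamble) and returns the pixel
#' grid. Intensities are returned exactly as stored (unsigned 8- or 16-bit);
#' use [normalizeRaster()] to rescale to `[0, 1]`.
#'
#' @param path DICOM file path.
#' @return An [ImageRaster-class]; `id` is the PatientID element (falling back
#'   to the file stem when absent).
#' @export
readDicomImage <- function(path) {
  if (!file.exists(path)) stop("DICOM file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", file.size(path))
  pos <- 1L
  if (length(raw) >= 132 && rawToChar(raw[129:132]) == "DICM") pos <- 133L

  rows <- cols <- bits <- NA_integer_
  frames <- 1L
  samples <- 1L
  id <- sub("\\.dcm$", "", basename(path))
  pixdata <- NULL
  longVRs <- c("OB", "OW", "OF", "OL", "SQ", "UC", "UR", "UT", "UN")

  while (pos + 7 <= length(raw)) {
    group <- .dcmU16(raw[pos:(pos + 1)])
    elem <- .dcmU16(raw[(pos + 2):(pos + 3)])
    vrBytes <- as.integer(raw[(pos + 4):(pos + 5)])
    explicit <- all(vrBytes >= 65 & vrBytes <= 90)
    vr <- if (explicit) rawToChar(raw[(pos + 4):(pos + 5)]) else ""
    if (explicit) {
      if (vr %in% longVRs) {
        len <- .dcmU32(raw[(pos + 8):(pos + 11)])
        hdr <- 12L
      } else {
        len <- .dcmU16(raw[(pos + 6):(pos + 7)])
        hdr <- 8L
      }
    } else {
      len <- .dcmU32(raw[(pos + 4):(pos + 7)])
      hdr <- 8L
    }
    if (!is.finite(len) || len == 4294967295) stop("undefined-length DICOM elements are unsupported", call. = FALSE)
    body <- if (len > 0) raw[(pos + hdr):(pos + hdr + len - 1)] else raw(0)
    tag <- sprintf("%04x,%04x", group, elem)
    if (tag == "0010,0020") id <- trimws(rawToChar(body))
    else if (tag == "0028,0002") samples <- .dcmU16(body[1:2])
    else if (tag == "0028,0008") frames <- as.integer(trimws(rawToChar(body)))
    else if (tag == "0028,0010") rows <- .dcmU16(body[1:2])
    else if (tag == "0028,0011") cols <- .dcmU16(body[1:2])
    else if (tag == "0028,0100") bits <- .dcmU16(body[1:2])
    else if (tag == "7fe0,0010") { pixdata <- body; break }
    pos <- pos + hdr + len
  }

  if (is.null(pixdata)) stop("no PixelData element found", call. = FALSE)
  if (is.na(rows) || is.na(cols)) stop("missing Rows/Columns elements", call. = FALSE)
  if (!is.na(frames) && frames > 1) stop("multi-frame DICOM payloads are unsupported", call. = FALSE)
  if (samples != 1) stop("color (multi-sample) DICOM payloads are unsupported", call. = FALSE)
  if (is.na(bits)) bits <- 16L
  if (!bits %in% c(8L, 16L)) stop("only 8- and 16-bit payloads are supported", call. = FALSE)

  n <- rows * cols
  vals <- if (bits == 8L) {
    as.integer(pixdata[seq_len(n)])
  } else {
    if (length(pixdata) < 2 * n) stop("PixelData shorter than Rows x Columns", call. = FALSE)
    readBin(pixdata, "integer", n = n, size = 2, signed = FALSE, endian = "little")
  }
  # DICOM stores pixels row by row (top-left origin)
  px <- matrix(as.numeric(vals), nrow = rows, ncol = cols, byrow = TRUE)
  imageRaster(px, id)
}
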