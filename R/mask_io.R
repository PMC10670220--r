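# Mask containers and grayscale image I/O.
#
# All continuous masks live on the 0-255 byte scale with an explicit
# foreground polarity; binary masks are {0,1} integer matrices. The internal
# canonical polarity is foreground_high; polarity is reconciled at the
# boundaries (binarize, fuse), never assumed.

POLARITIES <- c("foreground_high", "foreground_low")

#' Round half away from zero
#'
#' Deterministic rounding used everywhere a real-valued score or coordinate
#' is mapped to an integer (byte rescaling, fusion, prompt coordinates), so
#' examples are exactly reproducible. `round()` in R rounds half to even,
#' which is why this helper exists.
#'
#' @param x Numeric vector/matrix.
#' @return `x` rounded to integers, halves away from zero.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Construct a continuous score mask
#'
#' A `score_mask` holds per-pixel integer scores on the byte scale
#' \eqn{[0, 255]} plus an explicit foreground polarity: `"foreground_high"`
#' means large values denote the object, `"foreground_low"` the opposite
#' convention (used e.g. by segmentators that score the background class).
#'
#' @param scores Numeric matrix with all values integers in `[0, 255]`.
#' @param polarity `"foreground_high"` or `"foreground_low"`. No default:
#'   every mask must declare its convention.
#' @return An object of class `score_mask`: an integer matrix with a
#'   `polarity` attribute.
#' @examples
#' m <- score_mask(matrix(c(0, 255, 128, 64), 2, 2), "foreground_high")
#' mask_polarity(m)
#' @export
score_mask <- function(scores, polarity) {
  polarity <- match.arg(polarity, POLARITIES)
  if (!is.matrix(scores)) stop("`scores` must be a matrix", call. = FALSE)
  if (nrow(scores) < 1L || ncol(scores) < 1L) {
    stop("mask must have at least one pixel", call. = FALSE)
  }
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("scores must be finite", call. = FALSE)
  }
  if (any(scores < 0 | scores > 255) || any(scores != trunc(scores))) {
    stop("scores must be integers in [0, 255]", call. = FALSE)
  }
  storage.mode(scores) <- "integer"
  structure(scores, polarity = polarity, class = "score_mask")
}

#' Construct a binary mask
#'
#' @param labels Numeric or logical matrix; values must be 0/1 (or
#'   FALSE/TRUE). 1 denotes foreground.
#' @return An object of class `binary_mask` (integer matrix).
#' @examples
#' binary_mask(matrix(c(0, 1, 1, 0), 2, 2))
#' @export
binary_mask <- function(labels) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  if (nrow(labels) < 1L || ncol(labels) < 1L) {
    stop("mask must have at least one pixel", call. = FALSE)
  }
  if (is.logical(labels)) labels[] <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  structure(labels, class = "binary_mask")
}

#' @export
print.score_mask <- function(x, ...) {
  cat(sprintf("<score_mask %dx%d, polarity=%s, range=[%d, %d]>\n",
              nrow(x), ncol(x), attr(x, "polarity"), min(x), max(x)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %dx%d, foreground=%d px (%.1f%%)>\n",
              nrow(x), ncol(x), sum(x), 100 * mean(x)))
  invisible(x)
}

#' Polarity of a score mask
#' @param mask A `score_mask`.
#' @return `"foreground_high"` or `"foreground_low"`.
#' @export
mask_polarity <- function(mask) {
  stopifnot(inherits(mask, "score_mask"))
  attr(mask, "polarity")
}

is_binary_mask <- function(x) inherits(x, "binary_mask")
is_score_mask <- function(x) inherits(x, "score_mask")

#' Read a grayscale score mask from disk
#'
#' Reads PNG (canonical, lossless) or JPEG (compatibility; read-only in this
#' package). Multi-channel images are collapsed to gray with the BT.601 luma
#' weights (0.299 R + 0.587 G + 0.114 B); an alpha channel is ignored.
#' Higher bit depths are linearly rescaled so the full scale maps to 255.
#' The caller must declare which polarity convention the file uses.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @param polarity Polarity of the stored mask (see [score_mask()]).
#' @return A [score_mask()].
#' @export
read_mask <- function(path, polarity) {
  polarity <- match.arg(polarity, POLARITIES)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(img) == 0L) stop("zero-sized raster: ", path, call. = FALSE)
  # readPNG/readJPEG normalize any bit depth to [0,1] doubles
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    gray <- if (nc >= 3L) {
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img[, , 1]  # gray + alpha
    }
  } else {
    gray <- img
  }
  scores <- round_half_away(gray * 255)
  score_mask(matrix(scores, nrow(gray), ncol(gray)), polarity)
}

#' Rescale raw real-valued scores to the byte range
#'
#' Linear per-image min-max map: the minimum raw score maps to 0, the
#' maximum to 255, rounding halves away from zero. A constant input carries
#' no foreground information and maps to all zeros by convention.
#'
#' @param raw Numeric matrix of finite raw scores (e.g. logits).
#' @param polarity Polarity to tag the result with (default
#'   `"foreground_high"`, the internal canonical convention).
#' @return A [score_mask()].
#' @examples
#' rescale_to_byte(matrix(c(0, 1, 2, 4), 2, 2, byrow = TRUE))
#' @export
rescale_to_byte <- function(raw, polarity = "foreground_high") {
  if (!is.matrix(raw)) stop("`raw` must be a matrix", call. = FALSE)
  if (length(raw) < 1L) stop("at least one pixel required", call. = FALSE)
  if (anyNA(raw) || any(!is.finite(raw))) {
    stop("raw scores must be finite (no NaN/Inf)", call. = FALSE)
  }
  rng <- range(raw)
  scores <- if (rng[1] == rng[2]) {
    matrix(0L, nrow(raw), ncol(raw))
  } else {
    round_half_away(255 * (raw - rng[1]) / (rng[2] - rng[1]))
  }
  score_mask(matrix(scores, nrow(raw), ncol(raw)), polarity)
}

#' Invert a score mask
#'
#' Maps every score s to 255 - s and flips the polarity tag; used to
#' reconcile segmentators that follow opposite foreground conventions
#' before fusing. Involution: `invert(invert(m))` equals `m`.
#'
#' @param mask A [score_mask()].
#' @return The inverted [score_mask()].
#' @export
invert <- function(mask) {
  stopifnot(is_score_mask(mask))
  pol <- setdiff(POLARITIES, mask_polarity(mask))
  score_mask(matrix(255L - as.integer(mask), nrow(mask), ncol(mask)), pol)
}

#' Threshold a score mask into a binary mask
#'
#' The threshold is interpreted in the mask's *native* convention. A
#' foreground_high mask labels a pixel foreground when score >= threshold.
#' A foreground_low mask is first normalized by inversion and the margin t
#' is mirrored to 256 - t, so that "native score < t" and
#' "inverted score >= 256 - t" classify identical byte values (the half-open
#' complement; 256 rather than 255 keeps the two rules consistent).
#'
#' @param mask A [score_mask()].
#' @param threshold Integer margin in `[0, 255]`. The conventional default
#'   is 128; a stricter margin such as 32 (for foreground_low sources)
#'   restricts prompts to high-confidence regions.
#' @return A [binary_mask()].
#' @export
binarize <- function(mask, threshold = 128) {
  stopifnot(is_score_mask(mask))
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 255 || threshold != trunc(threshold)) {
    stop("threshold must be a single integer in [0, 255]", call. = FALSE)
  }
  if (mask_polarity(mask) == "foreground_low") {
    mask <- invert(mask)
    threshold <- 256 - threshold
  }
  binary_mask(matrix(as.integer(unclass(mask) >= threshold),
                     nrow(mask), ncol(mask)))
}

#' Write a mask to a PNG file
#'
#' Score masks round-trip bit-exactly through [read_mask()]. Binary masks
#' are stored with the conventional {0, 255} byte values.
#'
#' @param mask A [score_mask()] or [binary_mask()].
#' @param path Output path; the parent directory must exist. Only PNG
#'   output is supported (JPEG is lossy and read-only in this package).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!dir.exists(dirname(path))) {
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  }
  if (tolower(tools::file_ext(path)) != "png") {
    stop("write_mask only writes PNG", call. = FALSE)
  }
  bytes <- if (is_binary_mask(mask)) {
    unclass(mask) * 255L
  } else if (is_score_mask(mask)) {
    unclass(mask)
  } else {
    stop("mask must be a score_mask or binary_mask", call. = FALSE)
  }
  png::writePNG(matrix(bytes / 255, nrow(mask), ncol(mask)), target = path)
  invisible(path)
}
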