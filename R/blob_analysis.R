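# Connected-component ("blob") extraction and binary morphology.
#
# Components are 8-connected. Erosion follows the strict structuring-element
# definition: an output pixel is foreground iff the kernel, anchored there,
# fits entirely inside the input foreground; out-of-image pixels count as
# background, so border pixels erode away.

#' Elliptical structuring element
#'
#' Discrete filled ellipse inscribed in an `size[1] x size[2]` box: pixel
#' (r, c) (0-based) belongs to the element iff
#' ((r - (h-1)/2) / (h/2))^2 + ((c - (w-1)/2) / (w/2))^2 <= 1.
#' The default 10 x 10 element is the boundary-avoiding kernel used by the
#' border-mode prompt extraction.
#'
#' @param size Integer vector `c(height, width)`; a single value is used for
#'   both. May also be a string spec like `"ellipse"` via [make_kernel()].
#' @return Logical matrix marking the element's support.
#' @export
elliptical_kernel <- function(size = c(10, 10)) {
  if (length(size) == 1L) size <- c(size, size)
  h <- as.integer(size[1]); w <- as.integer(size[2])
  stopifnot(h >= 1L, w >= 1L)
  r <- matrix(0:(h - 1L), h, w)
  cc <- matrix(0:(w - 1L), h, w, byrow = TRUE)
  ((r - (h - 1) / 2) / (h / 2))^2 + ((cc - (w - 1) / 2) / (w / 2))^2 <= 1
}

#' Build a structuring element from a config-style spec
#'
#' @param shape `"ellipse"` or `"rect"`.
#' @param size `c(height, width)` in pixels.
#' @return Logical matrix.
#' @export
make_kernel <- function(shape = c("ellipse", "rect"), size = c(10, 10)) {
  shape <- match.arg(shape)
  if (length(size) == 1L) size <- c(size, size)
  switch(shape,
    ellipse = elliptical_kernel(size),
    rect = matrix(TRUE, size[1], size[2])
  )
}

# Default anchor for a kernel: (ceiling(h/2)-1, ceiling(w/2)-1), 0-based --
# the common convention for even-sized kernels, which have no center pixel.
kernel_anchor <- function(kernel) {
  c(ceiling(nrow(kernel) / 2) - 1L, ceiling(ncol(kernel) / 2) - 1L)
}

# Shift a logical matrix by (dr, dc), filling exposed cells with `fill`.
shift_matrix <- function(m, dr, dc, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  if (abs(dr) < h && abs(dc) < w) {
    rs <- max(1L, 1L + dr):min(h, h + dr)
    cs <- max(1L, 1L + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
  }
  out
}

#' Morphological erosion of a binary mask
#'
#' Output pixel p is foreground iff every kernel pixel, with the kernel
#' anchored at p, lies on input foreground. The neighborhood outside the
#' image is background, so objects shrink at the image border too. A kernel
#' larger than the image yields an all-background mask (not an error).
#'
#' @param mask A [binary_mask()].
#' @param kernel Logical structuring-element matrix (default the 10 x 10
#'   discrete ellipse from [elliptical_kernel()]).
#' @param anchor 0-based `c(row, col)` anchor inside the kernel; default
#'   `(ceiling(h/2)-1, ceiling(w/2)-1)`, i.e. (4, 4) for the 10 x 10 kernel.
#' @return The eroded [binary_mask()].
#' @export
erode_mask <- function(mask, kernel = elliptical_kernel(), anchor = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(kernel)) stop("kernel must be nonempty", call. = FALSE)
  if (is.null(anchor)) anchor <- kernel_anchor(kernel)
  fg <- unclass(mask) == 1L
  offs <- which(kernel, arr.ind = TRUE) - 1L  # 0-based kernel coords
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offs))) {
    # input pixel probed for output pixel p is p + (off - anchor);
    # equivalently AND with the input shifted by -(off - anchor)
    out <- out & shift_matrix(fg, anchor[1] - offs[i, 1], anchor[2] - offs[i, 2])
    if (!any(out)) break
  }
  binary_mask(matrix(as.integer(out), nrow(mask), ncol(mask)))
}

# Morphological dilation (internal; used by the synthetic boundary jitter).
# Output pixel is foreground iff the reflected kernel anchored there touches
# any input foreground pixel.
dilate_mask <- function(mask, kernel = elliptical_kernel(), anchor = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  if (is.null(anchor)) anchor <- kernel_anchor(kernel)
  fg <- unclass(mask) == 1L
  offs <- which(kernel, arr.ind = TRUE) - 1L
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offs))) {
    out <- out | shift_matrix(fg, offs[i, 1] - anchor[1], offs[i, 2] - anchor[2])
  }
  binary_mask(matrix(as.integer(out), nrow(mask), ncol(mask)))
}

#' Label the connected foreground components of a binary mask
#'
#' Components are 8-connected (diagonal neighbors connect), the common
#' imaging default; it avoids splitting thin diagonal structures. Blobs are
#' returned ordered by (row_min, col_min) of their bounding box, then by
#' area, and re-numbered 1..n in that order so labeling is deterministic.
#'
#' @param mask A [binary_mask()].
#' @return A list of `blob` objects, each with fields `id`, `pixels`
#'   (n x 2 integer matrix of 0-based (row, col) coordinates, in column-major
#'   scan order), `area`, `bbox` (`c(row_min, col_min, row_max, col_max)`,
#'   inclusive, 0-based) and `centroid` (real-valued mean (row, col)).
#'   An empty mask yields an empty list.
#' @export
label_blobs <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  lab <- label_matrix(mask)
  n <- attr(lab, "n_blobs")
  if (n == 0L) return(list())
  lapply(seq_len(n), function(id) {
    idx <- which(lab == id)
    r0 <- (idx - 1L) %% nrow(mask)        # 0-based row
    c0 <- (idx - 1L) %/% nrow(mask)       # 0-based col
    ord <- order(c0, r0)                  # column-major, 0-based
    pixels <- cbind(row = r0[ord], col = c0[ord])
    structure(list(
      id = id,
      pixels = pixels,
      area = nrow(pixels),
      bbox = c(row_min = min(r0), col_min = min(c0),
               row_max = max(r0), col_max = max(c0)),
      centroid = c(row = mean(r0), col = mean(c0))
    ), class = "blob")
  })
}

#' @export
print.blob <- function(x, ...) {
  cat(sprintf("<blob #%d: area=%d, bbox=(%d,%d)-(%d,%d), centroid=(%.2f, %.2f)>\n",
              x$id, x$area, x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4],
              x$centroid[1], x$centroid[2]))
  invisible(x)
}

# Integer label matrix of 8-connected components, labels 1..n ordered by
# (row_min, col_min, area); 0 = background. Attribute "n_blobs" gives n.
# Algorithm: seed each foreground pixel with its own id and iteratively take
# the minimum over the 8-neighborhood until a fixed point; converges in at
# most the largest intra-blob path length, each sweep fully vectorized.
label_matrix <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- unclass(mask) == 1L
  lab <- matrix(0L, h, w)
  if (!any(fg)) return(structure(lab, n_blobs = 0L))
  ids <- matrix(seq_len(h * w), h, w)
  ids[!fg] <- .Machine$integer.max
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  repeat {
    nxt <- ids
    for (k in seq_len(nrow(shifts))) {
      sh <- shift_matrix_int(ids, shifts$dr[k], shifts$dc[k])
      nxt <- pmin(nxt, sh)
    }
    nxt[!fg] <- .Machine$integer.max
    if (identical(nxt, ids)) break
    ids <- nxt
  }
  roots <- ids[fg]
  # order blob labels by bbox (row_min, col_min), then area
  info <- do.call(rbind, lapply(split(which(fg), roots), function(idx) {
    r0 <- (idx - 1L) %% h; c0 <- (idx - 1L) %/% h
    c(min(r0), min(c0), length(idx))
  }))
  ord <- order(info[, 1], info[, 2], info[, 3])
  remap <- stats::setNames(seq_along(ord), rownames(info)[ord])
  lab[fg] <- remap[as.character(roots)]
  structure(lab, n_blobs = length(ord))
}

shift_matrix_int <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(.Machine$integer.max, h, w)
  if (abs(dr) < h && abs(dc) < w) {
    rs <- max(1L, 1L + dr):min(h, h + dr)
    cs <- max(1L, 1L + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
  }
  out
}
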