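# Checkpoint (point-prompt) generation from the blobs of a source mask.
#
# Four strategies, one per the field's common choices:
#   A - bounding-box center of each blob (may fall outside concave blobs),
#   B - pixel centroid, snapped to the nearest blob pixel if it falls outside,
#   C - a uniformly random blob pixel (seeded),
#   D - a regular lattice of step b clipped to the blobs, with an optional
#       boundary-avoiding erosion ("border mode") and a shift fallback that
#       guarantees at least one checkpoint per blob.
# Coordinates are (row, col), 0-based; they serialize as x = col, y = row,
# the convention of point-promptable segmentators.

#' Prompt-generation configuration
#'
#' @param method One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param b Grid step in pixels for method D (default 50, a good average
#'   choice across heterogeneous datasets; smaller b means denser prompts).
#' @param border_mode If `TRUE` (method D), the source mask is eroded with
#'   `erosion_kernel` before the lattice is laid, so prompts keep away from
#'   object boundaries.
#' @param rng_seed Integer seed for method C's random pixel draw.
#' @param erosion_kernel Structuring element for border mode; default the
#'   10 x 10 discrete ellipse.
#' @param rescue_on_empty_erosion If `TRUE` (default) a blob that erosion
#'   removes entirely falls back to its un-eroded pixel set instead of
#'   silently losing its prompt.
#' @return A `prompt_config` list.
#' @export
prompt_config <- function(method = c("D", "A", "B", "C"), b = 50,
                          border_mode = FALSE, rng_seed = 1L,
                          erosion_kernel = elliptical_kernel(),
                          rescue_on_empty_erosion = TRUE) {
  method <- match.arg(method)
  b <- as.integer(b)
  if (method == "D" && b < 1L) stop("grid step b must be >= 1", call. = FALSE)
  structure(list(method = method, b = b, border_mode = isTRUE(border_mode),
                 rng_seed = as.integer(rng_seed),
                 erosion_kernel = erosion_kernel,
                 rescue_on_empty_erosion = isTRUE(rescue_on_empty_erosion)),
            class = "prompt_config")
}

checkpoint_df <- function(row = integer(), col = integer(),
                          blob_id = integer(), method = character()) {
  data.frame(row = as.integer(row), col = as.integer(col),
             blob_id = as.integer(blob_id), method = as.character(method),
             stringsAsFactors = FALSE)
}

#' Method A: bounding-box center
#'
#' The "average coordinates" of the blob, taken as the midpoint of its
#' bounding box, rounded half away from zero. For concave blobs (rings,
#' L-shapes) the point can fall outside the blob; this is the method's
#' documented weakness and the reason methods B-D exist.
#'
#' @param blob A blob from [label_blobs()].
#' @return One-row checkpoint data frame (`row`, `col`, `blob_id`, `method`).
#' @export
method_a <- function(blob) {
  r <- round_half_away((blob$bbox[["row_min"]] + blob$bbox[["row_max"]]) / 2)
  cc <- round_half_away((blob$bbox[["col_min"]] + blob$bbox[["col_max"]]) / 2)
  checkpoint_df(r, cc, blob$id, "A")
}

#' Method B: center of mass, snapped into the blob
#'
#' Rounds the pixel centroid to integer coordinates; if that point is not a
#' blob pixel (hollow or concave blobs), snaps to the nearest blob pixel by
#' Euclidean distance, ties broken by (row, col) order. The returned
#' checkpoint therefore always lies inside the blob.
#'
#' @inheritParams method_a
#' @return One-row checkpoint data frame.
#' @export
method_b <- function(blob) {
  r <- round_half_away(blob$centroid[["row"]])
  cc <- round_half_away(blob$centroid[["col"]])
  px <- blob$pixels
  inside <- any(px[, "row"] == r & px[, "col"] == cc)
  if (!inside) {
    d2 <- (px[, "row"] - blob$centroid[["row"]])^2 +
          (px[, "col"] - blob$centroid[["col"]])^2
    ord <- order(d2, px[, "row"], px[, "col"])
    r <- px[ord[1], "row"]; cc <- px[ord[1], "col"]
  }
  checkpoint_df(r, cc, blob$id, "B")
}

#' Method C: seeded random blob pixel
#'
#' Draws one pixel uniformly from the blob's pixel set with a local,
#' seed-controlled generator; identical (blob, seed) pairs give identical
#' checkpoints and the global RNG state is left untouched.
#'
#' @inheritParams method_a
#' @param rng_seed Integer seed.
#' @return One-row checkpoint data frame.
#' @export
method_c <- function(blob, rng_seed = 1L) {
  i <- with_local_seed(as.integer(rng_seed), sample.int(blob$area, 1L))
  checkpoint_df(blob$pixels[i, "row"], blob$pixels[i, "col"], blob$id, "C")
}

#' Method D: lattice sampling with border mode and shift fallback
#'
#' Lays the global lattice `{(i*b, j*b)}` (anchored at the image origin) and
#' keeps every lattice point that falls inside a blob, giving multiple
#' prompts for large objects. With `border_mode` the mask is first eroded by
#' the configured kernel so prompts avoid boundaries; a blob that erosion
#' removes entirely is rescued to its un-eroded pixel set (if
#' `rescue_on_empty_erosion`). Any blob the lattice misses triggers the
#' fallback: the lattice is shifted one pixel at a time, first horizontally
#' (dx = 1..b-1 at dy = 0), then through the vertical-major sweep
#' (dy = 1..b-1, dx = 0..b-1), stopping at the first shift that intersects
#' that blob. Every nonempty blob therefore contributes at least one
#' checkpoint; results are ordered by (row, col).
#'
#' @param mask A [binary_mask()].
#' @param config A [prompt_config()] (its `method` field is ignored here).
#' @return Checkpoint data frame, possibly zero rows.
#' @export
method_d <- function(mask, config = prompt_config("D")) {
  b <- config$b
  if (b < 1L) stop("grid step b must be >= 1", call. = FALSE)
  work <- mask
  if (config$border_mode) {
    eroded <- erode_mask(mask, config$erosion_kernel)
    if (config$rescue_on_empty_erosion) {
      keep <- unclass(eroded) == 1L
      for (blob in label_blobs(mask)) {
        idx <- blob$pixels[, "row"] + 1L + blob$pixels[, "col"] * nrow(mask)
        if (!any(keep[idx])) keep[idx] <- TRUE  # rescue vanished blob
      }
      work <- binary_mask(matrix(as.integer(keep), nrow(mask), ncol(mask)))
    } else {
      work <- eroded
    }
  }
  blobs <- label_blobs(work)
  if (length(blobs) == 0L) return(checkpoint_df())
  lab <- label_matrix(work)
  out <- checkpoint_df()
  for (blob in blobs) {
    pts <- lattice_hits(lab, blob$id, nrow(mask), ncol(mask), b, 0L, 0L)
    if (nrow(pts) == 0L) {
      for (off in fallback_offsets(b)) {
        pts <- lattice_hits(lab, blob$id, nrow(mask), ncol(mask), b,
                            off[1], off[2])
        if (nrow(pts) > 0L) break
      }
    }
    if (nrow(pts) > 0L) {
      out <- rbind(out, checkpoint_df(pts[, 1], pts[, 2], blob$id, "D"))
    }
  }
  out <- out[order(out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Lattice points (i*b + dy, j*b + dx) inside the image that land on `id`.
lattice_hits <- function(lab, id, h, w, b, dy, dx) {
  if (dy > h - 1L || dx > w - 1L) {
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  }
  rows <- seq.int(dy, h - 1L, by = b)
  cols <- seq.int(dx, w - 1L, by = b)
  g <- expand.grid(row = rows, col = cols)
  hit <- lab[cbind(g$row + 1L, g$col + 1L)] == id
  as.matrix(g[hit, , drop = FALSE])
}

# Fallback enumeration: horizontal shifts first, then the vertical-major
# sweep; 1-pixel steps guarantee every residue class (hence every blob) is
# eventually covered.
fallback_offsets <- function(b) {
  offs <- list()
  if (b > 1L) {
    for (dx in 1:(b - 1L)) offs[[length(offs) + 1L]] <- c(0L, dx)
    for (dy in 1:(b - 1L)) {
      for (dx in 0:(b - 1L)) offs[[length(offs) + 1L]] <- c(dy, dx)
    }
  }
  offs
}

#' Extract a prompt set from a source mask
#'
#' Dispatches to the configured method: A/B/C yield one checkpoint per blob
#' of [label_blobs()]; D delegates to [method_d()]. The source mask may be a
#' ground-truth mask (the "oracle" protocol, which upper-bounds achievable
#' performance) or a binarized segmentator output — the code path is
#' identical, only the source differs.
#'
#' @param mask A [binary_mask()].
#' @param config A [prompt_config()].
#' @return A `prompt_set`: list with `checkpoints` (data frame) and `config`.
#' @export
extract_prompts <- function(mask, config = prompt_config()) {
  stopifnot(inherits(mask, "binary_mask"), inherits(config, "prompt_config"))
  cps <- switch(config$method,
    A = per_blob(mask, method_a),
    B = per_blob(mask, method_b),
    C = per_blob(mask, function(blob) {
      # one independent, reproducible stream per blob
      method_c(blob, config$rng_seed + blob$id)
    }),
    D = method_d(mask, config),
    stop("unknown method: ", config$method, call. = FALSE)
  )
  structure(list(checkpoints = cps, config = config), class = "prompt_set")
}

per_blob <- function(mask, f) {
  rows <- lapply(label_blobs(mask), f)
  if (length(rows) == 0L) return(checkpoint_df())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.prompt_set <- function(x, ...) {
  cat(sprintf("<prompt_set: method %s, %d checkpoint(s), %d blob(s)>\n",
              x$config$method, nrow(x$checkpoints),
              length(unique(x$checkpoints$blob_id))))
  invisible(x)
}

#' Serialize a prompt set to JSON
#'
#' Checkpoints are exported with `x = col`, `y = row` (0-based), the
#' coordinate convention of point-promptable segmentators, together with the
#' generating method and parameters so runs are reproducible.
#'
#' @param prompts A `prompt_set` from [extract_prompts()].
#' @param path Output path; if `NULL`, the JSON string is returned.
#' @return `path` (or the JSON string), invisibly.
#' @export
write_prompts <- function(prompts, path = NULL) {
  stopifnot(inherits(prompts, "prompt_set"))
  cps <- prompts$checkpoints
  obj <- list(
    method = prompts$config$method,
    b = prompts$config$b,
    border_mode = prompts$config$border_mode,
    rng_seed = prompts$config$rng_seed,
    checkpoints = data.frame(x = cps$col, y = cps$row, blob_id = cps$blob_id,
                             method = cps$method, stringsAsFactors = FALSE)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}

#' Read a prompt set from JSON
#' @param path Path written by [write_prompts()].
#' @return A `prompt_set`.
#' @export
read_prompts <- function(path) {
  obj <- jsonlite::fromJSON(path)
  cps <- if (length(obj$checkpoints) == 0L) checkpoint_df() else {
    checkpoint_df(obj$checkpoints$y, obj$checkpoints$x,
                  obj$checkpoints$blob_id, obj$checkpoints$method)
  }
  cfg <- prompt_config(obj$method, b = obj$b, border_mode = obj$border_mode,
                       rng_seed = obj$rng_seed)
  structure(list(checkpoints = cps, config = cfg), class = "prompt_set")
}

# Run `expr` under a temporary RNG seed, restoring global state afterwards.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
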