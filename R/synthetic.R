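# Synthetic ground truth, a controllable degradation model, and a mock
# promptable backend, so the full prompt -> segment -> fuse -> evaluate
# pipeline is testable without model weights or external data.
#
# Defaults emulate a modest multi-object scene: a 128 x 128 frame with 3
# well-separated elliptical objects of radius 8-15 px — large enough that a
# grid of step 8 always samples every object, small enough that everything
# runs in milliseconds.

#' Specification for a synthetic ground-truth mask
#'
#' @param height,width Image size in pixels (default 128 x 128).
#' @param n_blobs Number of disjoint foreground objects (default 3).
#' @param blob_radius_range `c(min, max)` object radius in pixels (default
#'   8-15; "radius" is the maximum semi-axis).
#' @param min_separation Minimum gap in pixels between any two objects
#'   (default 4, so objects are never 8-adjacent and the component count is
#'   verifiable by [label_blobs()]).
#' @param shape_family `"ellipse"` (rotated ellipses) or `"blobby_polygon"`
#'   (star-convex shapes with a low-frequency radial perturbation).
#' @param rng_seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(height = 128, width = 128, n_blobs = 3,
                           blob_radius_range = c(8, 15), min_separation = 4,
                           shape_family = c("ellipse", "blobby_polygon"),
                           rng_seed = 1L) {
  shape_family <- match.arg(shape_family)
  stopifnot(height >= 1, width >= 1, n_blobs >= 0,
            blob_radius_range[1] >= 1,
            blob_radius_range[2] >= blob_radius_range[1],
            min_separation >= 1)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_blobs = as.integer(n_blobs),
                 blob_radius_range = blob_radius_range,
                 min_separation = min_separation,
                 shape_family = shape_family,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic ground-truth mask
#'
#' Places `n_blobs` shapes by rejection sampling: centers are redrawn until
#' every pair of objects is at least `min_separation` pixels apart (measured
#' between bounding circles). Guaranteed component count: `label_blobs()`
#' on the result returns exactly `n_blobs` blobs.
#'
#' @param spec A [synthetic_spec()].
#' @return A [binary_mask()].
#' @export
generate_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$rng_seed, generate_gt_impl(spec))
}

generate_gt_impl <- function(spec) {
  h <- spec$height; w <- spec$width
  mask <- matrix(0L, h, w)
  if (spec$n_blobs == 0L) return(binary_mask(mask))
  rmin <- spec$blob_radius_range[1]; rmax <- spec$blob_radius_range[2]
  placed <- matrix(numeric(0), 0, 3)  # (row, col, bounding radius)
  budget <- 400L * spec$n_blobs
  tries <- 0L
  while (nrow(placed) < spec$n_blobs) {
    tries <- tries + 1L
    if (tries > budget) {
      stop("could not place ", spec$n_blobs, " blobs of radius ",
           rmin, "-", rmax, " in a ", h, "x", w,
           " frame; reduce n_blobs or the radii", call. = FALSE)
    }
    r <- stats::runif(1, rmin, rmax)
    cr <- stats::runif(1, r + 1, h - r - 2)
    cc <- stats::runif(1, r + 1, w - r - 2)
    if (nrow(placed) > 0L) {
      d <- sqrt((placed[, 1] - cr)^2 + (placed[, 2] - cc)^2)
      if (any(d < placed[, 3] + r + spec$min_separation)) next
    }
    blob <- rasterize_shape(h, w, cr, cc, r, spec$shape_family)
    if (!any(blob)) next
    mask[blob] <- 1L
    placed <- rbind(placed, c(cr, cc, r))
  }
  binary_mask(mask)
}

# Rasterize one shape with bounding radius r centered at (cr, cc), 1-based
# fractional coordinates; returns a logical matrix. Uses the current RNG
# stream for shape parameters.
rasterize_shape <- function(h, w, cr, cc, r, family) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dr <- rows - cr; dc <- cols - cc
  if (family == "ellipse") {
    a <- r                                   # major semi-axis
    b <- stats::runif(1, 0.6 * r, r)         # minor semi-axis
    th <- stats::runif(1, 0, pi)
    u <- dr * cos(th) + dc * sin(th)
    v <- -dr * sin(th) + dc * cos(th)
    (u / a)^2 + (v / b)^2 <= 1
  } else {
    # star-convex blob: radius modulated by low-frequency harmonics,
    # clamped to [0.5 r, r] so the shape stays connected and inside the
    # bounding circle used for the separation check
    amp <- stats::runif(3, 0, 0.25)
    ph <- stats::runif(3, 0, 2 * pi)
    ang <- atan2(dc, dr)
    mod <- 1 + amp[1] * cos(2 * ang + ph[1]) + amp[2] * cos(3 * ang + ph[2]) +
      amp[3] * cos(4 * ang + ph[3])
    rad <- pmin(pmax(0.75 * r * mod, 0.5 * r), r)
    sqrt(dr^2 + dc^2) <= rad
  }
}

#' Specification of segmentator-output degradation
#'
#' Emulates the failure modes of an imperfect conventional segmentator:
#' noisy boundaries (random dilation/erosion), missed objects (blob drops),
#' spurious regions (false blobs) and per-pixel score noise.
#'
#' @param score_noise_sd Standard deviation of additive Gaussian score noise
#'   on the byte scale (0 = none).
#' @param boundary_jitter Maximum magnitude, in pixels, of a random whole-mask
#'   dilation (positive draw) or erosion (negative draw); the shift is drawn
#'   uniformly from `-boundary_jitter..boundary_jitter`.
#' @param false_blob_rate Expected number (Poisson) of spurious small blobs.
#' @param drop_blob_prob Probability that each true blob is dropped.
#' @param rng_seed Integer seed.
#' @return A `degradation_spec` list.
#' @export
degradation_spec <- function(score_noise_sd = 0, boundary_jitter = 0,
                             false_blob_rate = 0, drop_blob_prob = 0,
                             rng_seed = 1L) {
  stopifnot(score_noise_sd >= 0, boundary_jitter >= 0, false_blob_rate >= 0,
            drop_blob_prob >= 0, drop_blob_prob <= 1)
  structure(list(score_noise_sd = score_noise_sd,
                 boundary_jitter = as.integer(boundary_jitter),
                 false_blob_rate = false_blob_rate,
                 drop_blob_prob = drop_blob_prob,
                 rng_seed = as.integer(rng_seed)),
            class = "degradation_spec")
}

#' Degrade a ground-truth mask into a noisy "segmentator" score mask
#'
#' Applies, in order: blob drops, whole-mask boundary jitter, spurious blob
#' insertion, conversion to {0, 255} scores, and clipped Gaussian score
#' noise. With an all-zero spec the output binarizes back to the input
#' exactly. Polarity of the output is foreground_high.
#'
#' @param gt A [binary_mask()].
#' @param spec A [degradation_spec()].
#' @return A [score_mask()].
#' @export
degrade <- function(gt, spec = degradation_spec()) {
  stopifnot(inherits(gt, "binary_mask"), inherits(spec, "degradation_spec"))
  with_local_seed(spec$rng_seed, degrade_impl(gt, spec))
}

degrade_impl <- function(gt, spec) {
  h <- nrow(gt); w <- ncol(gt)
  m <- gt
  if (spec$drop_blob_prob > 0) {
    keep <- unclass(m) == 1L
    for (blob in label_blobs(m)) {
      if (stats::runif(1) < spec$drop_blob_prob) {
        keep[blob$pixels[, "row"] + 1L + blob$pixels[, "col"] * h] <- FALSE
      }
    }
    m <- binary_mask(matrix(as.integer(keep), h, w))
  }
  if (spec$boundary_jitter > 0) {
    k <- sample.int(2L * spec$boundary_jitter + 1L, 1L) -
      spec$boundary_jitter - 1L
    if (k > 0L) {
      m <- dilate_mask(m, elliptical_kernel(2L * k + 1L))
    } else if (k < 0L) {
      m <- erode_mask(m, elliptical_kernel(2L * abs(k) + 1L))
    }
  }
  if (spec$false_blob_rate > 0) {
    n_false <- stats::rpois(1, spec$false_blob_rate)
    add <- unclass(m) == 1L
    for (i in seq_len(n_false)) {
      r <- stats::runif(1, 2, 6)
      cr <- stats::runif(1, r + 1, h - r)
      cc <- stats::runif(1, r + 1, w - r)
      add <- add | rasterize_shape(h, w, cr, cc, r, "ellipse")
    }
    m <- binary_mask(matrix(as.integer(add), h, w))
  }
  scores <- unclass(m) * 255
  if (spec$score_noise_sd > 0) {
    scores <- scores + stats::rnorm(h * w, 0, spec$score_noise_sd)
  }
  scores <- round_half_away(pmin(pmax(scores, 0), 255))
  score_mask(matrix(scores, h, w), "foreground_high")
}

#' Mock promptable backend
#'
#' Returns a backend function emulating a point-promptable zero-shot
#' segmentator against a known scene: a prompt landing inside a ground-truth
#' blob "selects" that whole object (the way promptable segmentators expand
#' a point into an object); prompts on background contribute nothing. The
#' union of selected objects is rendered as {0, 255} scores and perturbed
#' with clipped Gaussian noise of standard deviation `(1 - fidelity) * 255`,
#' so `fidelity = 1` is a perfect oracle and lower values degrade smoothly.
#' The backend is a pure function: identical prompt sets give bit-identical
#' masks.
#'
#' @param gt The scene's ground-truth [binary_mask()].
#' @param fidelity Output quality in `[0, 1]`.
#' @param rng_seed Integer seed for the noise (fixed per backend, so calls
#'   are reproducible).
#' @return A function `(image, prompts) -> score_mask` (foreground_high);
#'   `image` is an opaque pass-through payload and may be `NULL`, `prompts`
#'   is a `prompt_set` or checkpoint data frame.
#' @export
mock_backend <- function(gt, fidelity = 1, rng_seed = 1L) {
  stopifnot(inherits(gt, "binary_mask"), fidelity >= 0, fidelity <= 1)
  force(gt); force(fidelity); rng_seed <- as.integer(rng_seed)
  lab <- label_matrix(gt)
  function(image, prompts) {
    cps <- if (inherits(prompts, "prompt_set")) prompts$checkpoints else prompts
    h <- nrow(gt); w <- ncol(gt)
    sel <- matrix(FALSE, h, w)
    if (!is.null(cps) && nrow(cps) > 0L) {
      inb <- cps$row >= 0L & cps$row < h & cps$col >= 0L & cps$col < w
      ids <- unique(lab[cbind(cps$row[inb] + 1L, cps$col[inb] + 1L)])
      ids <- ids[ids > 0L]
      if (length(ids) > 0L) sel <- matrix(lab %in% ids, h, w)
    }
    scores <- sel * 255
    if (fidelity < 1) {
      noise <- with_local_seed(rng_seed,
                               stats::rnorm(h * w, 0, (1 - fidelity) * 255))
      scores <- scores + noise
    }
    scores <- round_half_away(pmin(pmax(scores, 0), 255))
    score_mask(matrix(scores, h, w), "foreground_high")
  }
}

#' Write a synthetic fixture set to disk
#'
#' Dumps `n_images` scenes as `gt_<i>.png` (ground truth) and
#' `source_<i>.png` (degraded score mask) under `dir`, plus a
#' `manifest.csv` mapping image ids to paths — the layout consumed by
#' [run_pipeline()].
#'
#' @param dir Output directory (created if missing).
#' @param n_images Number of scenes.
#' @param spec A [synthetic_spec()]; its `rng_seed` seeds scene `i` as
#'   `rng_seed + i`.
#' @param degradation A [degradation_spec()]; seeded the same way.
#' @return Path to the manifest CSV, invisibly.
#' @export
write_fixture_set <- function(dir, n_images, spec = synthetic_spec(),
                              degradation = degradation_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sp <- spec; sp$rng_seed <- spec$rng_seed + i
    dg <- degradation; dg$rng_seed <- degradation$rng_seed + i
    gt <- generate_ground_truth(sp)
    src <- degrade(gt, dg)
    gt_path <- file.path(dir, sprintf("gt_%03d.png", i))
    src_path <- file.path(dir, sprintf("source_%03d.png", i))
    write_mask(gt, gt_path)
    write_mask(src, src_path)
    rows[[i]] <- data.frame(image_id = sprintf("img_%03d", i),
                            source = src_path, gt = gt_path,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
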