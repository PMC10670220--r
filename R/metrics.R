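# Binary segmentation evaluation: IoU, Dice, MAE, weighted F-measure and
# enhanced-alignment E-measure, plus dataset aggregation.
#
# All metrics take binary masks; continuous masks must be binarized first
# (scores are reported on thresholded outputs). Empty-empty pairs count as a
# perfect prediction of absence: IoU = Dice = 1, MAE = 0.

check_pair <- function(P, T) {
  stopifnot(inherits(P, "binary_mask"), inherits(T, "binary_mask"))
  if (!identical(dim(P), dim(T))) {
    stop("mask shapes differ: ", paste(dim(P), collapse = "x"), " vs ",
         paste(dim(T), collapse = "x"), call. = FALSE)
  }
}

#' Intersection over union
#'
#' `|P intersect T| / |P union T|`, counted in pixels; 1 is a pixel-perfect
#' prediction. Both masks empty also gives 1.
#'
#' @param P Predicted [binary_mask()].
#' @param T Ground-truth [binary_mask()].
#' @return Ratio in `[0, 1]`.
#' @export
iou <- function(P, T) {
  check_pair(P, T)
  p <- unclass(P) == 1L; t <- unclass(T) == 1L
  u <- sum(p | t)
  if (u == 0L) return(1)
  sum(p & t) / u
}

#' Dice similarity coefficient
#'
#' `2|P intersect T| / (|P| + |T|)`; equals `2*IoU / (1 + IoU)` exactly.
#' Both masks empty gives 1.
#'
#' @inheritParams iou
#' @return Ratio in `[0, 1]`.
#' @export
dice <- function(P, T) {
  check_pair(P, T)
  p <- unclass(P) == 1L; t <- unclass(T) == 1L
  denom <- sum(p) + sum(t)
  if (denom == 0L) return(1)
  2 * sum(p & t) / denom
}

#' Mean absolute error
#'
#' Mean over pixels of `|P_i - T_i|` with masks in {0,1}: the fraction of
#' mismatched pixels, i.e. 1 minus pixel accuracy. Lower is better.
#'
#' @inheritParams iou
#' @return Ratio in `[0, 1]`.
#' @export
mae <- function(P, T) {
  check_pair(P, T)
  mean(abs(unclass(P) - unclass(T)))
}

#' Weighted F-measure for foreground maps
#'
#' The spatially weighted precision/recall F-score of Margolin, Zelnik-Manor
#' and Tal's foreground-map evaluation: the per-pixel error is (i) propagated
#' from each background pixel to its nearest ground-truth pixel, (ii)
#' smoothed with a 7 x 7 Gaussian (sigma = 5), capped on ground truth by the
#' raw error, and (iii) down-weighted away from the object by
#' `2 - exp(log(0.5)/5 * d)` where d is the Euclidean distance to the ground
#' truth. Weighted TP/FP then give precision and recall, combined with
#' beta^2 = 1. Errors near the true object therefore cost more than the same
#' errors far away.
#'
#' Nearest-ground-truth ties are resolved to the smallest column-major linear
#' index (the convention of the reference formulation's distance transform).
#'
#' @inheritParams iou
#' @return Score in `[0, 1]`. Empty ground truth: 1 if the prediction is
#'   also empty, else 0.
#' @export
weighted_fmeasure <- function(P, T) {
  check_pair(P, T)
  gt <- unclass(T) == 1L
  pd <- unclass(P)
  if (!any(gt)) return(if (any(pd == 1L)) 0 else 1)
  eps <- .Machine$double.eps
  E <- abs(pd - unclass(T))
  Et <- E
  D <- matrix(0, nrow(T), ncol(T))
  if (any(!gt)) {
    nn <- nearest_foreground(gt)
    Et[!gt] <- E[nn$index[!gt]]
    D[!gt] <- nn$dist[!gt]
  }
  K <- gaussian_kernel(7L, 5)
  EA <- conv2_zero(Et, K)
  MIN_E_EA <- E
  sel <- gt & (EA < E)
  MIN_E_EA[sel] <- EA[sel]
  B <- matrix(1, nrow(T), ncol(T))
  B[!gt] <- 2 - exp(log(0.5) / 5 * D[!gt])
  Ew <- MIN_E_EA * B
  TPw <- sum(gt) - sum(Ew[gt])
  FPw <- sum(Ew[!gt])
  R <- 1 - mean(Ew[gt])
  Pw <- TPw / (eps + TPw + FPw)
  Q <- 2 * R * Pw / (eps + R + Pw)
  max(0, min(1, Q))
}

#' Enhanced-alignment measure (E-measure)
#'
#' The enhanced-alignment measure of Fan et al.: both masks are mean
#' centered, the per-pixel alignment `2 * gc * pc / (gc^2 + pc^2)` is mapped
#' through `((align + 1)^2) / 4`, and the result is averaged over pixels, so
#' the score combines local pixel matching with image-level statistics.
#' Degenerate ground truths follow the reference formulation: all-background
#' scores `mean(1 - P)`, all-foreground scores `mean(P)`. The average is
#' taken over all pixels (rather than pixels minus one) so that a perfect
#' prediction scores exactly 1 and the measure stays in `[0, 1]`.
#'
#' @inheritParams iou
#' @return Score in `[0, 1]`.
#' @export
emeasure <- function(P, T) {
  check_pair(P, T)
  p <- as.numeric(unclass(P)); t <- as.numeric(unclass(T))
  n_fg <- sum(t)
  enhanced <- if (n_fg == 0) {
    1 - p
  } else if (n_fg == length(t)) {
    p
  } else {
    gc <- t - mean(t); pc <- p - mean(p)
    # gc is never 0 for a mixed ground truth, so the denominator is positive
    align <- 2 * gc * pc / (gc^2 + pc^2)
    (align + 1)^2 / 4
  }
  mean(enhanced)
}

#' Evaluate a list of prediction/ground-truth pairs
#'
#' Computes the five metrics per image and their unweighted arithmetic means
#' over images. Pairs that fail validation (shape mismatch, wrong type) are
#' recorded as row-level errors, excluded from the aggregates and counted.
#'
#' @param pairs List of `list(P = , T = , image_id = )` entries.
#' @return A `metric_report`: list with `per_image` (data frame with columns
#'   image_id, iou, dice, mae, wfm, emeasure), `aggregate` (named column
#'   means), `n_images`, `n_errors` and `errors` (data frame of image_id +
#'   message).
#' @export
evaluate_pairs <- function(pairs) {
  if (length(pairs) == 0L) stop("no pairs to evaluate", call. = FALSE)
  rows <- list(); errs <- list()
  for (pr in pairs) {
    id <- if (is.null(pr$image_id)) NA_character_ else as.character(pr$image_id)
    res <- tryCatch(
      data.frame(image_id = id,
                 iou = iou(pr$P, pr$T), dice = dice(pr$P, pr$T),
                 mae = mae(pr$P, pr$T), wfm = weighted_fmeasure(pr$P, pr$T),
                 emeasure = emeasure(pr$P, pr$T),
                 stringsAsFactors = FALSE),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(image_id = id,
                                              message = conditionMessage(res),
                                              stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  per_image <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(), iou = numeric(), dice = numeric(),
               mae = numeric(), wfm = numeric(), emeasure = numeric(),
               stringsAsFactors = FALSE)
  metric_cols <- c("iou", "dice", "mae", "wfm", "emeasure")
  aggregate <- if (nrow(per_image)) colMeans(per_image[metric_cols]) else
    stats::setNames(rep(NA_real_, 5), metric_cols)
  structure(list(per_image = per_image, aggregate = aggregate,
                 n_images = nrow(per_image), n_errors = length(errs),
                 errors = if (length(errs)) do.call(rbind, errs) else NULL),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report: %d image(s), %d error(s)>\n",
              x$n_images, x$n_errors))
  print(round(x$aggregate, 4))
  invisible(x)
}

#' Write a metric report to CSV (and optionally JSON)
#'
#' The CSV holds the per-image rows followed by an `aggregate` footer row.
#'
#' @param report A `metric_report`.
#' @param csv_path Output CSV path.
#' @param json_path Optional JSON path for the full report.
#' @return `csv_path`, invisibly.
#' @export
write_metric_report <- function(report, csv_path, json_path = NULL) {
  stopifnot(inherits(report, "metric_report"))
  footer <- data.frame(image_id = "aggregate",
                       iou = report$aggregate[["iou"]],
                       dice = report$aggregate[["dice"]],
                       mae = report$aggregate[["mae"]],
                       wfm = report$aggregate[["wfm"]],
                       emeasure = report$aggregate[["emeasure"]],
                       stringsAsFactors = FALSE)
  utils::write.csv(rbind(report$per_image, footer), csv_path,
                   row.names = FALSE)
  if (!is.null(json_path)) {
    writeLines(jsonlite::toJSON(list(per_image = report$per_image,
                                     aggregate = as.list(report$aggregate),
                                     n_images = report$n_images,
                                     n_errors = report$n_errors),
                                auto_unbox = TRUE, digits = NA),
               json_path)
  }
  invisible(csv_path)
}

# --- numeric helpers ------------------------------------------------------

# Exact Euclidean distance (and nearest-pixel linear index) from every pixel
# to the foreground of a logical matrix. Vectorized over chunks of query
# pixels to bound memory; ties go to the smallest column-major index.
nearest_foreground <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  fi <- which(fg)                       # column-major, ascending
  fr <- (fi - 1L) %% h; fc <- (fi - 1L) %/% h
  dist <- matrix(0, h, w)
  index <- matrix(0L, h, w)
  index[fg] <- which(fg)
  qi <- which(!fg)
  if (length(qi) == 0L) return(list(dist = dist, index = index))
  qr <- (qi - 1L) %% h; qc <- (qi - 1L) %/% h
  chunk <- max(1L, floor(4e6 / length(fi)))
  for (s in seq(1L, length(qi), by = chunk)) {
    e <- min(s + chunk - 1L, length(qi))
    d2 <- outer(qr[s:e], fr, "-")^2 + outer(qc[s:e], fc, "-")^2
    best <- max.col(-d2, ties.method = "first")
    sel <- qi[s:e]
    dist[sel] <- sqrt(d2[cbind(seq_len(e - s + 1L), best)])
    index[sel] <- fi[best]
  }
  list(dist = dist, index = index)
}

# Normalized 2D Gaussian kernel (size x size, given sigma).
gaussian_kernel <- function(size = 7L, sigma = 5) {
  half <- (size - 1) / 2
  x <- seq(-half, half)
  g <- exp(-(x^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# 2D correlation with zero padding ("same" size), via shift-accumulate.
conv2_zero <- function(x, k) {
  kh <- nrow(k); kw <- ncol(k)
  ar <- (kh - 1L) %/% 2L; ac <- (kw - 1L) %/% 2L
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      if (k[i, j] == 0) next
      out <- out + k[i, j] * shift_num(x, ar - (i - 1L), ac - (j - 1L))
    }
  }
  out
}

shift_num <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  if (abs(dr) < h && abs(dc) < w) {
    rs <- max(1L, 1L + dr):min(h, h + dr)
    cs <- max(1L, 1L + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
  }
  out
}
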