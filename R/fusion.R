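# Weighted late fusion of two continuous score masks.
#
# Both masks are first normalized to the foreground_high convention (the
# promptable segmentator's native output is typically the opposite of a
# conventional segmentator's, so one of them gets inverted), then combined
# per pixel as a weighted average normalized by the weight sum — keeping the
# fused mask on the 0-255 scale so a single fixed threshold stays meaningful
# regardless of the weights — and finally thresholded.

#' Fusion configuration
#'
#' @param seg_weight Weight of the conventional segmentator's mask
#'   (default 2: the segmentator, trained on the target task, gets twice the
#'   say of the zero-shot model).
#' @param zs_weight Weight of the promptable (zero-shot) segmentator's mask
#'   (default 1).
#' @param threshold Byte threshold applied to the fused mask (default 128;
#'   foreground wins ties at exactly the threshold).
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(seg_weight = 2, zs_weight = 1, threshold = 128) {
  if (seg_weight < 0 || zs_weight < 0 || seg_weight + zs_weight <= 0) {
    stop("weights must be nonnegative with a positive sum", call. = FALSE)
  }
  if (threshold < 0 || threshold > 255) {
    stop("threshold must be in [0, 255]", call. = FALSE)
  }
  structure(list(seg_weight = seg_weight, zs_weight = zs_weight,
                 threshold = as.integer(threshold)),
            class = "fusion_config")
}

#' Fuse two score masks with the weighted rule
#'
#' Per pixel, `fused = (w_seg * s_seg + w_zs * s_zs) / (w_seg + w_zs)`,
#' rounded half away from zero, after both inputs are normalized to
#' foreground_high. The binary output is `fused >= threshold`.
#'
#' @param seg [score_mask()] of the conventional segmentator.
#' @param zs [score_mask()] of the promptable segmentator.
#' @param config A [fusion_config()].
#' @return List with `score` (fused [score_mask()], foreground_high) and
#'   `binary` (its thresholded [binary_mask()]).
#' @examples
#' seg <- score_mask(matrix(c(255L, 0L), 1, 2), "foreground_high")
#' zs <- score_mask(matrix(c(0L, 0L), 1, 2), "foreground_high")
#' fuse(seg, zs)$score  # (2*255 + 0)/3 = 170 at pixel 1
#' @export
fuse <- function(seg, zs, config = fusion_config()) {
  stopifnot(inherits(seg, "score_mask"), inherits(zs, "score_mask"),
            inherits(config, "fusion_config"))
  if (!identical(dim(seg), dim(zs))) {
    stop("mask shapes differ: ", paste(dim(seg), collapse = "x"), " vs ",
         paste(dim(zs), collapse = "x"), call. = FALSE)
  }
  if (mask_polarity(seg) == "foreground_low") seg <- invert(seg)
  if (mask_polarity(zs) == "foreground_low") zs <- invert(zs)
  w <- config$seg_weight + config$zs_weight
  fused <- round_half_away(
    (config$seg_weight * unclass(seg) + config$zs_weight * unclass(zs)) / w
  )
  score <- score_mask(matrix(fused, nrow(seg), ncol(seg)), "foreground_high")
  list(score = score, binary = binarize(score, config$threshold))
}

#' Fuse two masks stored on disk
#'
#' Reads both masks, fuses them, and writes `<out_prefix>_fused.png` (the
#' continuous mask), `<out_prefix>_binary.png`, and a JSON provenance
#' sidecar `<out_prefix>_provenance.json` recording weights, threshold and
#' input polarities. Nothing is written if the inputs are incompatible.
#'
#' @param seg_path,zs_path Input mask image paths.
#' @param seg_polarity,zs_polarity Polarity of each input file.
#' @param config A [fusion_config()].
#' @param out_prefix Output path prefix (parent directory must exist).
#' @return Named character vector of the three output paths, invisibly.
#' @export
fuse_files <- function(seg_path, zs_path, seg_polarity, zs_polarity,
                       config = fusion_config(), out_prefix) {
  seg <- read_mask(seg_path, seg_polarity)
  zs <- read_mask(zs_path, zs_polarity)
  res <- fuse(seg, zs, config)  # validates shapes before any write
  paths <- c(fused = paste0(out_prefix, "_fused.png"),
             binary = paste0(out_prefix, "_binary.png"),
             provenance = paste0(out_prefix, "_provenance.json"))
  write_mask(res$score, paths[["fused"]])
  write_mask(res$binary, paths[["binary"]])
  sidecar <- list(seg_path = seg_path, zs_path = zs_path,
                  seg_polarity = seg_polarity, zs_polarity = zs_polarity,
                  seg_weight = config$seg_weight, zs_weight = config$zs_weight,
                  threshold = config$threshold)
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, digits = NA),
             paths[["provenance"]])
  invisible(paths)
}
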