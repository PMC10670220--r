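Package: promptfuse
Title: Point-Prompt Engineering and Logit-Mask Fusion for Promptable Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for improving a conventional image segmentator with a
    promptable ("segment anything" style) zero-shot segmentator. Generates
    point prompts (checkpoints) from the connected components of a source
    segmentation mask using bounding-box-center, centroid, random-point and
    grid sampling strategies, with optional boundary-avoiding mask erosion
    and a shift-based fallback that guarantees every blob receives a prompt.
    Fuses the continuous score masks of the two segmentators with a weighted
    average on the 0-255 byte scale followed by thresholding, and evaluates
    binary segmentations with IoU, Dice, mean absolute error, the weighted
    F-measure and the enhanced-alignment E-measure. A synthetic mask
    generator, a controllable degradation model and a mock promptable
    backend make the full pipeline testable without model weights or
    external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    jpeg,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
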