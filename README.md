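# promptfuse

Improve a conventional image segmentator with a point-promptable zero-shot
segmentator ("segment anything"-style), without retraining anything.

Conventional segmentators produce a continuous score mask for a target class
but stumble on unfamiliar objects; promptable zero-shot models segment almost
anything but need to be told where to look. promptfuse implements the bridge:

1. **Checkpoint engineering** — turn the connected components ("blobs") of a
   source mask into point prompts. Four methods: bounding-box center (A),
   centroid snapped into the blob (B), seeded random blob pixel (C), and a
   grid of step *b* (D) with an optional boundary-avoiding erosion ("border
   mode", 10×10 elliptical kernel) and a shift fallback that guarantees every
   blob at least one prompt.
2. **Weighted logit-mask fusion** — after reconciling foreground polarity,
   combine the two score masks per pixel as
   `round((w_seg·s_seg + w_zs·s_zs) / (w_seg + w_zs))` on the 0–255 scale
   (defaults `w_seg = 2`, `w_zs = 1`), then threshold at 128 to get the final
   binary mask.
3. **Evaluation** — IoU, Dice, MAE, the weighted F-measure (spatially
   weighted errors, β² = 1, Gaussian 7×7 σ = 5) and the enhanced-alignment
   E-measure, per image and averaged over datasets.

A synthetic scene generator, a controllable degradation model and a mock
promptable backend make the full pipeline runnable and testable on a laptop:
no model weights, no datasets, no GPU. Extracting prompts from the ground
truth instead of a segmentator output gives the *oracle protocol*, an upper
bound on what prompting can achieve.

## Worked example

A synthetic scene, a noisy "segmentator" mask, grid prompts, a mock
promptable backend at fidelity 0.85, and the weighted fusion:

```r
library(promptfuse)

gt  <- generate_ground_truth(synthetic_spec(rng_seed = 11))
gt
#> <binary_mask 128x128, foreground=1158 px (7.1%)>

seg     <- degrade(gt, degradation_spec(score_noise_sd = 40,
                                        boundary_jitter = 2, rng_seed = 99))
seg_bin <- binarize(seg, 128)
prompts <- extract_prompts(seg_bin, prompt_config("D", b = 8))
prompts
#> <prompt_set: method D, 24 checkpoint(s), 14 blob(s)>

backend <- mock_backend(gt, fidelity = 0.85, rng_seed = 7)
zs      <- backend(NULL, prompts)
fused   <- fuse(seg, zs, fusion_config(seg_weight = 2, zs_weight = 1,
                                       threshold = 128))

report <- evaluate_pairs(list(
  list(P = seg_bin,           T = gt, image_id = "segmentator"),
  list(P = binarize(zs, 128), T = gt, image_id = "promptable"),
  list(P = fused$binary,      T = gt, image_id = "fused")
))
print(report$per_image, digits = 3)
#>      image_id   iou  dice      mae   wfm emeasure
#> 1 segmentator 0.638 0.779 0.025818 0.846    0.903
#> 2  promptable 0.994 0.997 0.000427 0.995    1.000
#> 3       fused 0.658 0.794 0.024170 0.865    0.906
```

Reading the numbers: the boundary jitter and score noise cost the
segmentator a third of its IoU (0.638). The prompted backend nearly recovers
the scene (0.994) because every degraded blob still received a grid prompt.
The fusion — which deliberately weights the segmentator twice as much —
improves on the segmentator baseline across all five metrics (IoU 0.638 →
0.658, MAE down, weighted F and E-measure up) while staying anchored to it.
Batch runs over a directory of mask pairs go through `write_fixture_set()` +
`run_pipeline()`, which also writes prompt JSONs, fused PNGs, per-image CSV
reports and a reproducibility manifest. A thin command-line front end with
verbs `fixtures`, `prompts`, `fuse`, `evaluate` and `run` lives at
`inst/cli/promptfuse.R`.

## Package layout

| Where | What |
| --- | --- |
| `R/mask_io.R` | score/binary mask types, PNG/JPEG I/O, rescaling, polarity, thresholds |
| `R/blob_analysis.R` | 8-connected components, elliptical kernels, erosion |
| `R/prompts.R` | checkpoint methods A–D, border mode, fallback, JSON serialization |
| `R/fusion.R` | weighted fusion rule, file-level fusion with provenance |
| `R/metrics.R` | IoU, Dice, MAE, weighted F-measure, E-measure, aggregation |
| `R/synthetic.R` | scene generator, degradation model, mock promptable backend |
| `R/pipeline.R` | manifest-driven runs, reports, run comparison |

The methods vignette (`vignettes/prompt-fusion.Rmd`) documents the model,
the conventions chosen where upstream descriptions are ambiguous, and the
limits of the synthetic testbed.
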