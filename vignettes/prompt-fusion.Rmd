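---
title: "Checkpoint prompting and weighted logit-mask fusion: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Checkpoint prompting and weighted logit-mask fusion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promptfuse)
```

## The problem

Conventional segmentators (DeepLabv3+-style encoder-decoders, transformer
segmentators) produce a continuous per-pixel score map for a target class but
generalize poorly to unfamiliar objects. Point-promptable zero-shot
segmentators (the "segment anything" family) can segment almost anything but
need to be told *where* to look. promptfuse implements the glue between the
two: it turns a segmentator's mask into point prompts (*checkpoints*), feeds
them to the promptable model, and fuses the two continuous score masks into a
final segmentation that is usually better than either input.

Everything operates on two data types. A **score mask** holds per-pixel
integer scores on the byte scale $[0, 255]$ with an explicit *polarity* tag:
`foreground_high` (large = object) or `foreground_low` (the opposite, used by
segmentators that score the background class). No operation ever assumes a
default polarity; the tag travels with the data and is reconciled exactly
twice, in `binarize()` and `fuse()`. A **binary mask** holds $\{0,1\}$
labels; its 8-connected components are the *blobs* from which prompts are
extracted.

## Checkpoint extraction

Given a source binary mask (a thresholded segmentator output, or the ground
truth in the *oracle protocol*), four methods generate prompts:

* **A** — the bounding-box center of each blob. "Average coordinates" in the
  loosest sense: cheap, but for concave or hollow blobs the point can fall
  outside the object and mis-prompt the zero-shot model.
* **B** — the pixel centroid, rounded, and *snapped to the nearest blob
  pixel* (Euclidean, ties by (row, col)) whenever the rounded centroid is not
  itself a blob pixel. Membership in the blob is therefore an invariant of
  method B here, not just a tendency.
* **C** — a uniformly random blob pixel from a seeded generator; the blob id
  plus the configured seed fully determine the draw.
* **D** — a global lattice $\{(ib, jb)\}$ anchored at the image origin,
  clipped to the blobs, so large objects receive many prompts. Two
  refinements:
  * *Border mode*: the mask is first eroded with a $10 \times 10$ discrete
    elliptical structuring element so that prompts keep a margin from object
    boundaries, where promptable models are most easily confused. A blob that
    erosion removes entirely is rescued to its un-eroded pixel set (toggle
    `rescue_on_empty_erosion`), since losing all prompts for a small object
    is strictly worse than prompting near its boundary.
  * *Fallback*: a blob containing no lattice point gets the lattice shifted
    one pixel at a time — horizontal shifts $(dy{=}0, dx{=}1..b{-}1)$ first,
    then the vertical-major sweep $(dy{=}1..b{-}1, dx{=}0..b{-}1)$ — stopping
    at the first shift that intersects the blob. Because the shifts cover
    every residue class modulo $b$, termination with at least one checkpoint
    per nonempty blob is a theorem, not a hope, and the test suite checks it
    against an exhaustive oracle.

On the A/B distinction: for a binary blob the mean of pixel coordinates *is*
the center of mass, so a literal reading would make A and B identical, while
their documented failure modes differ (A can leave the blob, B rarely does).
We resolve this by making A the bounding-box center — an "average of coordinate
extremes" that genuinely can leave the blob — and B the true centroid with
snapping. The distinction is recorded here because the upstream description
is ambiguous; pick B when in doubt.

Two further conventions that the upstream description leaves open: the
lattice is anchored at the image origin (any anchor works once the fallback
exists; the origin makes results reproducible across images of different
sizes), and the fallback shift step is one pixel (the smallest step is the
one for which the residue-class coverage argument is exact).

Coordinates are 0-based (row, col) internally and serialize to JSON as
`x = col`, `y = row` — the convention of point-promptable models.

## Thresholding conventions

`binarize(mask, t)` interprets the margin `t` in the mask's *native*
convention. A `foreground_high` mask labels foreground where score $\ge t$.
A `foreground_low` mask is inverted first and the margin mirrored to
$256 - t$, so that "native score $< t$" and "inverted score $\ge 256 - t$"
classify identical byte values; using 255 instead of 256 would misclassify
the value $t$ itself. The default margin is 128; the stricter preset 32
(`source_threshold = "strict32"` in the pipeline) keeps only high-confidence
foreground of a foreground-low source, which discards outlier prompts while
fusion still uses the original continuous mask.

## The fusion rule

Both masks are normalized to `foreground_high` (the promptable model's
convention is typically opposite the segmentator's, so one inversion is the
norm, not the exception). Then, per pixel,

$$s_\text{fused} = \mathrm{round}\!\left(\frac{w_\text{seg}\, s_\text{seg} + w_\text{zs}\, s_\text{zs}}{w_\text{seg} + w_\text{zs}}\right),$$

followed by `fused >= threshold`. Defaults: $w_\text{seg} = 2$,
$w_\text{zs} = 1$, threshold 128. The weight-sum normalization is a
deliberate choice: it keeps the fused mask on the byte scale, so one fixed
threshold remains meaningful for *any* weights; an unnormalized sum would
silently couple the threshold to the weights. Ties at the threshold go to
foreground. The segmentator's double weight reflects that it was trained on
the target task while the zero-shot model was not; the weight is a config
field, not a constant, because the optimum is task dependent.

Consequences worth knowing: the fused score is a convex combination (bounded
by the per-pixel min and max of the inputs); with equal weights the rule is
symmetric in its inputs; and as one weight dominates, the binary output
converges to the single-mask binarization — all property-tested.

## Evaluation metrics

Five measures over prediction $P$ and ground truth $T$ (binary; continuous
masks are binarized by the caller):

* **IoU** $= |P \cap T| / |P \cup T|$ and **Dice** $= 2|P \cap T| / (|P| + |T|)$,
  with the exact identity $\mathrm{Dice} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$
  used as a permanent self-check.
* **MAE** $= \frac{1}{n}\sum_i |P_i - T_i|$: the mismatched-pixel fraction.
* **Weighted F-measure** (Margolin-style foreground-map evaluation):
  background errors are propagated to their nearest ground-truth pixel,
  smoothed with a $7 \times 7$ Gaussian ($\sigma = 5$), capped on the ground
  truth by the raw error, and attenuated away from the object by
  $2 - e^{\log(0.5)\,d/5}$; weighted precision/recall combine with
  $\beta^2 = 1$. The upstream description does not print these constants; we
  use the published defaults of the cited formulation.
* **E-measure** (enhanced alignment): both masks are mean-centered, aligned
  per pixel via $2 g c / (g^2 + c^2)$, mapped through $((\cdot)+1)^2/4$ and
  averaged. Degenerate ground truths score $\mathrm{mean}(1-P)$ (empty) or
  $\mathrm{mean}(P)$ (full), per the reference formulation.

Conventions chosen where references are silent or inconsistent:

* *Empty-empty pairs*: IoU = Dice = 1, MAE = 0 — predicting absence correctly
  is a perfect prediction, and it avoids 0/0.
* *E-measure normalization*: the reference code divides the alignment sum by
  $wh - 1$, which makes a perfect prediction score slightly **above** 1. We
  divide by $wh$ (a plain mean), so the measure is exactly 1 at $P = T$ and
  stays in $[0,1]$. On any realistically sized image the difference is below
  $10^{-3}$.
* *Distance-transform ties*: when a background pixel is equidistant from
  several ground-truth pixels, the error of the one with the smallest
  column-major linear index is used (the convention of MATLAB's `bwdist`,
  which the reference formulation relies on). This makes the weighted
  F-measure deterministic, at the price of exact invariance under image
  transposition (observed differences are a few times $10^{-3}$).
* The E-measure is *not* monotone under flipping a single mismatched pixel to
  match: the flip shifts the prediction mean, which can worsen alignment
  elsewhere. An exhaustive scan over all $3\times 3$ masks confirms this, so
  the suite asserts the properties that do hold ($P = T$ is the global
  maximum; score 1 at perfection) rather than a plausible-sounding one that
  does not.

Dataset aggregation is the unweighted arithmetic mean over images; failed
pairs are excluded, counted and reported.

## The synthetic testbed

`generate_ground_truth()` places well-separated elliptical or star-convex
blobs by rejection sampling; the separation constraint (default 4 px)
guarantees the component count, so every generated scene is its own oracle.
Defaults — $128 \times 128$ frame, 3 blobs of radius 8–15 px — are small
enough for millisecond turnaround and large enough that a grid of step 8
intersects every object.

`degrade()` emulates the documented failure modes of real segmentators at
two separate levels, so tests can isolate them: blob drops (missed objects),
whole-mask boundary jitter of up to ±`boundary_jitter` px via random
dilation/erosion (inaccurate boundaries), Poisson false blobs (spurious
regions) and clipped Gaussian score noise (soft confidence errors).

`mock_backend()` emulates a point-promptable segmentator: a prompt inside a
ground-truth blob selects the whole blob; background prompts select nothing.
This makes *prompt coverage*, not prompt count, the driver of recall —
exactly the failure axis that separates single-point methods (A–C) from grid
prompting (D). Fidelity $f$ adds clipped Gaussian noise with
$\sigma = (1-f) \cdot 255$, so $f = 1$ is a perfect oracle.

What the testbed does **not** emulate: texture, camouflage, semantic
ambiguity, correlated (structured) noise, and a promptable model's tendency
to return a semantically valid but unintended object. Passing tests
demonstrate the machinery is correct and the fusion logic beneficial under
this noise model; they do not predict absolute scores on real imagery.

Two headline experiments anchor the suite and the acceptance script:

* *Oracle recovery*: prompts from the ground truth, fidelity-1 backend,
  fusion against the ground truth's own scores must return IoU = Dice = 1,
  MAE = 0 across seeds — the pipeline is lossless end to end.
* *Fusion benefit*: with a noisy source (score noise sd 40, boundary jitter
  ±2 px) and a fidelity-0.85 backend prompted *from the degraded mask*, the
  fused IoU exceeds the source IoU on essentially every seed (paired sign
  test across 200 seeds, $p < 0.01$). The mechanism: the backend restores
  exact boundaries for every blob the prompts reach, and the weighted
  average pulls boundary pixels across the threshold in the right direction.

## Numerical choices

* Rounding is half-away-from-zero everywhere a real becomes an integer
  (rescaling, fusion, prompt coordinates); R's banker's rounding would make
  worked examples irreproducible across platforms.
* `rescale_to_byte()` is per-image min–max (min to 0, max to 255). A constant
  input maps to all zeros: an uninformative mask must not claim foreground.
* The $10 \times 10$ elliptical kernel is the filled discrete ellipse
  inscribed in its bounding box; even-sized kernels have no center pixel, so
  the anchor is fixed at $(\lceil h/2 \rceil - 1, \lceil w/2 \rceil - 1) =
  (4, 4)$, the common imaging convention. Out-of-image neighborhoods count
  as background, so objects erode at the frame edge too.
* Connectivity is 8-connected: the common imaging default, and it avoids
  splitting thin diagonal structures (ribs, limbs). Blobs are ordered by
  (row_min, col_min, area) and renumbered, so labeling is deterministic.
* Whole-mask erosion (not per-blob) in border mode; blobs are re-labeled
  afterwards, which also merges nothing and keeps the implementation a
  single pass.
* PNG is the canonical mask format because the suite asserts bit-exact round
  trips; JPEG (lossy) is read-only for compatibility with archives that used
  it to save space.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
metric identities on 500–1000 random pairs up to $64 \times 64$; metric
oracles on 200 pairs up to $32 \times 32$; grid/erosion oracles on 100 masks
of $36$–$40$ px; the oracle-recovery and fusion-benefit experiments on 20 and
200 scenes of $128 \times 128$. These sizes give stable statistics (the
fusion-benefit sign test is unambiguous at $n = 200$) while keeping a full
run within a couple of minutes on one core.

## Known limitations

* The weighted F-measure's distance computation is exact but
  $O(n_\text{bg} \cdot n_\text{fg})$ per image (chunked to bound memory);
  fine at the pipeline's image sizes, noticeable beyond ~$512^2$.
* Only two masks fuse at a time; no learned or per-pixel adaptive weights.
* Prompts are foreground points only — no boxes, text or negative points.
* The external-backend contract is an R function; wiring an actual promptable
  model in means wrapping its inference call (or a subprocess) behind
  `function(image, prompts) -> score_mask`.
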