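---
title: "Weakly supervised lesion localization in fundus photographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised lesion localization in fundus photographs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusWSSH)
```

## The problem

Diabetic retinopathy (DR) is graded 0 (healthy) to 4 (proliferative) from
color fundus photographs. The gradeable evidence is small: hard exudates
(sharp-edged, yellowish deposits), hemorrhages and microaneurysms (dark red
dots), against a reddish retinal field crossed by dark vessels, with one
large bright structure — the optic disc (OD) — that is *not* pathology but
shares the exudates' color. A classifier trained only on image-level grades
contains, in its final-layer weights, enough information to point at the
lesions it used; this package implements that weakly supervised localization
route and the plumbing around it:

1. **Preprocessing** — median denoising, CLAHE on the LAB lightness channel,
   gamma correction, optional Kirsch compass edge maps.
2. **Optic-disc removal** — Sobel gradients, automatic global thresholding,
   binary morphology, a circular Hough accumulator, disc excision.
3. **Classifier head** — a small convolutional backbone ending in
   global/region average pooling and a dense softmax layer, trained by
   momentum SGD under a stepwise learning-rate schedule.
4. **WSSH localization** — class-sensitive heat maps built from the dense
   weights and final-layer feature maps, thresholded into lesion boxes, with
   the detected disc suppressed as the dominant false-positive source.

No external dataset is needed: a deterministic synthetic fundus generator
with exact ground truth drives development, testing and calibration.

## Preprocessing

`median_denoise()` replaces each pixel by the median of its *k* × *k*
neighborhood (default *k* = 3, the smallest edge-preserving window). All
3 × 3 neighborhood operators in the package read out-of-domain pixels by
**edge replication**, which avoids dark halos at the border.

`clahe_enhance()` converts sRGB to CIE LAB (D65, via `grDevices`), applies
contrast-limited adaptive histogram equalization to the lightness channel
only, and converts back. The implementation uses 256-bin tile histograms,
clips each bin at `clip_limit` times the uniform bin count (default 2.0,
8 × 8 tiles — common fundus-enhancement practice), redistributes the excess
uniformly, and blends per-tile CDF mappings bilinearly in tile-center
coordinates. With a single tile and a clip limit above the tile pixel count
this reduces *exactly* to plain histogram equalization — the property the
test suite checks against an independently written CDF-mapping oracle.
Note one subtlety: a *flat* channel is only mapped to a flat output; under
clipping with unequal tile sizes the per-tile mappings of a flat channel
can differ, so "flat in, flat out" is guaranteed only for equal-size tiles.

`gamma_correct()` applies `I' = 255 * (I / 155)^(1/g)` per channel and clips
to the declared range. The divisor 155 (rather than 255) is a deliberate
fidelity choice: it makes 155 the intensity that saturates, so the map
lightens the dark retinal periphery aggressively. Everything at or above
155 maps to 255. The default `g = 1.2` lightens mildly; `g` is the only
free parameter. The map is pointwise monotone, so image ordering is
preserved.

`kirsch_edge_map()` takes the maximum response over the eight directional
3 × 3 compass kernels (the ±5/∓3 pattern). Each kernel sums to zero, so
flat regions respond with exactly 0 and the kernel family is closed under
90° rotation — both properties are tested. Raw responses span up to
15 × 255, so the default output is min–max rescaled into the declared
range; `rescale = FALSE` exposes raw responses for oracle comparison.

The chain runs in the order median → CLAHE → gamma → (optional) Kirsch,
with per-stage intermediates retrievable for inspection panels.

## Optic-disc detection and removal

The disc is found by `detect_od()`: luminance conversion, Sobel gradient
magnitude, a light Gaussian blur of the edge map, automatic global
thresholding (exhaustive between-class-variance maximization over 256
levels — Otsu's criterion; ties resolve to the lowest level), opening and
closing cleanup, then a circular Hough accumulator over the radius range
`(0.03, 0.15) · min(H, W)` using `x = a + r cos θ`, `y = b + r sin θ`.

Two numerical choices matter and were set by measurement on the seeded
synthetic suite:

* **Candidates are ranked by supported arc length** (completeness ×
  circumference), not by completeness alone. Exudate rims are small but
  *complete* circles; under completeness ranking they outrank the disc.
  Under arc ranking the disc's longer supported rim wins. The reported
  `score` remains the supported fraction of the circumference, and the
  `score_floor` (default 0.25) rejects images with no disc-like structure.
* **The edge band must stay thin.** With a wide blur (σ = 2) and heavy
  cleanup (opening/closing disks of radius 3/5) the disc rim becomes a
  band thick enough that large eccentric circles riding one side of it
  accumulate more arc than the true rim; disc recovery collapsed to 6/25
  on the synthetic suite. With σ = 1 and radius-1/2 elements recovery is
  25/25 at 256 px. Those are therefore the defaults.

Ties in the accumulator break to the smaller radius, then row-major center
order, making detection fully deterministic. `remove_od()` excises the
disc: every pixel with `(x−a)² + (y−b)² ≤ (r+margin)²` (boundary included)
is set to the fill value (black by default; optionally the median
background intensity), and the disc mask is returned for later heat-map
suppression.

Binary morphology uses the **clipped-translate convention**: structuring
element offsets falling outside the domain are ignored, so erosion/dilation
form an adjunction on in-domain masks and opening/closing stay idempotent
at borders. Grayscale dilation follows the sup-plus definition with edge
replication. All of these agree exactly with naive double-loop reference
implementations in the tests.

The grayscale conversion is the standard luminance weighting; the
horizontally-adjacent-product variant (`eq4_product = TRUE`), which darkens
anything next to a dark pixel, is available behind a flag but is not part
of the default chain.

## Classifier head and training

The bundled backbone is three 3 × 3 same-padding conv blocks
(conv → ReLU → batch norm, the normalization after the non-linearity), a
2 × 2 max pool after the first block, ending in `region_pool()`: each final
feature map is pooled into five units — the global mean `A_n1` over all
`N_1` units and the four quadrant means `A_n2..A_n5` (top/left blocks take
the ceiling split for odd sizes; the quadrants tile the map exactly). A
dense layer maps the 5·n pooled units to class scores; `softmax_prob()`
(max-shifted) gives probabilities; the loss is cross-entropy, the natural
partner of a softmax head.

Pooling only once is a deliberate localization choice: with 64 px inputs
the final maps stay at 32 × 32, and heat-map peaks inherit that spatial
precision. A `pool_after` option restores deeper pyramids. Any backbone
exposing final feature maps plus the region-pooled dense head can be
plugged in; full-scale compound-scaled architectures are out of scope.

Every parameter is updated by `momentum_update()`:
`v' = γ v + η ∂C/∂ω + decay`, `ω' = ω − v'`, with γ = 0.9 and λ = 10⁻⁴ as
defaults. The printed form of the decay term adds the *penalty value*
`(λ/2n) Σ ω²` — a scalar — into a vector update; the default mode uses the
gradient of that penalty, `(λ/n) ω`, which is dimensionally coherent, and
the literal scalar form is kept behind `decay_mode = "as_printed"`. The
mini-batch statistics use the population (1/n) variance.

The learning-rate schedule is piecewise constant: 0.1 through epoch 25,
0.01 through 37, 0.001 through 45, 10⁻⁴ through 60. Each printed milestone
is read as the *last* epoch of its plateau, with the drop taking effect the
following epoch, and the rate before the first milestone is the milestone's
own value. `lr_scale` multiplies the schedule for backbones whose stable
step size differs from its absolute level; the bundled small network trains
with `lr_scale = 0.3`.

Batch-norm inference statistics are not taken from the exponential running
average (which converges too slowly over short runs) but from a final
calibration pass that measures exact population statistics over the
training set — so single-image inference reproduces the statistics training
saw, and seeded training is bit-reproducible end to end.

## The WSSH localization layer

The class-sensitive heat map is `H_c(x, y) = Σ_n w_n^c f_n(x, y)` with
`w_n^c` the class's global-region dense weight. Its spatial mean equals the
class score contribution `(1/N_1) Σ_x Σ_y Σ_n W_n^c A^n_{x,y}` — the
algebraic identity (checked to 10⁻⁶ over a thousand random draws) that lets
classification weights double as localization weights with no box
annotations.

The region-weighted variant builds, for each quadrant region *j* = 2..5,
`I_cj(x, y) = Σ_k (w_{k1}^c / 4 + w_{kj}^c) f_k(x, y)`; the global weight
enters at a quarter of its value, one share per sub-region. How the four
per-region maps combine into one saliency map was an open design point; the
package takes the **elementwise maximum**, so evidence concentrated in any
single region stays visible, and also exposes the per-region maps.

Heat maps live on the final-feature grid and are upsampled bilinearly
(align-corners convention: output corners coincide with input corners;
constants are preserved and source grid points reproduce exactly). For
peak-based use the upsampled map can be smoothed with a small Gaussian
(default σ = 1.5 px in the localization stage): the argmax of the smoothed
map is the local center of heat mass, which removes the half-cell
quantization bias of the coarse feature grid. The smoothing is off by
default in `upsample_heatmap()` itself so the pure interpolation contract
remains testable.

The smoothed argmax still carries the feature grid's quantization, and
different training seeds leave different sub-pixel directional biases in
the learned filters. The localization stage therefore ends with
`refine_peak()`: within a small disc (default radius 4 px — one feature
cell of quantization plus the smoothing kernel's displacement) around the
heat argmax, the reported peak moves to the pixel most extreme against its
median-filtered surround, `|L − med₇(L)|`. Lesions are exactly the locally
extreme structures — exudates bright, hemorrhages dark — so the class
evidence proposes the neighborhood and the image pins the pixel. The
refinement is deterministic, needs no annotations, and was chosen over
dihedral test-time averaging, which cancels less of the bias at several
times the cost.

`heatmap_to_roi()` binarizes at `frac · max(heat)` (default 0.2, the usual
convention for activation-map thresholding), zeroes everything inside the
supplied OD mask, extracts 8-connected components, and drops any candidate
whose bounding box still touches the disc mask — the operational form of
removing the disc as a false exudate. ROIs are ordered by descending peak
value with row-major tie-breaks; heat maps are not ReLU-clipped before
thresholding unless requested. `warp_roi()` crops a box and resizes it
bilinearly to a fixed patch size. `pointing_game()` is the strict
evaluation metric: a hit if and only if the heat argmax (row-major
tie-break) lies inside the ground-truth lesion mask.

## The synthetic fundus generator

`generate_fundus()` renders, deterministically per `(seed, grade, config)`:
a black background with a circular retinal field (radial shading, Gaussian
noise, σ = 3 by default); a bright yellowish disc (radius 8–12 % of the
image side, offset 25–45 % of the field radius); two to four dark vessel
branches leaving the disc as quadratic Bézier curves; sharp-edged exudates
whose color is drawn from the disc's own range — deliberately reproducing
the disc/exudate confusion the pipeline addresses; and dark-red hemorrhage
dots. Lesion counts per grade (exudates 0/2/4/7/10, hemorrhages 0/1/3/5/8)
are non-decreasing in grade, and grade 0 renders no lesions. Lesions avoid
the disc plus a safety ring and avoid each other, so every exudate-mask
pixel is strictly brighter than its local background and localization
ground truth is unambiguous. One RNG substream per structure (disc,
vessels, lesions, noise) means toggling the lesion load does not move the
disc.

What the generator does **not** emulate: camera optics, illumination
gradients across rigs, vessel branching realism, soft exudates,
microaneurysm/hemorrhage distinction, laser scars, or any inter-patient
variability beyond its parameter ranges. Tests passing on this generator
show the pipeline's mechanics are correct under the stated geometry and
contrast assumptions; they are not evidence of clinical performance on
photographic data.

## Harness sizes and numerical conventions

The package's own verification suite runs at desk scale, sizes chosen as a
compromise between statistical resolution and a laptop-class single-CPU
run: definitional oracles on 100 random 16 × 16 inputs; disc recovery on
50 seeded 256 × 256 images (center within 5 px, radius within 10 %, at
least 45/50); disc suppression on 100 seeded 128 × 128 images (zero ROIs
touching the disc); end-to-end weak localization with 400 training images
at 64 × 64 (lesion-present vs grade-0, 12 epochs, batch 32, momentum 0.9,
weight decay 10⁻⁴, the stepwise schedule scaled by 0.3) and 100 held-out
lesion images, requiring the localization stage's reported peak
(disc-suppressed, contrast-refined) to land inside a lesion mask — the
pointing game on the stage's output — on at least 80 % of images under the
fixed seed.

Conventions collected in one place: pixel coordinates are 0-based
(row, col) with the origin at top-left; bounding boxes are half-open;
gray neighborhood operators replicate edges; binary morphology clips
element translates to the domain; Otsu scans 256 bins of the declared
range and returns the lower edge of the winning bin (lowest on ties);
`atan(Gy/Gx)` angles live in (−π/2, π/2] with the degenerate gradient
assigned 0; all argmax-style tie-breaks are row-major; every stochastic
step flows from a single seed.

## Known limitations

* The Hough stage assumes one dominant circular bright structure; images
  with two comparable discs resolve by tie-break, not by modeling.
* The classifier head is deliberately small; grades are collapsed to
  lesion-present vs healthy in the bundled harness, and 5-grade training,
  while supported, is not calibrated here.
* Heat-map localization has feature-grid resolution; lesions much smaller
  than one feature cell are found by the smoothed peak but their ROI
  extents are optimistic.
* CLAHE tile counts that do not divide the image size produce unequal
  tiles, whose clipped mappings can differ on degenerate (flat) input.
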