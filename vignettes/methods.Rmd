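---
title: "Methods: automated annulus measurement and device sizing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated annulus measurement and device sizing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 5)
library(tavisize)
```

## The problem

Transcatheter aortic valve implantation (TAVI) replaces a stenotic aortic
valve with a stented prosthesis delivered by catheter. The prosthesis size
is chosen from the dimensions of the *aortic annulus* — the virtual ring
at the base of the valve leaflets — measured on a 2-D cross-section of a
contrast-enhanced CT volume (the annular plane). Balloon-expandable
devices (Edwards Sapien 3) are sized by annulus **area**; self-expanding
devices (Medtronic Evolut) by annulus **perimeter**. Under- or
over-sizing carries real clinical risk, and manual planimetry is a known
source of interobserver variability.

`tavisize` implements a fully automated pipeline from annular-plane image
to device size:

1. **Preprocess** — resample the plane to two isotropic resolutions
   (1.0 mm and 0.5 mm) and clip a 128 × 128 px window centred on the
   annulus.
2. **Segment** — an encoder–decoder residual network per resolution
   produces per-pixel annulus probabilities.
3. **Fuse and measure** — the two probability maps are fused on the fine
   grid, the annulus contour is extracted with a canny edge detector, and
   area/perimeter follow from the shoelace formula and polyline arc
   length.
4. **Size** — chart lookup per device family, with out-of-range
   sentinels instead of forced nearest sizes.
5. **Validate** — Dice overlap, paired Wilcoxon signed-rank tests,
   Bland–Altman limits of agreement, Pearson correlation, Shapiro–Wilk
   normality and device-size agreement ratios.

Because clinical CT cohorts cannot be redistributed, the package ships a
**synthetic phantom generator** with exact analytic ground truth, which
is what every quantitative claim in the test suite is checked against.

## Phantom model

A phantom is an elliptical lumen (semi-axes $a \ge b$, rotation
$\theta$, centre offset) of contrast-enhanced blood-pool intensity,
surrounded by a soft-tissue wall ring of configurable thickness, zero to
four calcific deposits (small high-intensity discs straddling the lumen
boundary), all on a soft-tissue background with additive Gaussian noise.
Intensities are in Hounsfield units (HU). The defaults
(`cohort_ranges()`) span lumen 350–450 HU, wall 100–140 HU, background
20–60 HU, calcium 700–1100 HU, noise SD 10–30 HU, $a \in [10, 16]$ mm,
$b \in [7, 10]$ mm on a 140 mm field of view at 0.7 mm native spacing —
plausible adult annulus geometry and CT contrast.

The ground truth is analytic, not rasterized: area $\pi a b$ exactly, and
perimeter by adaptive quadrature of the ellipse arc-length integral
(`ellipse_perimeter()`, relative tolerance $10^{-10}$). The truth contour
is a dense 720-vertex polygon whose polygonal area/perimeter agree with
the closed forms to about $10^{-5}$ relative — far below every tolerance
used downstream.

Limits of realism: no leaflets, no left-ventricular outflow tract
anatomy, no streak or beam-hardening artefacts, elliptical rather than
truly irregular annuli. The phantoms exercise the *pipeline* (geometry,
optimization, measurement, statistics), not clinical generalization.

```{r phantom}
sample <- generate_phantom(phantom_spec(semi_axis_a = 12, semi_axis_b = 9,
                                        rotation = 0.5), seed = 1)
sample$truth_area
sample$truth_perimeter
image(sample$plane$values, col = gray.colors(128), asp = 1, axes = FALSE)
```

## Preprocessing

Raw planes are resampled with separable cubic splines
(`stats::spline`, natural "fmm" ends) to each target spacing, then
clipped to 128 × 128 px with the pixel nearest the annulus centre placed
at 0-based index (64, 64); out-of-field pixels are padded with
−1024 HU (air). At 1.0 mm the window spans 128 mm (global context); at
0.5 mm it spans 64 mm (boundary detail). Before entering the network,
HU are clamped to $[-1024, 1500]$ and mapped linearly to $[-1, 1]$.

Training masks are rasterized from the truth contour by the pixel-centre
even-odd rule, so mask area converges to the analytic area as spacing
shrinks.

## Segmentation network

No deep-learning framework is assumed: the network is implemented in
RcppArmadillo as an op tape (3 × 3 and 1 × 1 convolutions via
im2col + BLAS GEMM, ReLU, residual addition, 2 × 2 max pooling, nearest
upsampling, skip concatenation, sigmoid head) with hand-derived
reverse-mode gradients and an Adam optimizer. The architecture is a
U-Net with residual blocks: `depth` encoder levels (channels doubling
from `base_channels`), a bottleneck, and a mirrored decoder with skip
connections.

The loss is the sum of binary cross-entropy and a soft-Dice term
($\varepsilon = 1$ smoothing); the head bias is initialized at −2 so the
initial prediction matches the background-dominant class prior. Weights
use He initialization, except the second convolution of every residual
block, which starts at zero so each block begins as the identity
(Fixup/ReZero-style). The network has no normalization layers, and
without identity residual blocks its trainability was a lottery over the
initialization seed — some seeds never escaped the all-background
minimum; with them, every seed tested reaches validation Dice ≈ 0.9
within one epoch on 200 phantoms. Training applies on-the-fly augmentation
(flips, rotation up to 30°, integer translations up to 5 px, global HU
shifts) and keeps the weights of the epoch with the best validation hard
Dice. Everything is deterministic under the configuration seed.

Two configurations matter:

* `model_config()` defaults (depth 4, 16 base channels, 2 residual
  blocks/level, 30 epochs) — the reference architecture.
* the **small configuration** (depth 3, 4 base channels, 1 block/level,
  10 epochs, batch 4, learning rate $2 \times 10^{-3}$) — used by the
  test suite and acceptance script so the full 200-phantom study trains
  in minutes on one CPU. A pilot showed validation Dice ≈ 0.95 with only
  50 training phantoms at this size; phantom segmentation does not need
  the full capacity.

One model is trained per resolution, on the matching clipped planes.

## Detection and measurement

At inference the coarse (1.0 mm) probability map is resampled bilinearly
onto the fine (0.5 mm) grid using exact mm coordinates and averaged with
the fine map (`"mean"` fusion; `"minmax"` rescales each map by its own
range first). The grids are required to be concentric within one coarse
pixel: the clip step snaps each window to its own pixel grid, so a
sub-pixel centre offset is expected and harmless — the bilinear lookup
works in physical coordinates.

The contour is extracted from the fused map by canny edge detection
(Gaussian $\sigma$ = 1 px, Sobel gradients, non-maximum suppression,
hysteresis thresholds 0.1/0.2). Each 8-connected edge component is
linked into a polygon by **angular-sector radial averaging**: pixels are
partitioned into equal angular sectors about the component centroid
(sector count scales with component size, clamped to [16, 72]) and every
occupied sector contributes one vertex at the mean position of its
pixels. This is the package's main deliberate numerical choice. Naive
alternatives fail in characteristic ways: raw pixel-centre polygons carry
a staircase bias that inflates the perimeter of smooth shapes by several
percent, and pure angle-ordering of the pixels zigzags whenever canny
leaves a locally double edge, which falsely triggers open-loop rejection.
Sector averaging collapses both artefacts, and openness becomes a
coverage criterion: a component whose occupied sectors span less than
90 % of the circle (an arc cut by the border, a straight ridge) is
rejected as open. The closed loop enclosing the greatest area wins. No
further vertex smoothing is applied by default — a moving average on an
inscribed polygon systematically shrinks it. On held-out phantoms this
linking yields mean absolute area error ≈ 1.9 % and perimeter error
≈ 0.8 %; on hard binary discs the canny ridge sits about half a pixel
inside the true boundary, a small known negative bias. Area uses the
shoelace formula, perimeter the closed polyline length, and the
`measurement` class enforces the isoperimetric inequality
$P^2 \ge 4\pi A$ as a sanity invariant.

## Sizing

Charts are ordered sequences of contiguous, non-overlapping half-open
bands $[\ell, u)$ mapping a parameter to a size label; overlaps and gaps
are rejected at load with the offending band pair named. Values outside
the chart yield `OUT_OF_RANGE_LOW` / `OUT_OF_RANGE_HIGH` sentinels —
never a coerced nearest size. Selection is therefore a monotone step
function of the measurement. The bundled YAML charts (area bands for
Sapien 3, perimeter bands for Evolut) are editable configuration data
transcribed from public sizing documents, not validated clinical ground
truth. Note the perimeter chart is in mm (some clinical tables print cm).

```{r sizing}
det_meas <- measurement(area = pi * 10.4^2, perimeter = 2 * pi * 10.4)
size_case(det_meas,
          load_chart(default_chart_path("sapien3")),
          load_chart(default_chart_path("evolut")))
```

## Statistics

The agreement battery mirrors standard interobserver methodology:

* **Dice**: $2|A \cap B| / (|A| + |B|)$ on binary masks.
* **Wilcoxon signed-rank** (two-sided, on paired differences): exact
  p-values from the full null distribution (dynamic programme over the
  $2^n$ sign assignments) when there are no zeros or ties and
  $n \le 25$; otherwise a normal approximation with continuity and tie
  corrections and Pratt's treatment of zeros (ranked, then dropped from
  the statistic). On tie/zero-free inputs it reproduces
  `stats::wilcox.test` exactly.
* **Bland–Altman**: bias $\pm 1.96\,\mathrm{SD}$ of the differences.
* **Pearson** via `stats::cor`; **Shapiro–Wilk** via
  `stats::shapiro.test` (Royston's AS R94).
* **Size agreement**: fraction of exactly equal labels plus a confusion
  table and under/over counts using the ordering
  `OUT_OF_RANGE_LOW` < numeric sizes < `OUT_OF_RANGE_HIGH`.

`evaluate_cohort()` matches two measurement tables by case id (unmatched
ids are an error, listed by name) and assembles the full report;
degenerate comparisons (identical series) report bias 0, limits of
agreement (0, 0), Wilcoxon p = 1 and `NA` where a statistic is undefined.

## Problem sizes and budgets

The study size used in the tests and the acceptance script — 200
training phantoms, 50 held-out test phantoms, small configuration — is
the package's own choice: large enough that mean Dice ≥ 0.90 and mean
absolute area/perimeter errors ≤ 5 % are meaningful, small enough to
train both models and run all detections in well under 15 minutes on a
single CPU with single-threaded BLAS.

## Limitations

* Phantoms are elliptical with simplified anatomy; results do not claim
  clinical performance.
* The network is intentionally compact; no GPU path exists.
* Charts are configuration data; clinical use would require validated
  manufacturer tables.
* Contour extraction requires a closed edge loop; a probability map with
  no value ≥ 0.5 or with only open edge traces is a detection failure
  (reported per stage), not a silent fallback.
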