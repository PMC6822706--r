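---
title: "Methods: image analysis of fungal micrographs in fungalfeatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image analysis of fungal micrographs in fungalfeatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fungalfeatures)
```

## Scope and model

`fungalfeatures` quantifies four phenotypes of filamentous fungi from 2-D
grayscale micrographs: spore/conidia counts, per-spore morphometry,
mycelium architecture (single images and hourly-style time series), and
counts of the dense adhesive-network traps formed by nematode-trapping
fungi. The package assumes high-contrast 2-D images — dark spores or
traps on a bright brightfield background, or dye-stained bright
structures on a dark background — and makes no attempt to interpret
structures that live in three dimensions, such as aerial hyphae.

Images are plain numeric matrices with intensities in [0, 1]
(`read_gray_image()` normalizes 8/16-bit PNG and TIFF input; RGB is
converted to gray as the unweighted channel mean). All neighborhood
operations use 8-connectivity so that thin diagonal hyphae stay
connected.

## Calibration parameters

Every pipeline is driven by one parameter object, mirroring the idea that
a whole image set is analyzed with a single fixed calibration:

| parameter | units | default | role |
|---|---|---|---|
| `b1` | intensity fraction | 0.5 | strong threshold: seeds of the foreground |
| `b2` | intensity fraction | 0.3 | weak threshold: pixels joined to a seed |
| `min_area` | px | 30 | smallest component kept (rejects dust) |
| `max_area` | px | 2000 | largest component kept (rejects merged debris) |
| `elongation_max` | — | 0.7 | rejects long narrow artifacts (hyphal fragments) |
| `gaussian_radius` | px (kernel SD) | 20 | background estimation scale for mycelium images |
| `min_hyphae` | px | 10 | skeleton component deletion / branch pruning threshold |
| `scale` | μm/px | 1 | physical calibration; lengths × scale, areas × scale² |

The hysteresis rule is strict (`> b1`, `> b2`): a pixel exactly at a
threshold is background. Gates, by contrast, are closed intervals —
a component exactly at `min_area` or `elongation_max` is admissible —
matching the natural semantics of choosing an admissible value on a
slider. Filtering is done in pixel units, before any physical scaling,
since the gates parameterize the segmentation rather than the biology.
`preset_params()` ships calibrations tuned to the synthetic generators'
default contrast; real acquisitions should be re-calibrated with
`sweep_calibration()`, which replaces interactive sliders with a
parameter grid, one overlay per grid point, and a headline metric.

## Shape descriptors

Components are measured from their pixel sets. The best-fit ellipse is
the ellipse with the same normalized second central moments; its full
axes give length and width. Elongation is defined as
1 − minor/major: bounded in [0, 1], zero for a circle, monotone in the
axis ratio, and therefore a direct expression of the "long and narrow"
artifacts the gate is meant to reject. A single-pixel component is
assigned elongation 0.

Circularity is 2·√(π·A)/P, the perimeter of the equal-area disk over the
actual perimeter. The perimeter estimator matters here: counting
boundary pixels biases rasterized disks away from 1 depending on
orientation. The package uses a Crofton (intercept-count) estimator:
value transitions are counted along rows, columns and both diagonals
(line spacings 1 and 1/√2) and converted to length as
P = π/8·(c_h + c_v + (c_d1 + c_d2)/√2). This is exact for disks in the
continuum limit — a rasterized radius-20 disk scores circularity ≈ 0.98 —
and accurate to a few percent for smooth convex shapes; tests therefore
use 5% tolerances on rasterized fixtures. Very small objects (a few
pixels) can score slightly above 1; they are below any sensible
`min_area` in practice.

## Mycelium pipeline

The mycelium function chains: Gaussian background subtraction →
hysteresis binarization → 3×3 dilation → thinning → skeleton cleaning →
optional mask subtraction → graph extraction → metrics.

**Background subtraction.** The background is estimated as a Gaussian
blur of the image itself (kernel SD = `gaussian_radius`, support 3 SD,
replicated borders; images smaller than the kernel are replicate-padded
before filtering) and subtracted with clipping to [0, 1]. Slowly varying
illumination and staining gradients are essentially their own blur and
cancel; thin bright hyphae survive because their mass spreads over the
kernel. A radius of 0 is defined as the identity subtraction (an all-zero
image).

**Dilation before thinning.** Weakly stained or out-of-focus stretches
leave single-pixel gaps in the binary hyphae; a single 3×3 box dilation
closes them so the skeleton stays connected. The dilation is a
regularization for skeletonization only — the segmentation that accuracy
metrics are computed against is the pre-dilation binary
(`mycelium_binary()`), since dilating would systematically thicken every
hypha by two pixels and misstate boundary accuracy.

**Thinning.** A two-subiteration parallel thinning scheme of the
Zhang–Suen family, iterated to a fixed point. It preserves connectivity
and holes for structures wider than two pixels and leaves already-thin
lines unchanged. Tests assert topological properties (component counts,
tip counts, path coverage) rather than exact pixel sets, so any
equivalent topology-preserving thinning would satisfy them.

**Skeleton cleaning.** Two rules under one threshold: components with
fewer than `min_hyphae` pixels are deleted, and terminal branches whose
removable pixels (the path minus its junction pixel) number fewer than
`min_hyphae` are pruned back to their junction, iteratively, so spurious
thinning spurs disappear without eroding real branches. Pruning only
applies to branches attached to a junction; a free-standing short segment
is governed by the component rule alone. The threshold is measured in
pixels (path pixel count), the same unit as the sliders.

**Graph extraction.** Skeleton pixels of degree ≠ 2 become nodes, maximal
degree-2 chains become edges carrying their pixel path. Degree is counted
on a *reduced adjacency*: a diagonal link between two skeleton pixels is
ignored whenever one of the two orthogonal pixels bridging them is also
on the skeleton. Raw 8-neighbor counts misread the staircase corners of
near-diagonal runs as junctions (fragmenting one hypha into dozens of
spurious edges); under the reduced adjacency they are ordinary chain
pixels, and nothing can disconnect because a dropped diagonal always has
a two-step orthogonal detour. Adjacent junction pixels — thinning often
emits 2×2 junction clusters — are merged into one node at their centroid,
preventing spurious zero-length edges. A closed loop without junctions
becomes one node with a self-loop (degree 2); an isolated pixel becomes
an isolated node (degree 0), which is *not* counted as a tip, since tips
are defined strictly as nodes incident to exactly one edge.

**Metrics.** Total length sums edge lengths under the step rule
(orthogonal step 1, diagonal step √2), which is unbiased for diagonal
hyphae where a raw pixel count overestimates by up to √2; note that
staircase corners retained by the reduced adjacency make a near-45°
run measure slightly longer than its Euclidean chord, an effect shared
by the planted ground truth and bounded well within the 10% recovery
tolerance used in tests. Colonized area is the convex hull *of the graph
nodes* (shoelace formula on the `chull` vertices) — deliberately not the
hull of all skeleton pixels, so a long unbranched arc contributes only
its endpoints and the area is slightly underestimated for such shapes.
Fewer than three non-collinear nodes give area 0. Masks (e.g. well
edges) are subtracted from the cleaned skeleton, immediately before
graph extraction.

## Accuracy evaluation

`confusion_counts()` compares a predicted binary image with its ground
truth pixelwise; `accuracy_metrics()` derives precision, recall,
F-measure and MCC. Any metric with a zero denominator is reported as 0
rather than NaN so that batch tables stay numeric; such rows are
degenerate segmentations and obvious on inspection.
`evaluate_segmentation()` emits the conventional four-column table with a
trailing `Average` row holding true column means.

## The synthetic scene generators

The generators exist so that every pipeline has an exact, planted oracle:

* **Spore scenes** plant non-overlapping ellipses with sampled axes and
  orientation (placement by rejection sampling with a 3-px clearance, so
  segmented objects can never merge), plus two distractor classes a
  calibrated pipeline must reject: constant-width capsule bars
  (elongation ≈ 0.95, emulating hyphal fragments) and 1–3 px dust dots.
  Intensity follows the brightfield or fluorescence convention with
  additive Gaussian noise.
* **Mycelium scenes** grow a random branching tree of smooth unit-step
  polylines from a root: completed branches spawn two children at
  diverging angles (0.5–0.9 rad), branches stop at the margin or when
  approaching foreign branches, and the minimum branch length (30 px)
  exceeds the pruning threshold so every planted tip survives the
  pipeline. Centerlines are dilated to the drawn width (default 3 px) —
  this dilated centerline is both the rendered foreground and the ground
  truth for segmentation accuracy. Rendering adds a smooth intensity
  field along the mycelium, a low-frequency illumination gradient, and
  Gaussian noise. The exact generative tree is returned as a
  `mycelial_graph`, so tip counts and total length are known without any
  imaging.
* **Trap scenes** superimpose dense ring-and-spoke clusters (≥ 2200 px,
  radial spokes guarantee single-component connectivity) on sparse
  wavy hyphal strands, with clearance between traps and strands so the
  planted count is exact under trap-scale gates; under spore-scale gates
  the same scene fails deliberately, demonstrating that calibration, not
  the algorithm, separates the two functions.
* **Growth series** render nested prefixes of one tree as consecutive
  frames: planted length is strictly increasing, illumination is fixed
  across frames, noise is redrawn per frame.

Each generator is deterministic under its seed and restores the caller's
random-number state. Default scenes are 1024×1024, a desk-scale size at
which the full suite runs in well under a minute per pipeline.

What the generators do *not* emulate — and what passing tests therefore
do not establish for real data: optics (point-spread function, depth of
field), touching or overlapping spores (the pipeline deliberately counts
a touching clump as one object; no watershed declumping is attempted),
crossing hyphae in spore images, partial staining along a hypha,
background texture from the growth medium, and traps genuinely fused to
thick mycelial mats. Accuracy figures on synthetic suites are upper
bounds on what comparable real images would give; on real data the
calibration sweep and visual inspection of overlays remain essential.

## Numerical and interface choices

* Connectivity is 8-connected throughout (labeling, hysteresis flood
  fill); the graph layer alone refines this to the reduced adjacency
  described above.
* Component labeling builds on a 4-connected labeling pass followed by a
  union–find merge across diagonal label adjacencies.
* Droplet-to-dish extrapolation rounds to the nearest integer — counts
  are integers, and the pure ratio is exact for typical volumes anyway.
* Batch outputs are a pure function of input bytes and configuration: no
  timestamps, no unseeded randomness; reruns are byte-identical. Images
  are processed in lexicographic filename order, which also defines
  time-series order. Per-image failures become error rows and the batch
  continues.
* Config files are `key=value` text with exactly the eight parameter
  keys; unknown keys, malformed lines and missing keys are hard errors
  with line numbers, and `#` comments are ignored.
* Morphometry is reported per spore in long format (one row per
  conidium), the shape in which per-species distributions are plotted.

## Problem sizes used by the test suite

Unit tests run on small drawn grids (lines, Y-shapes, rings, disks) and
256–512 px scenes. The end-to-end accuracy checks use the generators'
study-scale defaults: 20 spore scenes of 25–200 planted spores at
1024×1024 with noise σ = 0.05 and distractors for the counting error,
and 10 mycelium scenes with noise and a 0.1-amplitude illumination
gradient for segmentation precision and F-measure. The exhaustive
hysteresis oracle covers all 3-level 2×3 grids plus randomized 4×4
grids.

## Known limitations

* No declumping of touching spores; counts are of connected objects.
* Elongation thresholds are tied to this package's definition
  (1 − minor/major); thresholds from tools using a different elongation
  convention do not transfer numerically.
* Absolute skeleton lengths depend on the step rule and the reduced
  adjacency; comparisons across software should use relative changes.
* The convex hull of graph nodes underestimates the area of long
  unbranched arcs.
* 3-D structures (aerial hyphae) and z-stacks are out of scope.
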