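---
title: "Composing multi-instrument training scenes by mask-based object insertion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composing multi-instrument training scenes by mask-based object insertion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mboi)
```

## The problem

Robotic scrub nurses need to detect and segment every instrument of a surgical
set from camera images of the instrument table. Training an instance
segmentation model for this requires many annotated multi-instrument images,
and pixel-accurate mask annotation is the expensive part. The instrument table
has convenient structure, though: instruments lie flat on a cloth, are arranged
without overlap, and the camera is an RGB-D device, so per-pixel depth is
available.

`mboi` exploits this structure. From a small pool of *single-instrument* (SI)
images — each with a segmentation mask, a depth map in meters, and the camera
intrinsics — plus a handful of background pictures, it composes arbitrarily
many *multi-instrument* (MI) scenes, automatically annotated with masks and
boxes, with class-balanced instance counts, with no inter-instrument overlap,
and with the instruments' relative physical size preserved.

## The insertion model

Each instrument is cut out by its mask and pasted onto the background by pixel
substitution after a randomized similarity transform with parameters

* flip bits $n, m \sim \mathrm{Bernoulli}(0.5)$,
* rotation $\theta \sim U(-\pi/2, \pi/2)$,
* translation $t_x \sim U(-w/2, w/2)$, $t_y \sim U(-h/2, h/2)$ for a frame of
  width $w$ and height $h$,
* a scale factor $s$ that is *not* random (next section).

The homogeneous matrix is composed as
$T = \mathrm{Translate}(t_x, t_y)\,\mathrm{Scale}(s)\,
\mathrm{Rotate}(\theta)\,\mathrm{Flip}(n, m)$ with
$\mathrm{Flip}(n,m) = \mathrm{diag}((-1)^n, (-1)^m)$. In the unflipped,
unit-scale case this is the familiar rotation-plus-translation matrix. We
deliberately build the matrix from these four factors rather than multiplying
the scale and flip signs into the cosine terms only: the factored form is a
similarity transform for *every* parameter combination (the linear block
divided by $s$ stays orthogonal, $|\det| = s^2$), which is the only reading
compatible with treating $s$ as a scalar pixels-per-meter ratio. The geometry
acts about the mask centroid, and the centroid lands at
$(w/2 + t_x,\; h/2 + t_y)$, so the translation law covers the frame uniformly
regardless of where the instrument sits in its source image. RGB is
interpolated bilinearly; masks use nearest neighbor, so no re-thresholding
ambiguity arises.

## Preserving relative size

SI images are taken at varying camera distances, so raw pixel sizes carry no
physical meaning. The package defines the *scale* of an instrument in an image
as

$$ s = \frac{l_{[p]}}{l_{[m]}} \quad \text{(pixels per meter)} $$

where $l_{[p]}$ is the mask diameter (the largest Euclidean distance between
two mask pixel centers, computed exactly via the convex hull) and $l_{[m]}$ is
the physical length of the same extent. The physical length comes from the
depth map: the two endpoint pixels realizing the diameter are deprojected
through the pinhole model $X = (u - c_x)z/f_x$, $Y = (v - c_y)z/f_y$, $Z = z$,
and $l_{[m]}$ is the Euclidean distance of the two 3D points. Because consumer
depth sensors leave holes, $z$ is taken as the median of valid (non-zero)
depths in a 5×5 window around each endpoint; the window size is an argument of
`physical_length()`.

The first instrument inserted into a scene keeps its raw scale ($s = 1$) and
its pixels-per-meter ratio becomes the scene reference $s^0$. Every subsequent
instrument $i$ is resized by

$$ s^i = \frac{l^i_{[m]}}{l^i_{[p]}} \cdot s^0 $$

after which its pixels-per-meter ratio equals $s^0$ — so a 20 cm needle holder
is always twice the length of a 10 cm one in the composed image, whatever
distances their source photos were taken at. $s^0$ is computed analytically
(applied scale × raw diameter / physical length) rather than re-measured on
the warped raster; for a similarity transform the two are equivalent, and the
analytic form avoids rasterization noise. The pseudo mode
(`preserve_relative_size = FALSE`) pastes everything at $s = 1$ instead and
exists as the ablation baseline.

## Occlusion avoidance and the out-of-frame rule

Real instrument tables avoid overlap, so the generator does too: a candidate
placement whose warped mask intersects the occupied pixels (optionally dilated
by `overlap_margin`) is rejected and the random parameters are redrawn —
keeping $s$ fixed, since $s$ is determined by the scale logic, not sampled.
After 20 total attempts (configurable) the instrument is omitted from the
scene. If the first instrument of a scene is omitted the whole scene is
abandoned and redrawn, because the scene has no reference scale without it.

The translation law deliberately lets instruments hang over the frame edge. If
at least 50 % of an instrument's warped pixels fall outside the frame, the
visible part is still pasted but the instrument is *not annotated*: a mostly
missing instrument carries too little information to define its class, and a
label on it would be noise. The boundary is exact: a missing fraction of
0.499 is annotated, 0.5 is not. Setting `keep_unannotated_paste = FALSE`
omits such instruments entirely, for training setups that dislike unlabeled
foreground.

## Class balance

A per-class ledger counts annotated instances. Each scene draws its class
subset by largest remaining quota first (ties broken uniformly at random), and
only *annotated* instances decrement the ledger — omitted and
pasted-unannotated placements are tallied in the generation log but do not
count, since balance matters for the training labels, not the pixels.
Generation stops when every class holds exactly `instances_per_class`
annotated instances, so the final histogram is exactly flat. Terminal scenes
may hold fewer than `min_per_image` instruments when fewer classes retain a
deficit; that is required for exact quota attainment.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `instances_per_class` | 1000 | annotated instances per class at termination |
| `min_per_image`, `max_per_image` | 3, 12 | per-scene instrument count range |
| `max_resample_iters` | 20 | total placement attempts before omission |
| `out_of_frame_drop_fraction` | 0.5 | missing-pixel fraction that cancels annotation |
| `preserve_relative_size` | `TRUE` | depth-derived scales vs raw-scale pasting |
| `overlap_margin` | 0 px | dilation of occupied pixels in the overlap test |
| `seed` | — | seeds the whole run; identical seeds reproduce identical JSON |

## The fixture generator

Real SI images require an RGB-D camera over an instrument table. For testing,
`make_collections()` procedurally emulates that raw material: per class, an
elongated silhouette of known physical length is rendered onto a flat
(fronto-parallel) depth plane at a known distance with known intrinsics. Five
silhouette families mirror the shape structure of a wisdom-teeth extraction
set (plain sticks, two-prong forks, looped retractors, crossed scissors-like
bars, and lumpy "unique" blobs), with the family multiplicities 4/4/3/2/5 of
the 18-class registry, so confusion-structure tests can exercise
similar-shape ambiguity.

Shapes are built as capsule strokes whose two tip caps sit exactly a diameter
apart on the horizontal axis, with all decoration strictly inside the
enclosing disc; the shape is centered on a pixel center or pixel corner,
whichever makes the rasterized extent closest to the continuous projection
$f L / z$. This keeps the measured mask diameter within one pixel of the
pinhole prediction, and the depth-recovered physical length within 2 % of the
configured truth — the fixtures' analytic ground truth is what the test suite
leans on.

Defaults were chosen once as realistic study conditions: 12 assets per class,
20 backgrounds, 320×240 frames with $f_x = f_y = 1.4\,w = 448$ px, camera
distances spread over 0.35–0.6 m (a table-mounted RGB-D working range), and
per-class lengths between 0.125 and 0.22 m (dental surgical instruments; the
big and small needle holders get 0.20 m and 0.125 m so the size-only class
distinction is represented). A tilted-plane option exercises the full 3D
distance path.

What the fixtures do *not* emulate: photorealistic appearance, specular
metallic texture, depth noise beyond holes, lens distortion, shadows, or
inter-instrument lighting interaction. Tests passing on fixtures therefore
validate the geometry, bookkeeping, and formats of the pipeline — not that a
detector trained on composed scenes transfers to real operating-room images.

## Evaluation machinery

The package also ships the measurement side: detections below a class score of
0.7 are discarded (inclusive at the threshold — a score of exactly 0.7
survives); box and mask IoU are intersection-over-union with half-open pixel
boxes; reports aggregate per-ground-truth-instance IoU via class-agnostic
greedy matching, scoring unmatched ground truth as 0, which penalizes missed
detections; and the normalized confusion matrix gates candidate pairs at
bounding-box IoU ≥ 0.5 (inclusive), matches greedily one-to-one, and
normalizes each row by that class's ground-truth count, with a `missed`
column for undetected instances. Matching is label-blind at the IoU gate —
otherwise cross-class confusion could never be tallied — and false-positive
detections are counted in an attribute rather than a matrix column, since the
matrix is defined per true class. Where the aggregation rule was genuinely
open (per-instance vs per-image means, matching criterion for mask IoU), the
package matches on bounding-box IoU and averages per instance; both choices
are stated here so results are interpretable.

## Numerical choices and degenerate inputs

* Image coordinates are 0-based, origin top-left, pixel centers at
  half-integers; boxes are `(x, y, w, h)` half-open. Masks are logical
  matrices; depth is meters in memory and 16-bit millimeters on disk (0 =
  invalid in both).
* Empty masks are errors everywhere a mask is measured (diameter, bbox,
  centroid): there is no meaningful answer.
* Zero-area boxes yield IoU 0 with a warning rather than an error, since they
  can appear in malformed detection files.
* The mask diameter uses the convex hull before the all-pairs scan; the
  brute-force scan is retained in the test suite as the oracle.
* Scenes are composed at 320×240 in the tests and the acceptance run; the
  composition cost is linear in pixels and the geometry is scale-free, so
  nothing but speed depends on the frame size.

## Known limitations

* The generator assumes the depth map and mask agree; a mask that includes
  background pixels biases the endpoint depth and hence the recovered length.
* Physical length is tip-to-tip along the mask diameter; for strongly curved
  instruments this is a chord, not an arc length, and the scale definition
  inherits that.
* Placement is rejection sampling; extremely full scenes (large
  `min_per_image` at small frames) degrade to many omissions rather than
  failing fast.
* The pasted foreground keeps its source illumination; no photometric
  harmonization with the background is attempted (explicitly out of scope).
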