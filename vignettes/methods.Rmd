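---
title: "Quantifying myotube area and nuclear fusion index with myofuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myotube area and nuclear fusion index with myofuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Myogenic cultures fuse mononucleated myoblasts into multinucleated
myotubes, and the standard way to quantify how far differentiation has
progressed is to immunostain a cytoskeletal marker (desmin or myosin
heavy chain) together with DAPI, then measure (i) the surface area
covered by myotubes and (ii) the nuclear fusion index (NFI): the number
of nuclei incorporated into myotubes as a proportion of all visible
nuclei in the field of view. Manual quantification is slow and
subjective — raters disagree about where a myotube's border runs, how
many nuclei a DAPI clump contains, and which marker-positive structures
are still unfused myoblasts. `myofuse` automates the whole measurement
so the same rules are applied to every image.

The package analyses bi- or tri-channel TIFFs in which one channel
carries the cytoskeletal stain and another the DAPI stain. For each
image it reports: total nuclei, nuclei inside any marker-positive
structure, nuclei inside *retained* structures (those holding at least
`min_nuclei` nuclei — the rest are classed as myoblasts and excluded),
the summed pixel area of retained structures, and
`NFI = nuclei_in_retained_tubes / total_nuclei`.

## The pipeline

### Myotube segmentation

1. **Illumination flattening.** The channel is divided by a heavily
   smoothed copy of itself and rescaled to [0, 1]. The background
   estimate is a cascade of three box filters whose combined impulse
   response approximates a Gaussian of standard deviation
   `4 * max_circle_rad` (160 px at defaults) — much larger than any
   nucleus or tube cross-section, so structures keep their local
   contrast while field-wide shading is removed. The box cascade runs in
   linear time regardless of scale, which matters because the kernel is
   frequently larger than small test images. An all-zero channel is
   returned unchanged rather than divided.
2. **Thresholding.** A global automatic threshold is computed by
   maximising between-class variance (Otsu's criterion, 256 bins) and
   scaled by the user's `tube_thresh`; pixels strictly above the product
   are foreground. This gives `tube_thresh` the documented behaviour: a
   lower value detects fainter staining, and the foreground is
   monotonically non-increasing in the setting.
3. **Filling and smoothing.** Holes are filled, then the border is
   smoothed by a morphological closing followed by an opening, both with
   a disc of radius `fill_size` (10 px). Closing-before-opening bridges
   small gaps before debris is removed; one consequence worth knowing is
   that any structure narrower than the disc diameter does not survive
   the opening.
4. **Size filtering.** Connected components (8-connectivity) smaller
   than `smallest_myotube_pixel_count` (500 px) are deleted. "Smaller
   than" is read strictly: a 500 px component survives, a 499 px one
   does not. The same strict reading is applied to every size gate in
   the package.

### Nucleus detection

1. **Adaptive denoising.** A pixel-wise Wiener-type filter in a 5x5
   window: the local mean is returned where the local variance is at the
   noise floor (estimated as the mean of all local variances) and the
   pixel is preserved where variance is high, so edges survive while
   additive noise is suppressed. The window size is a fixed
   implementation constant; 5x5 is the conventional default for this
   filter family and small relative to the 15-40 px nuclear radii.
2. **Thresholding and cleaning.** Automatic global threshold, hole
   filling, closing/opening with a disc of radius `nuc_fill_size`
   (5 px), then removal of components below
   `smallest_nucleus_pixel_count` (300 px) or above
   `height x width / max_nuc_size_divisor` — at the default divisor of
   100, anything larger than 1% of the image is discarded (exactly 1%
   survives; the ceiling is strict "larger than").
3. **Rounded nuclei by circle Hough transform.** Votes are accumulated
   on the boundary pixels of the cleaned mask over integer radii in
   `[min_circle_rad, max_circle_rad]`. A candidate needs at least half
   of the theoretical perimeter vote for its radius — a fraction rather
   than an absolute count so acceptance is scale-invariant across the
   radius range — and greedy non-maximum suppression forbids accepted
   centres closer than `min_circle_rad`. A candidate is finally accepted
   only if its circle covers at least 70% of its connected component's
   pixels. This roundness gate is what "rounded nuclei are identified"
   means operationally: a union of two overlapping discs always exposes
   more than half of each circle's perimeter (the occluded arc fraction
   `acos(d/2r)/pi` never exceeds one half), so a vote threshold alone
   cannot distinguish an isolated round nucleus from a nucleus inside a
   clump. The coverage gate routes clumps to the watershed stage while
   isolated round nuclei are claimed here. Single-circle coverage of a
   two-disc union never exceeds ~68% at realistic overlaps, so 0.7
   separates the two cases with margin on both sides.
4. **Watershed splitting of the remainder.** Hough-claimed circles are
   erased and the remaining regions are split by watershed on the
   distance transform. Instead of seeding from raw regional maxima —
   which over-segments whenever a blob has several shallow maxima — the
   watershed fragments whose distance-map peaks are closer than
   `min_circle_rad` are merged (single linkage). Reusing the radius
   prior avoids introducing a new tuning parameter. Fragments below the
   nucleus area floor are discarded; each survivor contributes one
   nucleus at its centroid (snapped to the nearest fragment pixel if
   the centroid of a crescent-shaped fragment falls outside it).

Each detected nucleus records its provenance (`hough` or `watershed`)
and size (circle radius or fragment area), and the full set is ordered
row-major so repeated runs are bit-identical.

### Fusion analysis

A nucleus belongs to the structure that contains its centre point.
Centre-point containment was chosen over pixel-overlap fractions because
it is unambiguous and assigns each nucleus to exactly one structure.
Structures with fewer than `min_nuclei` (3) nuclei are myoblasts and are
excluded; the reported area is summed over retained structures only, so
myoblast area never inflates the myotube area measurement. The NFI
numerator is the count of nuclei in *retained* structures, consistent
with excluding myoblasts before analysis; the raw in-any-structure count
is reported alongside it, so the alternative ratio can be recomputed
from the same output. With no nuclei in the image the NFI is defined as
0. An optional `scale_um_per_px` factor converts the retained area to
square micrometres; no attempt is made to read physical calibration
from image metadata.

## Parameters

| name | default | unit | role |
|---|---|---|---|
| SmallestMyotubePixelCount | 500 | px | myotube area floor (strict) |
| SmallestNucleusPixelCount | 300 | px | nucleus area floor (strict) |
| MyotubeChannel | 2 | — | cytoskeletal channel (1 = red, 2 = green, 3 = blue) |
| NucChannel | 3 | — | nuclear channel |
| FillSize | 10 | px | disc radius for tube border smoothing |
| NucFillSize | 5 | px | disc radius for nucleus border smoothing |
| MinCircleRad | 15 | px | lower nuclear radius bound; also the watershed marker-merge distance |
| MaxCircleRad | 40 | px | upper nuclear radius bound |
| TubeThresh | 1 | — | scale on the automatic tube threshold |
| MinNuclei | 3 | count | retention floor for structures |
| MaxNucSizeDivisor | 100 | — | nuclear ceiling = image area / divisor |

The channel convention follows the published value column (tubes green,
nuclei blue); radius parameters should be rescaled for magnifications
other than 20x. `TubeThresh` multiplies an automatically computed base
threshold rather than acting as an absolute intensity: the original
description of the parameter is purely behavioural, and a relative scale
keeps one default meaningful across differently exposed images.

## The synthetic-fixture generator

Real validation images cannot ship with the package, so every claim the
test suite makes is checked against `make_culture()`: seeded fields with
capsule-shaped myotubes (half-width 20-28 px), small ellipse myoblasts
holding 1-2 nuclei, anti-aliased nuclear discs with radii drawn from
[15, 25] by default, optional deliberately touching pairs (centre
distance 0.9x the radius sum, so single-circle coverage stays below the
roundness gate and the watershed route is exercised), additive Gaussian
noise (sigma 0.02 by default, 0.05 in the stress tests) and an optional
linear shading gradient. The generator records exact ground truth —
every structure's drawn pixel area and every nucleus centre, radius and
structure membership — and is bit-reproducible from its seed.

What the generator does *not* emulate: point-spread blurring, chromatic
aberration, intensity variation within nuclei (pyknotic vs euchromatic),
autofluorescence texture, or myotubes that cross each other. Passing the
synthetic suite therefore demonstrates that the pipeline's logic is
correct under the stated geometry and noise model, not that its default
parameters are optimal for any particular microscope; on real data the
radius bounds and `TubeThresh` are expected to need per-study
adjustment, which is why they are exposed.

`make_boundary_field()` engineers components whose post-smoothing pixel
area is *exact* (499 vs 500, 299 vs 300, 1% of the field), which is what
makes the strict boundary readings testable at all. Because morphology
changes pixel counts, the generator tunes a disc's real-valued radius
against the actual pipeline prefix, and when rasterisation jumps skip
the target area it slides a secondary disc — just larger than the
smoothing element, so the opening cannot delete it — out of the main
disc as a ~1 px area knob. Structures are tuned sequentially on the
growing composite field, so compositing cannot perturb the engineered
areas.

## Numerical choices and degenerate inputs

* Thresholds are strict (`>`); size floors are inclusive (`>=` floor),
  the size ceiling is exclusive (`<=` ceiling retained).
* Flat rasters threshold to empty masks; all-zero channels skip
  illumination division; empty masks propagate to empty results and an
  NFI of 0 rather than errors.
* Component labelling is 8-connected everywhere (diagonal contact joins
  a component); the 4-connected labeller underneath is augmented with a
  diagonal merge pass.
* Ties in the Hough accumulator are broken deterministically
  (score, then row-major position); all result orderings are canonical
  row-major sorts, so identical inputs give bit-identical outputs.
* The problem sizes used by the shipped tests (320-640 px fields,
  40-60 nuclei, 50-image invariant fuzz) were chosen so the full suite
  exercises every route — Hough, watershed, myoblast exclusion, batch
  mode — at desk scale; the pipeline itself has no upper size limit
  beyond memory.

## Command-line use

`exec/myofuse` exposes the published parameter syntax
(`myofuse TubeThresh 0.95 image.tif`, names case-insensitive); passing
a directory triggers batch mode, which processes every `*.tif`/`*.tiff`
non-recursively in lexicographic order, isolates per-image failures,
and writes `batch_summary.csv`, `batch_log.txt`, and per-image
diagnostics (4 overlay PNGs and a text summary each).

## Known limitations

* Touching or crossing myotubes are not separated into individuals, and
  no per-myotube size distribution is reported; the tool measures
  aggregate area.
* Nuclei outside `[MinCircleRad, MaxCircleRad]` are found only via the
  watershed route, and only if they clear the area floor.
* Heavily confluent DAPI fields (many-nucleus clumps) rely entirely on
  distance-transform geometry; accuracy degrades when overlaps exceed
  roughly half a radius.
* Physical-unit output requires a user-supplied pixel size; embedded
  TIFF calibration is ignored.
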