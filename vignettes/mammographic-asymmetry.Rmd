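---
title: "Detecting bilateral mammographic asymmetry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bilateral mammographic asymmetry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MammoAsym)
```

## The problem

Radiologists routinely compare the left and right breast of the same
patient: a difference in overall shape, or a difference in the thickness
of the skin line, can be an early sign of pathology. MammoAsym implements
a computer-aided pipeline that quantifies both comparisons on pairs of
digital mammograms:

1. **Shape asymmetry.** Each breast mask is reduced to a *radial
   signature* — the distance from the mask centroid to the outermost
   breast pixel as a function of angle over $[0, \pi]$. The two
   signatures are aligned with dynamic time warping (DTW) and summarized
   by a unitless index in $[0, 1]$; indices above 0.08 flag possible
   shape asymmetry.
2. **Skin-thickness asymmetry.** The bright skin rim is segmented by
   seeded region growing (Otsu mask → erosion → border seeds →
   conditional expansion). Mean rim thickness per unit of border length
   is compared across sides; relative differences above 0.39 flag
   possible skin asymmetry.

Both decision thresholds are the cohort-mean decision levels reported by
the study the method derives from; they are configurable everywhere they
appear.

## Ingestion and preprocessing

DICOM files are read by a minimal Part-10 parser (explicit and implicit
little-endian), since no DICOM reader is otherwise available to the
package. When a `WindowCenter`/`WindowWidth` pair is stored, the linear
VOI LUT transform maps stored values to $[0,1]$; otherwise intensities
are divided by $2^b - 1$, with $b$ taken from `BitsStored` when present
and inferred as the smallest depth in $\{8, 10, 12, 14, 16\}$ covering
the maximum stored value otherwise (these are the depths digital
mammography uses). Tabulated VOI LUT sequences and the sigmoid VOI
function are not applied — only the linear form is implemented.

Images are resized to the standard analysis frame of 512×512 px with
bilinear interpolation. Aspect ratio is not preserved; the acquisition
shape is kept on the object for reporting. Masks are computed *after*
resizing, so bilinear label mixing is not a concern.

Burned-in annotations are removed by thresholding at $T = 100$ on the
0–255 scale (the study's calibrated constant — internal intensities are
$[0,1]$, so the comparison is `image * 255 > T`) followed by selection of
the largest connected component (8-connectivity by default; 4 is
available). Orientation is standardized so every breast faces right; the
decision uses the mask's column-wise center of mass rather than the
DICOM laterality tag, because burned-in flips are common in practice.
Pixels outside the mask are set to zero so that the region grower's
"must not be black" condition cleanly excludes background. The threshold
is applied after all intensity normalization, including any VOI window.

## The radial signature and its angular convention

Rays are cast from the mask centroid at a configurable angular step
(default 1°, i.e. 181 samples over $[0, \pi]$; a coarse 1-radian mode is
available for fidelity experiments, but 4 samples cannot describe a
breast contour). **Convention:** $\theta = 0$ points straight up, the
sweep passes through left ($\pi/2$) and ends straight down ($\pi$). For
a right-oriented breast this traverses exactly the air–skin contour. The
obvious alternative — anchoring $\theta = 0$ on the chest-wall axis —
spends half the sweep on the frame edge and never samples the lower
contour, which we measured to make entire classes of contour deformity
invisible to the comparison; it was therefore rejected.

Distances are estimated sub-pixel: the binary mask is lightly smoothed
with a 3×3 box average (symmetric, so edges are not displaced), the ray
is sampled at quarter-pixel steps on a bilinear interpolation of that
surface, and the outermost 0.5-level crossing is refined by bisection.
This keeps normalized signatures invariant within 2% per angle under
translation and under uniform scaling between ×0.5 and ×2 of a
radius-50 disc — plain nearest-pixel lookup fails that bound at ×0.5,
where rasterization noise alone is ±2%.

Signatures are normalized by their maximum distance, making the
comparison size-invariant and bounding every local DTW cost by 1.

## DTW and the asymmetry index

The local cost matrix holds absolute (optionally squared) differences.
Cumulative costs use the classical three-move recursion (right,
diagonal, down), with out-of-range neighbours treated as $+\infty$. The
warping path is backtracked from the bottom-right corner; ties prefer
diagonal, then up, then left, fixed for reproducibility. The index is
the cumulative end cost divided by the warping path length; with
normalized inputs it lies in $[0, 1]$, zero for identical signatures.
The index is checked in the test suite against exhaustive enumeration of
all monotone warping paths for short sequences (lengths ≤ 6, 200 random
trials).

A property worth knowing when interpreting the index: dividing by the
path length makes the index a *mean per-step cost*, so isolated, narrow
contour features (e.g. a localized retraction) contribute little —
sustained differences across many angles dominate. A flagged pair
differs globally in contour, which matches the intended screening
semantics of the 0.08 cohort-level threshold.

## Skin segmentation by seeded region growing

Within the breast mask, an Otsu threshold (256-bin histogram) separates
the bright skin/dense pixels from darker tissue. The histogram is
restricted to breast pixels: on a whole frame the dark background
dominates and Otsu would merely re-find the breast outline rather than
"eliminate low-contrast tissue". Erosion of that mask with an $n \times
n$ box kernel (default 9) and the set difference mask − eroded yield the
border seeds, in row-major order. The image is framed by one row/column
of zeros (so frame-edge pixels need no special casing; seeds shift by
(+1, +1)), and growth proceeds breadth-first over 8-neighbours:

* the candidate must not be black (`image * 255 > 0`);
* its absolute intensity difference from the *originating seed of its
  growth chain* must lie strictly between the lower (default 1) and
  upper (default 200) thresholds, on the 0–255 scale;
* its Euclidean distance from that originating seed must not exceed the
  growth limit (default 3 px);
* each pixel is evaluated at most once (a visit counter), which also
  bounds the work by the image size.

Accepted pixels join the FIFO frontier attributed to the same
originating seed; the neighbour order (N, NE, E, SE, S, SW, W, NW) and
row-major seed order make the result deterministic. The defaults
(kernel 9, depth 3) are the optimum of the parametric study grid; the
prose alternatives (kernel 8, depth 4) do not appear in that grid and
are superseded by it. Even kernels (6, 12 appear in the grid) anchor
their extra row/column toward the bottom-right — erosion with even
kernels is convention-dependent, so the convention is fixed and tested.

The literal lower-bound condition excludes neighbours whose intensity is
*identical* to their seed, which is counter-intuitive for homogeneous
skin; it is implemented literally (it is part of the method as
described), and `lowerThreshold = 0` disables the lower bound for
sensitivity experiments. In practice tissue texture makes exact
intensity ties rare, and border seeds themselves are always admitted, so
the effect on segmented thickness is small and, importantly, identical
on both sides of a comparison.

**Thickness statistic.** The method's source never defines the thickness
statistic; we use segmented rim area divided by breast border length
(the outline pixel count of the hole-filled mask, excluding frame-edge
pixels — texture holes would otherwise inflate the denominator roughly
tenfold, and the chest-wall side carries no skin). The contralateral
difference is $|t_L - t_R| / \max(t_L, t_R)$, symmetric and bounded by
1. Both are isolated behind single functions so alternatives can be
swapped. Note the source reports one asymmetry value of 1.119, which no
max-relative difference can produce; its statistic was evidently
different, but is unrecoverable from the text, so the bounded,
interpretable form above was chosen.

## Validation metrics

ASSD (average symmetric surface distance) follows the standard
definition: surface points are mask pixels with at least one false
8-neighbour (the frame counts as false); the two directed sums of
nearest-point distances are divided by the total number of surface
points. RVD is signed, $(V_{seg} - V_{ref}) / V_{ref}$ — the unsigned
variant cannot produce the negative values the parametric study reports,
so the signed reading was adopted (the unsigned form is available behind
a flag). Distances are in pixels at the 512×512 working resolution; no
physical-mm conversion is attempted because pixel spacing varies across
acquisitions. The similarity-rate summary uses the population standard
deviation (the cohort is treated as complete; configurable).

The sweep harness runs the full 4×4×4×3 grid (kernel × depth × upper ×
lower = 192 cells) and marks the best row by minimal |mean RVD| with
mean ASSD as tie-break. Failures are recorded as missing cells.

## The phantom generator

Phantoms exist so every stage has pixel-level ground truth without any
patient data. Each phantom is an elliptical breast lobe anchored
`edgeOffset` px inside one lateral frame edge (the chest-wall side is
truncated by the frame, as compression produces), with:

* boundary radius $r(\theta) = r_e(\theta) + A \sin(f\theta + \varphi)$,
  where $r_e$ is the ellipse radius and the sinusoid models contour
  deformity;
* a skin rim: the outermost `rimWidth` px along the contour at a higher
  intensity (default 0.9 vs 0.45 interior);
* Gaussian tissue texture (sd 0.03 — strong enough to exercise Otsu,
  weak enough not to fragment the mask);
* small bright annotation islands near the background corners;
* deterministic rendering from an integer seed.

Pairs mirror the laterality and apply a contour-amplitude delta and/or
a rim-width ratio to the right side; labels derive from those deltas
(cutoffs: amplitude 5 px, ratio 1.5).

**How the geometry defaults were chosen.** The generator's defaults were
fixed by a calibration of the pipeline's response curves, then frozen.
Two findings drove them. First, with a plain half-ellipse the mask
centroid sits ≈ 0.42 r from the chest wall, so the radial profile itself
varies by ≈ 0.33 r; monotone warping can hide nearly any
amplitude perturbation inside that variation. Anchoring the lobe center
130 px inside the edge (`edgeOffset`) yields a truncated, near-circular
lobe (semi-axes 150, 150) whose profile is nearly flat, so contour
deformity shows up in the index instead of being warped away. Second,
because the index is a mean per-step cost, the labelled "asymmetric"
effect needs to be a sustained, gross deformity: cohort defaults use a
40 px amplitude delta (≈ 27% of the lobe radius — the kind of contour
distortion that is radiographically obvious) and a 2.5× rim thickening.
With these conditions the two flag thresholds separate labelled cohorts
cleanly (symmetric pairs score DTW ≈ 3×10⁻⁴ and thickness difference
≈ 0.005; asymmetric pairs ≈ 0.10–0.19 and ≈ 0.42–0.49).

**What the phantoms do not model** — and hence what passing tests do
*not* establish about clinical data: MLO pectoral muscle, glandular
structure and masses, detector noise models, scattered-dose gradients,
positioning variability between the two acquisitions of one patient, and
subtle (sub-centimetre) contour change. Cohort results on phantoms
demonstrate that the pipeline recovers the constructs it measures, not
clinical screening performance.

## Numerical and degenerate-input choices

* Component-size ties in largest-component selection break toward the
  component whose lexicographically smallest (row, col) pixel comes
  first.
* `resizeToStandard` returns 512×512 inputs unchanged bit-for-bit, so
  the operation is idempotent.
* All-zero images, empty masks, empty Otsu masks, empty seed sets and
  rays that never meet foreground raise immediate, descriptive errors
  rather than propagating NaNs.
* An index of exactly 0.08 (or a thickness difference of exactly 0.39)
  is *not* flagged: both classifiers use strict inequalities.
* Reports are serialized with `digits = NA`, so repeated runs are
  byte-identical.

## Problem sizes used by the shipped tests

The test-suite and acceptance-script sizes were chosen to exercise every
code path at full working resolution while remaining quick on one CPU:
512×512 phantoms throughout; a 40-pair cohort (half asymmetric) for
classification; 200 random short-sequence trials against the exhaustive
DTW oracle; 100 random 24×24 mask pairs against the brute-force ASSD
oracle; 100 random 32×32 images against an independently written
region-growing reference; and the full 192-cell sweep on 3 phantoms,
run twice to confirm byte-reproducibility.

## Known limitations

* Only single-frame grayscale DICOM is supported; tomosynthesis,
  multi-frame and color data are rejected.
* The DTW index's path-length normalization de-emphasizes narrow
  contour features (nipple retraction seen edge-on, small spiculations);
  a complementary localized statistic would be needed for those.
* The skin thickness statistic depends on the segmented area, so
  systematic over- or under-growth that is *symmetric* between sides
  cancels, but one-sided segmentation failure (e.g. a burned-in marker
  overlapping one breast's rim) will masquerade as asymmetry.
* No classifier is trained: thresholds are fixed operating points, and
  the cohort-level statistics here describe phantom constructs, not
  patients.
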