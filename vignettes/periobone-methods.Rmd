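---
title: "Measuring alveolar bone loss from segmented panoramic radiographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring alveolar bone loss from segmented panoramic radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periobone)
library(dplyr)
```

`periobone` covers the analysis layers that sit between a polygon
segmentation of a panoramic radiograph and a clinical summary: image
enhancement, landmark geometry, bone-loss percentages, prognosis staging,
and detector evaluation. This vignette explains the models and conventions
behind each layer, the parameters that matter, and what the synthetic
fixtures do and do not demonstrate.

## The geometric model

A panoramic radiograph is a 2-D projection in which periodontal bone loss
appears as the distance between two landmarks along a tooth: the
cemento-enamel junction (CEJ), a fixed anatomical reference where crown
enamel meets root cementum, and the alveolar bone crest, which migrates
apically as disease progresses. The package works from two polygon classes
per image — whole-tooth outlines and CEJ-to-bone-level regions — whatever
detector produced them.

**Tooth axis.** All distances are measured along the tooth's long axis,
not point-to-point. The axis is the principal axis of the polygon's area
moments (the eigenvector of the interior-uniform covariance, computed by
the exact shoelace integrals), anchored at the area centroid. Projection
onto the axis makes the measurement robust to where exactly the annotator
or detector placed vertices across the tooth's width; a Euclidean
CEJ-to-crest segment would inflate with any lateral offset.

The moments determine the axis only up to sign. The crown-to-apex
orientation is taken from the FDI quadrant when the tooth is labelled
(maxillary quadrants 1–2 point apex-up, mandibular 3–4 apex-down), and
defaults to apex-down otherwise, with perfectly isotropic polygons falling
back to vertical. We deliberately did not infer orientation from the
position of the CEJ region within the tooth: for severe loss the region's
centroid can sit apical to the tooth's midpoint, which makes any
centroid-based rule ambiguous exactly in the cases that matter most. An
explicit anatomical hint is deterministic everywhere.

**Landmarks.** For each CEJ-bone region assigned to a tooth, the CEJ (A)
is the region vertex with the smallest axial coordinate, the crest (B) the
vertex with the largest, and the apex (C) the tooth vertex with the
largest. Extraction by axial extremes guarantees the invariant
A ≤ B ≤ C along the axis; a region extending past the apex is rejected as
invalid. Regions are assigned to the tooth covering the greatest fraction
of their area — fraction of the *region*, not IoU, because the regions are
an order of magnitude smaller than teeth and IoU would be uninformative.
The default assignment floor is 0.05; regions below it are left
unassigned with a warning rather than guessed.

**Sides.** Mesial versus distal is a half-plane test of the region
centroid against the axis, interpreted through the FDI quadrant (the
mesial direction flips across the arch midline, and the patient's right
appears on the image's left in a panoramic frame). Without an FDI code the
side is reported as `midline` rather than guessed.

## Bone loss and prognosis

With calibration `mm_per_pixel` and biologic width *w* (default 2 mm, the
normal CEJ-to-crest distance of healthy bone), the per-site percentage is

$$\mathrm{loss} = 100 \cdot \frac{AB - w}{AC - w}$$

Raw values outside [0, 100] are clamped, with a warning: a crest coronal
to the biologic-width line is clinically "no loss", and a crest at or past
the apex cannot exceed total loss. A root whose CEJ-to-apex length does
not exceed *w* is a degenerate-root error — the package refuses to divide
by a non-positive denominator rather than producing a sign-flipped
percentage. Separately, any site whose gap exceeds a strict 2 mm threshold
is flagged abnormal; the formula offset and the flag threshold default to
the same constant but are configurable independently, since the threshold
is a screening choice while the offset is an anatomical one.

Measured distances are snapped to nanometer (1e-9 mm) precision before
use. This is pure float hygiene: a healthy synthetic site has a gap of
exactly 2 mm, and projection arithmetic otherwise leaves dust like
2 + 4e-16 that would trip the strict threshold.

Per tooth, the reported percentage is the maximum over its sites — the
"most severe site" convention that also defines the staging bands — and
bone support is its complement. The five prognosis levels are banded on
support: Good > 75, Fair/Poor on the closed band [50, 75], Questionable
[25, 50), Hopeless < 25. The published band notation overlaps at 75, 50
and 25; our convention resolves each boundary to the more favorable level
and makes the bands partition [0, 100] with no gaps, which the tests check
exhaustively. Clinical columns (probing depth, mobility, furcation) act as
per-level ceilings: a tooth gets the most favorable level whose support
floor and clinical ceilings it satisfies, so a deep pocket downgrades the
50–75 band from Fair to Poor, and absent fields satisfy every row —
missing clinical data never forces a downgrade. Radiographs alone cannot
measure probing depth, so radiographic-only runs report Fair for that band
and mark `basis = "radiographic_only"` to make the caveat explicit.

## Image enhancement

The enhancement chain is sharpen → global histogram equalization → 3×3
Gaussian smoothing, in that order. Sharpening is unsharp masking,
`clip(x + a(x − blur(x)))`, with the chain's own 3×3 Gaussian as the blur
and a configurable amount (default 1) — the standard parameter-light edge
enhancement. The smoothing kernel is the binomial (1/16)[1 2 1; 2 4 2;
1 2 1], the canonical 3×3 Gaussian approximation (σ ≈ 0.85), applied with
edge-replication padding, which makes the operator column-stochastic and
hence exactly mean-preserving before rounding. Equalization is global
(`round(255·cdf)`), not adaptive. Enhancement feeds annotation and
detection; the geometry layer consumes polygons only, so `analyze()` skips
the stage by default.

## Detector evaluation

Object-level matching is greedy in descending confidence, each prediction
taking the unmatched ground truth with the highest IoU ≥ 0.5, ties broken
toward the lower index — deterministic and standard. Polygon IoU is exact
(polygon clipping via `polyclip`), not rasterized. Average precision uses
the all-point interpolation (area under the precision envelope), the
current common definition for AP at a fixed IoU; per-class APs average
into mAP.

Confusion-matrix metrics need countable true negatives, which object
matching cannot provide. The package therefore counts TP/FP/FN/TN on a
fixed-size cell grid over the frame (default 64 px cells; a cell is
"covered" when a polygon contains its center). The grid is an explicit,
configurable evaluation unit: reported specificity and accuracy scale with
the cell size, which is why the unit is a parameter and not hidden.
Undefined ratios (zero denominators) are reported as `NA`, never silently
as 0. The dataset splitter shuffles under a fixed seed and gives the
rounded 10 % and 20 % shares to validation and test, the remainder to
training, so 2,000 ids split 1400/200/400 exactly.

## The synthetic generator

Synthetic scenes exist because clinical panoramic radiographs cannot be
shipped. Each scene lays out 1–16 lower-arch teeth (FDI codes) as
symmetric trapezoid-crown / tapered-root polygons with per-tooth jitter in
height, width and angulation (±8°), and draws each side's true bone loss
from a stated distribution (default uniform on 0–90 %). The crest of each
CEJ-bone region is placed by *inverting* the bone-loss formula, so the
generating percentage is ground truth by construction and parameter
recovery is a first-class test. The synthetic calibration is fixed at
0.1 mm/px (≈ 6 mm crowns, ≈ 12 mm roots — realistic magnitudes); rendering
adds mild Gaussian noise (σ = 2) and an optional blur built from repeated
3×3 passes.

The oracle detector returns the exact analytic polygons at confidence 1;
`perturb_annotations()` degrades them with vertex jitter and object drops
to emulate an imperfect detector for evaluation tests. Recovery through
the full pipeline from oracle polygons is exact to ~1e-8 percentage
points, which validates the geometry and formula chain — but deliberately
not the hard part of the real problem. Synthetic teeth are simplified,
non-overlapping and textured only trivially: passing these tests says the
measurement layers are correct *given* correct polygons, and says nothing
about how well any detector segments real anatomy, overlapping roots, or
poor-quality exposures.

Test and acceptance problem sizes — 50 scenes × 14 teeth for recovery,
1,000 random ≤ 6-object instances for matching-vs-exhaustive equivalence,
500 random polygons for the label round trip — were chosen as the package's
own balance of coverage against a few tens of seconds of runtime.

## Numerical conventions and limitations

Coordinates are 0-based, origin top-left, y downward; vertices are
pixel-center positions. YOLO labels are written with six decimals, so a
round trip is exact to well under the 0.5 px quantization bound on any
realistic frame. Polygons are repaired only by dropping duplicate
consecutive vertices; anything still self-intersecting is a hard error —
bad annotations should fail loudly, not be silently "fixed".

Known limitations: measurements are 2-D projections and inherit panoramic
magnification error beyond the single scalar calibration; teeth with
radiographically unmeasurable apices are errors, not guesses; the Fair/Poor
distinction genuinely requires probing data; and the grid-based confusion
matrix is one defensible choice of evaluation unit among several.
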