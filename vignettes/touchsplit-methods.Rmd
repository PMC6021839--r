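---
title: "Separating touching objects in binary depth masks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating touching objects in binary depth masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(touchsplit)
```

## The problem and the model

Top-down depth monitoring of group-housed animals produces binary
foreground/motion masks in which two adjacent moving animals merge into one
8-connected component. `touchsplit` splits such a blob into exactly two
labelled instances. The package assumes:

* the blob contains exactly two similar-sized objects (components larger
  than the touching gate of 500 pixels at the working resolution of
  256 x 212, where one weaning pig is about 35 x 10 px, roughly 350 px);
* the contact is a single interface (one neck), not an interleaving;
* coordinates are 1-based `(row, col)`, rows increasing downward;
  foreground is 8-connected and background 4-connected (the standard
  duality), and box bounds are inclusive.

Two routes produce the cut; a controller tries them in order.

### Detector-box route

An external detector (any instance detector trained on single animals)
proposes boxes with objectness probabilities. With the RoI being the blob's
tight enclosing box, `PP_RoI` the blob pixel count, and `BP_RoI` the count
of blob border pixels within `near_band` of the RoI perimeter, each
candidate box is scored by:

* **size condition** `size_lo * PP_RoI <= PP_BB <= size_hi * PP_RoI` — a
  useful box holds about half the blob;
* **boundary condition** `boundary_frac * BP_RoI <= BP_BB` — it reaches the
  blob's outer boundary (`BP_BB` counts blob border pixels near both the
  box perimeter and the RoI perimeter);
* **confidence** `(BP_BB - 0.2 BP_RoI) / |PP_BB - 0.5 PP_RoI|`, which
  rewards both properties at once. When a box holds exactly half the blob
  the denominator vanishes by construction; we floor it at half a pixel so
  such a box is maximally, finitely confident.

The best candidate is the confidence argmax (ties: larger pixel count, then
top-left-most box). A second box is accepted if its blob pixels outside the
first cover at least half of what the first leaves uncovered (**coverage
condition**). One box cuts along the single run where its perimeter crosses
the blob (two or more runs hand over to the shape route); two boxes cut
along their overlap rectangle's diagonal (the one more transverse to the
axis joining the box centres), their shared edge, or the midline of their
gap. A cut is accepted only behind two gates: boundary length at most
`seg_length_th` pixels and part-size ratio at most `seg_size_th` — long
contacts are exactly where box cuts go wrong, and they belong to the shape
route.

### Shape route

1. **Holes.** Enclosed background inside the blob ("natural" holes) marks
   the contact directly. Failing that, the blob is eroded
   `erosion_repeat_th` times with a 3x3 element: an enclosed void of the
   eroded shape is a hole; if the eroded shape instead *splits*, the neck is
   recovered as the meeting zone of the two largest remnants' geodesic
   reconstructions inside the original blob (dilate both step by step,
   masked by the blob, until they first meet; keep the meeting pixels that
   erosion had removed). If erosion empties the blob — the normal case for
   animals about 10 px wide, since 8 erosions remove 16 px of width — a
   last-resort hole is built from the medial-axis skeleton of the
   downsampled blob: the midpoint of the longest skeleton path approximates
   the contact centre, and a length-4 transversal through it (nearest
   outline point on each side, at least 90 degrees apart) becomes the hole.
2. **Guideline.** Each hole contributes the segment between its two
   farthest pixels; several holes are ordered along the principal axis of
   their union and chained nearest-end to nearest-end.
3. **Concave points.** The outline is unrolled against its convex hull into
   two series: `L`, the perpendicular distance to the covering hull chord
   (zero on the hull), and `G`, the Euclidean distance from the traversal
   start (the end of the last stored hull segment; hull segments are stored
   counterclockwise and the outline walked clockwise). Per hull segment the
   `L` argmax is a candidate concave point. A candidate survives if its
   defect is deeper than `min_depth` and its **fold ratio** — the maximum,
   over outline point pairs straddling it within its hull-defect run, of
   arc length walked over straight-line distance — reaches `cp_ratio_th`.
   At most two survivors (the deepest) remain.
4. **Cut.** Two concave points are joined through the guideline (assignment
   minimizing connector length); with one, the free guideline end attaches
   to the nearest outline point on the opposite side of the guideline's
   supporting line; with none, one end attaches to its globally nearest
   outline point and the other searches the opposite region. Invalid cuts
   retry with the next-nearest region point (5 retries).

Every constructed cut path is made 4-connected by inserting one pixel at
each diagonal step before removal: removing an 8-connected diagonal does not
disconnect an 8-connected foreground, so a pure Bresenham path cannot sever
the blob. After the split, the removed pixels are re-assigned each to its
nearest part (ties to the lower label), so the two labels partition the
input foreground exactly; labels are ordered by centroid (smaller row, then
column, is label 1) for reproducibility.

## Parameters

| key | default | meaning |
|---|---|---|
| `size_lo`, `size_hi` | 0.4, 0.6 | size condition band (fraction of blob pixels) |
| `boundary_frac` | 0.2 | boundary condition fraction |
| `probability_th` | 1.0 | objectness ingest threshold (compared with `>=`) |
| `near_band` | 2 px | "near the perimeter" band for border-pixel counting |
| `seg_length_th` | 20 px | max accepted boundary-line length (animal length ~35) |
| `seg_size_th` | 1.5 | max accepted part-size ratio |
| `erosion_repeat_th` | 8 | erosions for artificial holes (animal width ~10) |
| `skeleton_scale` | 0.5 | downsampling before skeletonization |
| `cp_band` | 0.1 | reported concave-section interval (fraction of G) |
| `cp_ratio_th` | 1.3 | minimum fold ratio for a concave point |
| `min_depth` | 1.0 px | minimum hull-defect depth (digitization floor) |
| `size_threshold` | 500 px | touching gate (strictly greater) |

Two defaults deserve comment. **`cp_ratio_th`:** a straight digital run has
fold ratio 1, axial+diagonal staircases reach ~1.1, a broad shallow
depression ~1.2, while genuine touching notches measure 1.4 and above; 1.3
separates the populations. **`min_depth`:** a digitized convex outline sags
up to one pixel below its own hull chords, so sub-pixel "defects" are
raster noise, not concavity — without this floor a perfect disc would yield
concave points.

`probability_th` defaults to 1.0 (the published detector operating point,
where boxes carry objectness exactly 1 after thresholding). The synthetic
detector below draws objectness in [0.8, 1), modelling post-threshold
survivors with calibrated confidence; evaluations on synthetic fixtures
therefore pass `probability_th = 0.8`. Both are exposed.

## What the synthetic generator does and does not emulate

`gen_pair()` rasterizes two ellipses (default semi-axes 17.5 x 5.5 px,
matching a ~35 x 11 px weaning pig at working resolution, and making a pair
exceed the 500 px gate) positioned so that the ground-truth contact
interface has a requested width; the interface width is the length of the
cut a perfect separation needs, and the distance search takes the largest
distance achieving it (light overlap — real touching animals do not
interpenetrate). Overlap pixels belong to the nearer centre (ties to label
1). Options carve a 1-4 px enclosed hole at the interface centre and flip a
fraction of boundary pixels with connectivity-preserving repair.
`gen_bbs()` jitters the ground-truth tight boxes by up to ±2 px per side
and adds distractor boxes outside the RoI. `gen_suite()` stratifies over
contact widths 4-24 px (chevron poses up to 10 px, side-by-side parallel
poses beyond, and an untilted heavy-overlap stratum at width 10 that yields
smooth, zero-concave-point blobs), hole carving, and noise rates 0/2/5%.

The generator does *not* emulate: depth-sensor speckle and invalid-depth
regions (the preprocessing stand-ins are tested separately), non-elliptical
body articulation (a pig bending its back is approximated only insofar as
tilted poses create broad shallow concavities), more than two animals, or
detector failure modes beyond jitter/drop/distractors. A green suite
therefore establishes the geometry engine and routing logic, not
field-camera performance; the published frame-level accuracy figures are
not reproducible without the original footage and detector weights.

## Numerical and design choices

* **Interpolation stand-ins.** The 2x2 spatial mean (512x424 to 256x212)
  ignores invalid pixels and keeps reals internally, quantizing only on
  export; three-frame temporal averaging treats a pixel as invalid only if
  all three frames are. Background subtraction is plain differencing
  (object at least `depth_delta` nearer the camera than the background);
  the full noise-removal chain of the original acquisition system is out of
  scope.
* **Fold ratio instead of a banded G section.** The distance-from-start
  series loses all resolution near its own origin (the band
  `G (1 ± 0.1)` collapses), and which side of the blob hosts the origin is
  an artifact of the hull convention; sections measured that way scored the
  same notch anywhere between 1.0 and 6 depending on orientation. The fold
  ratio is start- and orientation-independent and keeps the intended
  semantics (a notch folds the outline back on itself; a bent back does
  not). The `cp_band` interval is retained as the reported concave-section
  of each concave point.
* **Erosion-hole formalisation.** "Voids that appear under erosion" is
  implemented as (a) enclosed background of the eroded image, else (b) the
  first-meeting zone of the two largest remnants' geodesic reconstructions.
  The reconstruction is stopped at the first step where the remnants meet
  so the hole stays compact and centred on the vanished neck.
* **Skeleton details.** Zhang-Suen thinning on a block-OR downsampled mask
  stands in for the medial-axis transform; the "centroid" is the midpoint
  of the longest endpoint-to-endpoint skeleton path (double breadth-first
  search). Degenerate blobs (skeleton under 2 px) raise a typed error and
  the controller reports the blob unseparable.
* **Controller cascade.** When a hole source yields a guideline whose cut
  fails validity, the controller falls through to the next source in the
  fixed order natural -> erosion -> skeleton before giving up. Provenance
  (`module_used`, all gate flags) is attached to every result.
* **Determinism.** All tie-breaks are specified (lexicographic farthest
  pair, confidence/size/position box ordering, lower-label pixel
  assignment, centroid label ordering); the generator uses one RNG stream
  per seed with draws in documented order; batch reports are
  byte-reproducible.

## Limitations

* Exactly two objects; three or more touching animals are out of scope.
* The one-box cut requires the box perimeter to cross the blob in a single
  run, which is rare in practice (the two-box overlap cut does most of the
  work, as in the original system where single-box separations were ~2% of
  box-route successes).
* Side-by-side parallel poses put most of one object's pixels inside the
  other's tight box, so the size condition routes them to the shape route
  by design — the box route cannot be forced on wide contacts.
* The shape route assumes one dominant neck; two well-separated concavities
  on the same hull segment merge into one candidate (hull vertices exclude
  collinear points).
* Pixel-identity accuracy is per-blob; no temporal identity propagation is
  attempted.
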