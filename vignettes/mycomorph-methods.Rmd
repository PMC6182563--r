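---
title: "Quantifying mycelial morphology from micrographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mycelial morphology from micrographs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Submerged cultures of filamentous fungi evolve, within a day, from
micrometer-scale conidiospores through swollen spores, agglomerates,
germlings and hyphal clumps to pellets that can exceed a millimeter.
Morphology correlates strongly with productivity, and interventions such as
microparticle-enhanced cultivation (MPEC; adding ~10 um mineral
microparticles to the medium) are used to steer it. Tracking this evolution
quantitatively requires measuring the size and shape of every *mycelial
object* in large numbers of phase-contrast micrographs taken at changing
magnification, while ignoring debris — notably the microparticles
themselves.

`mycomorph` implements that measurement chain as a reproducible pipeline:

1. green-plane extraction from the RGB micrograph,
2. median smoothing (`median_smooth()`),
3. Sobel edge enhancement (`sobel_edge_magnitude()`),
4. edge-based segmentation into labeled objects (`segment_from_edges()`),
5. per-object descriptors (`measure_objects()`),
6. debris removal by size/shape filters and areas of interest
   (`apply_filters()`, `apply_aoi()`),
7. two-class partition and per-timepoint statistics with Student-t
   confidence bands (`partition_by_area()`, `summarize_morphology()`).

Working on *enhanced edges* rather than raw intensity makes segmentation
independent of the absolute shade of the objects, which changes with
objective and growth stage. Every image carries a um-per-pixel calibration,
so all size descriptors are physical (um, um^2).

## Descriptors

For an object mask of `n` pixels at calibration `c` (um/px):

* **Projected area** `A = n * c^2`.
* **Mean diameter** `D`: the average, over `n_dirs` equally spaced
  directions in `[0, pi)`, of the chord through the center of gravity
  (the contiguous run containing the centroid, traced in 0.25 px steps).
  The default is 180 directions; at 360 directions the disk and square
  test shapes move by well under 0.5%, so results are insensitive to the
  direction count at this scale. If the centroid falls outside the mask
  (strongly concave objects) the maximum diameter is substituted and the
  object is flagged.
* **Maximum diameter** `Dmax`: the maximum Feret diameter — the largest
  pairwise distance between boundary pixel centers (computed on the convex
  hull of the boundary) plus the 1 px footprint of the end pixels.
* **Elongation** `E`: the ratio of the larger to the smaller eigenvalue of
  the pixel-coordinate covariance — the squared quotient of the
  longitudinal and transversal deviation along the regression (major
  principal) axis. `E = 1` for a circle. A single pixel has `E = 1` by
  definition; a perfect pixel line returns an infinite sentinel, is
  flagged, and is excluded from summaries.
* **Roughness / solidity** `R`: projected area over the area of the
  rasterized convex hull (pixel centers inside or on the hull polygon).
  `R = 1` for a smooth convex object; protruding filaments push it down.
* **Circularity** `4 pi A / P^2`, with the perimeter `P` measured as the
  length of the traced 8-connected boundary chain, diagonal steps weighted
  `sqrt(2)`; objects too small to trace fall back on the crack perimeter.
  The formula is stated here because shape-filtering conventions differ
  between packages.
* **Morphology number**
  `Mo = 2 sqrt(A S) / (sqrt(pi) Dmax E)`, with `S = R`. For an ideal disk
  (`A = pi r^2`, `S = E = 1`, `Dmax = 2r`) the closed form gives exactly 1.
  Circular objects — ungerminated spores, ideal pellets — stay at or above
  about 0.6; evolved filamentous morphology falls below 0.5. An
  alternative reading of the composite, `2 sqrt(A) S / (sqrt(pi) Dmax E)`,
  coincides with ours for `S = 1` (every analytic test shape); the adopted
  form is recorded in the `mo_form` attribute of every object table.

Rasterization can push `R`, circularity and `Mo` a percent or two above 1
on digital disks; tables therefore report raw values alongside
clipped-to-[0, 1] convenience columns, with 1.02 treated as the
rasterization tolerance.

## Numerical and design choices

* **Median smoothing** defaults to a 3 x 3 neighborhood — the smallest
  kernel that smooths edges while preserving 2 um spores at high
  magnification. Radius 1 uses an exact vectorized median-of-9 network;
  larger radii use EBImage's constant-time median on a 16-bit quantization.
  Both filters replicate edges, so image size is preserved. A dedicated
  test bounds its effect on a disk's projected area below 2% — smoothing
  does not change object size or shape materially, but it is *not* exactly
  shape-free: its corner rounding perturbs the elongation of ~180 px
  objects by up to ~5%. For that reason the noise-free recovery
  experiments below run with smoothing disabled; on real (noisy) images
  the smoothing is what makes the edge map usable, and its small shape
  cost is accepted.
* **Segmentation**: the Sobel magnitude is thresholded (Otsu's method on
  the gradient histogram by default — the data decide, since no absolute
  threshold generalizes across objectives), contours are closed
  (radius 2 px, bridging 1-2 px gaps), holes are filled, and the result is
  eroded by 1 px with a 4-neighbor cross: the Sobel ridge of a sharp
  boundary straddles it by about one pixel on each side, so the filled
  region over-covers the object by that much. A full 3 x 3 erosion removes
  ~1.2 px and biases small-object areas low, which is why the cross is
  used. A final 3 x 3 majority vote rounds off residual +-1 px boundary
  quantization without a systematic area bias. Components are 8-connected
  and labeled 1..n.
* **Filtering**: objects touching the frame border are excluded by default
  (partial objects corrupt size statistics). Spore images remove
  non-circular objects below circularity 0.75 — rasterized spores sit
  above 0.85 while angular mineral grains land well below 0.7; pellet
  images remove objects below 200 um^2. The paper-style manual debris
  removal is replaced by a rule-based removal report; no interactive
  editing is provided. AOIs keep objects by an inclusive centroid-inside
  test, so surviving shapes are never truncated.
* **Statistics**: sample standard deviation uses the n-1 denominator;
  confidence half-widths are `t(1 - alpha/2, n - 1) sd / sqrt(n)` with
  `alpha = 0.05` by default. Groups of one object report the mean and are
  flagged rather than dividing by zero. The two-class area threshold
  defaults to 1e4 um^2; an object exactly on the threshold is assigned to
  the large class (the boundary had to be closed on one side; the choice
  is documented and tested). Slow, non-agglomerative pellet formation can
  require 1e5 um^2, which is a per-run override.
* **Coordinates**: pixel coordinates are 0-based, x rightward, y downward,
  in all tables and AOI files.

## The synthetic-scene generator

No micrograph data ship with the package, so a seedable generator
(`scene_new()`, `generate_spore_field()`, `generate_agglomerate()`,
`generate_hairy_pellet()`, `generate_clump()`, `generate_filament()`,
`add_microparticles()`, `simulate_timecourse()`) emulates the study
conditions: 2448 x 1920 frames, bright background with dark objects (the
green plane carries full contrast), spores of ~2-8 um, agglomerates,
hairy / core-shell / multicore pellets up to millimeter scale, branching
hyphal clumps, and angular ~10 um mineral grains booked as non-mycelial
debris. Ground truth stores every exact mask; true descriptor values are
computed by the same morphometry operations on the noiseless true masks,
which cleanly separates rendering/segmentation error from descriptor error.

Choices worth knowing:

* **Agglomerates** grow by ballistic aggregation: members arrive along a
  random direction with a random impact parameter and stick at first
  contact. This gives compact clusters whose area grows roughly linearly
  with member count, consistent with solid-packed spore agglomerates
  (an agglomerate of ~4000 spores of a few um^2 each has an area of the
  same order as the member sum). The true mask is then closed with a
  half-member-radius disc: pixel-wide crevices between members are below
  optical scale and are not realistic agglomerate geometry. Attachment is
  geometric, not physical — no adhesion model is implied.
* **Spore centers sit on the pixel grid.** An off-grid rasterized disk is
  measurably elliptical (true `E` up to ~1.08 at 20 px across), which
  would contradict the contract that circular spores have true
  `E = 1 +- 0.02`.
* **Pellets** are a disk core (or a compact cluster of up to 4 cores, each
  stored separately so core/pellet diameter ratios can be scored) with
  radially oriented filaments of jittered angle and length.
* **Clumps** are branching random walks with capped tip count (16), so
  branching cannot blow up exponentially.
* **Timecourses** follow four editable stage schedules
  (`timecourse_profiles()`): spore-agglomerative, hyphal-agglomerative,
  perithecia-seeded and non-agglomerative. They reproduce the *qualitative*
  developmental narratives only — e.g. the spore-agglomerative profile
  starts at mean `Mo ~ 0.95`, dips to ~0.1 during germination when germ
  tubes dominate the silhouette, and recovers to ~0.7 at the pellet stage;
  sizes straddle the 1e4 um^2 class threshold at the agglomerate stage.
  Stage parameters (member counts, filament lengths, per-stage
  calibration emulating objective changes) were chosen once as
  order-of-magnitude realistic; they are not calibrated to any measured
  distribution, because none is available. The default frames are
  2448 x 1920; tests use smaller frames where the geometry allows.

What passing the synthetic tests does **not** show: performance on real
phase-contrast optics (no point-spread function, halos are a crude rim,
no uneven illumination), on touching or overlapping objects (no watershed
splitting is attempted — the procedure deliberately does not split
objects), or on debris that is neither angular nor ~10 um.

## Verification strategy and problem sizes

The test suite checks three layers, each against an independent oracle:

1. **Analytic shapes** end to end (render, segment, measure): a disk of
   radius 200 px has `E = R = 1` within 0.02 and `Mo >= 0.6` (measured
   ~0.998); a 3 px wide, 300 px long sinusoidal filament has `Mo <= 0.5`
   (measured ~0.003). Closed forms used: disk `Mo = 1`; square mean
   diameter `(4/pi) ln(1 + sqrt 2) s`; rectangle elongation
   `(w^2 - 1)/(h^2 - 1)` from discrete uniform variances; Feret diameters
   against an O(n^2) brute-force pairwise search; solidity against an
   explicit half-plane hull rasterization; the t quantile against a
   published table value (2.776445 for 4 df).
2. **Recovery on 30 seeded noise-free scenes** (one ~4500 px agglomerate
   plus three 150-450 px spores each, 500 x 500 px at 0.5 um/px):
   measured `A` and `E` within 5% and `R` within 0.05 of ground truth for
   every object; with default spore filters, 100% of forty 10 um grains
   are removed from a full-frame fixture with zero true-spore loss.
3. **Qualitative trajectory**: the dip-then-rise of mean `Mo` along the
   spore-agglomerative timecourse holds for ground truth and for the
   measured pipeline output.

The full suite runs in under two minutes on one CPU; the heaviest pieces
are the 30-scene recovery block and the six-frame timecourse at
2448 x 1920.

## Known limitations

* Accuracy claims hold for objects of >= 100 px; below that, +-1 px
  boundary quantization dominates every descriptor.
* The mean diameter of strongly concave objects (flagged
  `centroid_outside`) falls back on `Dmax` and should be interpreted
  accordingly.
* Elongation of near-perfect pixel lines is unstable by construction and
  is reported as an infinite sentinel rather than a number.
* The per-objective calibration map shipped in `default_config()` holds
  plausible placeholders, not measured values; replace them with your
  microscope's calibration before analyzing real data.
* Solidity is *not* monotone in filament count at fixed filament length:
  once filaments span all directions the convex hull saturates, and
  additional filaments raise `R` again. Tests assert the meaningful
  contrasts (bare core vs. hairy, and the hairy bound `R < 0.9`).
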