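---
title: "Methods: quantifying epithelial organization and cadherin localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying epithelial organization and cadherin localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiquant)
```

`epiquant` quantifies two complementary readouts of E-cadherin function in
epithelial cell images: *where the protein sits* (membranous versus
perinuclear versus diffuse, from internuclear intensity profiles) and *how
the tissue is organized* (Delaunay network statistics over nuclear centers,
aggregation-assay areas, invasion counts). This vignette records the models,
the tunable parameters, the numerical conventions, and the design choices
that were genuinely open — and what the synthetic-scene tests do and do not
demonstrate about real data.

## Segmentation

Nuclei are segmented from the DAPI channel in four steps: a mean (box)
filter of radius `smoothing_radius` (pixels, default 1; summed-area-table
implementation, border windows renormalized by their in-image pixel count),
Otsu thresholding, connected-component labeling, and an area filter
(`min_area`, default 5 px²).

*Otsu.* The threshold maximizes the between-class variance
$\sigma_b^2(t) = w_0 w_1 (\mu_0 - \mu_1)^2$ over all histogram bin
boundaries; pixels strictly above the returned value are foreground. Ties
are broken toward the smallest qualifying threshold so results are
deterministic; a histogram with fewer than two occupied bins (a flat image)
is an error at the `otsu_threshold()` level and an empty result with a
warning at the `segment_objects()` level. Images are binned into 256 equal
bins between their observed minimum and maximum before thresholding.

*Connectivity and boundaries.* Foreground connectivity defaults to 8,
matching the Moore neighborhood used by the boundary tracer. Boundaries are
traced clockwise with the Moore–Neighbor algorithm starting at each
object's leftmost-uppermost pixel, entered from the west (the direction a
row-major raster scan arrives from). Tracing stops when the start pixel is
re-entered from that same initial direction (Jacob's criterion), which
avoids premature termination on contours that revisit the start pixel.
Labels are assigned in raster-scan order of each object's first pixel.

*Conventions.* All coordinates are 0-based `(row, col)` with pixel centers
at integer positions; centroids are arithmetic means of pixel coordinates;
object area is exactly the foreground pixel count (never a contour-polygon
area).

*Limitations.* Touching nuclei are not split — there is no watershed or
declumping step, and two merged nuclei count as one object. The synthetic
scenes guarantee separation, so passing tests say nothing about clumped
real monolayers. Likewise Otsu assumes a foreground/background contrast; a
noisy image with no objects will threshold its noise floor, so empty-field
detection must come from experimental controls, not from the segmenter.

## Cell networks

Nuclear centers are connected by Delaunay triangulation (computed with
`deldir`). Edge lengths are Euclidean internuclear distances; triangle
("triplet") areas come from the shoelace formula. Two numerical choices
matter:

* *Cocircular tie-break.* Four (or more) cocircular points admit several
  valid triangulations — on lattice-like layouts this is the rule, not the
  exception. Adjacent triangle pairs whose four vertices are cocircular
  (|in-circle determinant| ≤ 1e-9 × quad-diameter⁴, a scale-free test) are
  flipped toward the diagonal whose sorted endpoint coordinates are
  lexicographically smallest. The result is platform-independent: the unit
  square always uses the (0,0)–(1,1) diagonal.
* *Border control.* Sliver triangles along the convex hull can dominate
  mean areas in sparse fields. `network_summary()` therefore accepts an
  `edge_cutoff` (default `"auto"` = 1.5 × median edge length): edges longer
  than the cutoff, and every triangle containing one, are excluded.
  Unfiltered summaries remain available by passing `edge_cutoff = NULL`,
  and both are worth reporting when layouts differ strongly in density.

Fewer than three centers, or an all-collinear set, is a degenerate-geometry
error. When a cutoff removes everything the summary carries zero counts and
`NaN` means rather than erroring.

`compare_networks()` performs the two-tailed pooled-variance *t* on
**per-image mean** features: the image is the biological replicate, and
pooling thousands of triangles across images would pseudo-replicate. The
package intentionally supports only the per-image unit.

## Internuclear profiles

For every contiguous pair (Delaunay edge no longer than a cutoff, default
1.5 × median edge length), intensity is sampled by bilinear interpolation at
100 equally spaced points on the closed segment between the two nuclear
centers. Position 1 is the center of nucleus *i*, position 100 the center
of nucleus *j*.

*The "position 50" convention.* With 100 samples the geometric midpoint of
the segment falls between positions 50 and 51 (at continuous coordinate
u = 50.5). Throughout the package "position 50" denotes this midpoint:
`profile_summary()` reports the membrane intensity as the mean-profile
value at position 50, and geometric compensation anchors the interface at
u = 50.5. This keeps the identity property exact — a profile whose
interface is already at fractional position 0.5 passes through compensation
unchanged — while a planted midline ridge lands at sampled position 50 or
51. Similarly, a perinuclear offset of d = 0.25 of the internuclear
distance produces maxima at the sample points nearest t = 0.25 and
t = 0.75, which are positions 26 and 75.

*Geometric compensation.* Each profile is reparameterized by the piecewise-
linear warp fixing positions 1 and 100 and sending the interface coordinate
u_int = 1 + 99·t_int to 50.5, then resampled linearly onto the integer
grid. The warp is monotone, so extremes are preserved up to resampling.

*Interface detection.* For real images the interface is taken as the
intersection of the pair segment with the shared Voronoi boundary of the
two centroids. Because that boundary lies on the perpendicular bisector,
the intersection is the segment midpoint (t = 0.5) whenever the pair is
truly adjacent — an objective, parameter-free convention that coincides
with the planted interface in synthetic scenes. Asymmetric interfaces
(e.g. from unequal cell sizes estimated by other means, or from planted
truth) can be supplied per pair via `interface_positions`; compensation is
exercised against such inputs in the tests. Intensities are not
background-subtracted: raw values are primary, and any background model is
the caller's responsibility.

*Peaks and classification.* Local maxima of the per-position mean are
scored by topographic prominence (the drop to the higher of the two key
saddles); the default prominence threshold is 20% of the mean profile's
dynamic range. `classify_localization()` then applies transparent rules:

* **membranous** — the dominant peak lies in positions 45–55 and the
  membrane enrichment (mean intensity at positions 45–55 over the whole-
  profile mean) is at least 1.2;
* **perinuclear** — two off-center maxima symmetric about the interface
  (|p_left + p_right − 101| ≤ 8) dominate, with the membrane intensity
  below both;
* **diffuse_absent** — anything else, including structureless profiles
  (dynamic range below 20% of the profile mean).

The thresholds are exposed via `localization_thresholds()`; the defaults
were chosen once from the geometry of the planted phenotypes and are not
tuned per dataset.

`compare_profile_maps()` applies the two-tailed Wilcoxon signed-rank to the
100 paired per-position means — the pairing unit is the position, the only
reading under which a paired rank test on profile data is well-defined.
Whether maps should pool pairs across replicate images or average per image
first is application-dependent; the pipeline pools pairs but records
per-image provenance in the map's `pairs` table so either aggregation can
be recomputed.

## Statistics

`student_t()` is the classical pooled-variance test (Welch's correction
available behind `welch = TRUE`, but pooled is the default to match the
stated test convention of the assays this package serves). Zero-variance
inputs are flagged (`p = 1` for equal means, a `degenerate` flag with an
infinite statistic otherwise) rather than raised as errors, because
pipelines must survive degenerate synthetic inputs.

`wilcoxon_signed_rank()` drops zero differences (the classic convention;
the alternative Pratt treatment is not implemented), ranks absolute values
with midranks, and computes the two-tailed p as
$P(|W - \mu| \ge |w - \mu|)$ with $\mu = n(n+1)/4$. For up to 25 nonzero
differences the null distribution is exact — a dynamic program over doubled
ranks, identical to enumerating all $2^n$ sign assignments, including tied
ranks. Beyond that a normal approximation with continuity correction and
the tie-corrected variance $n(n+1)(2n+1)/24 - \sum(t^3 - t)/48$ is used.

No multiple-testing correction is applied anywhere; all reported p-values
are raw, and the pipeline's `results.json` says so explicitly.

## Synthetic scenes

The generator plants ground truth first and renders images from it, so
every downstream measurement has a known target.

* *Layouts.* `hexagonal` places cells on a jittered triangular lattice
  (mean spacing 20 px, jitter sd 1 px by default, nucleus radius 4 px) —
  a compact epithelial monolayer. `random_poisson` is hard-core uniform
  placement — a scattered phenotype. Infeasible requests (field too small,
  density too high) error rather than silently overlapping.
* *Cell regions.* Voronoi polygons of the planted centers clipped to the
  field. The membrane is a tent-profile ridge over the shared Voronoi
  boundary (full width 2 px, peaking exactly on the edge, i.e. at the
  perpendicular bisector), which puts the planted cadherin maximum of an
  adjacent pair exactly at the pair interface. Recorded pair interfaces are
  restricted to pairs whose center-to-center segment actually crosses their
  shared edge; marginal corner-neighbors are excluded.
* *Phenotypes.* Each cell's `expression_level` (default 5000 intensity
  units) is split across membrane, perinuclear and cytoplasm fractions
  summing to 1. Presets: wild-type-like `phenotype_membranous()`
  (0.7/0/0.3), mutant-like `phenotype_perinuclear()` (0/0.6/0.4, offset
  d = 0.25 — perinuclear spots at fraction d of each internuclear distance
  toward the neighbor), and `phenotype_diffuse()` (pure cytoplasm). Every
  compartment is renormalized to its exact intensity budget after
  rasterization, so with noise off the rendered per-cell total equals
  `expression_level` to machine precision; a cell lacking a compartment
  (no contiguous neighbor) re-routes that fraction to cytoplasm.
* *Nuclei.* Gaussian blobs of sd = nucleus radius / 2 and peak 1000 — the
  simplest shape Otsu reliably thresholds, recovering centroids well within
  1 px of the planted centers.
* *Noise.* Constant background (default 10), additive Gaussian read noise
  (default sd 2, i.e. well under a fifth of the planted signal), optional
  Poisson shot noise via a gain parameter (off by default). Each scene uses
  one private RNG stream seeded explicitly; the caller's RNG state is
  untouched and regeneration is bit-exact.
* *Serialization.* Channels are written as 16-bit TIFFs after linear
  scaling, with the scaling recorded in the truth JSON so original
  floating-point values are recoverable without 8-bit saturation.

What the scenes do **not** emulate: optics (no PSF, no chromatic offset,
no uneven illumination), 3-D structure, touching or dividing nuclei,
autofluorescence, or intensity variation between cells of one condition.
Passing the planted-recovery tests therefore validates the computational
chain — segmentation, geometry, profiling, statistics — not the robustness
of these algorithms to real acquisition artifacts. Microscope pixel size is
never modeled; all geometry is in pixel units.

## Validation problem sizes

The test suite and `scripts/acceptance.R` validate against independent
oracles at sizes chosen to make the checks exhaustive yet quick: 200 random
histograms against a brute-force Otsu search; full sign-flip enumeration of
the signed-rank null for all n ≤ 12; the empty-circumcircle property
checked point-by-point for 50 random sets of up to 50 points; convex-hull
area conservation on 100 random sets; 20 seeds per phenotype for peak
recovery (25-cell monolayers); 60 scenes for classification accuracy;
5 images per group for the network and aggregation discriminations; and a
radius grid of 8–32 px for the area-scaling exponent. These sizes give the
binomial recovery rates and regression fits enough resolution for the
95%-recovery and ±0.05-exponent checks without large simulations.

## Known limitations

* No declumping: merged objects count once (affects dense invasion filters
  and confluent monolayers).
* Otsu on an object-free noisy image thresholds noise; blank-field handling
  needs experimental controls.
* The localization rules assume profiles from roughly isotropic monolayers;
  elongated cells would shift the perinuclear symmetry window.
* Interface detection from centroids alone cannot produce asymmetric
  interfaces; supplying external interface estimates is supported but not
  automated.
* Absolute pixel² areas are microscope-dependent; only within-study
  comparisons are meaningful.
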