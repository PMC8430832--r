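# epiquant

Quantification of epithelial organization and cadherin localization in
two-channel fluorescence microscopy.

Loss of membranous E-cadherin is the cellular hallmark of diffuse gastric
cancer: pathogenic *CDH1* variants leave the protein stranded in the
cytoplasm or the perinuclear endoplasmic reticulum instead of at cell–cell
junctions, and the epithelium loosens. `epiquant` implements the image
computations used to demonstrate such a phenotype *in vitro*:

* **Nuclei segmentation** — mean-filter denoising, Otsu thresholding
  (foreground strictly above the threshold that maximizes the between-class
  variance w₀w₁(μ₀−μ₁)²), connected components, Moore–Neighbor boundary
  tracing with Jacob's stopping criterion, and geometric centers
  (`segment_objects()`, `count_invasive_nuclei()`).
* **Cell-network topology** — Delaunay triangulation over nuclear centers;
  edge lengths (internuclear distances) and triangle ("triplet") areas by
  the shoelace formula summarize epithelial packing
  (`build_network()`, `network_summary()`, `compare_networks()`).
* **Internuclear profiling** — bilinear-interpolated intensity at 100
  positions along the segment joining two contiguous nuclei (position 1 =
  center of nucleus 1, position 100 = center of nucleus 2, position 50 =
  plasma membrane), geometric compensation anchoring the detected cell–cell
  interface at position 50, peak finding with topographic prominence, and a
  rule-based membranous / perinuclear / diffuse localization call
  (`extract_profiles()`, `compensate_profiles()`, `profile_summary()`,
  `classify_localization()`).
* **Assay quantification** — slow-aggregation assay areas in pixel² and
  invasion-filter nuclei counts (`segment_aggregates()`, `assay_summary()`,
  `compare_assays()`).
* **Statistics** — two-tailed pooled-variance Student's *t* and a Wilcoxon
  signed-rank test with an exact tie-aware null (sign-flip enumeration up to
  n = 25, continuity-corrected normal approximation beyond), returned as
  tidy-able `comparison_result` objects (`student_t()`,
  `wilcoxon_signed_rank()`).
* **Synthetic scenes** — a generator that plants epithelial monolayers with
  membranous, perinuclear or diffuse cadherin, cell aggregates of known
  rasterized area, and invasion filters with known counts, all with
  machine-readable ground truth and bit-exact seeding
  (`generate_monolayer()`, `generate_aggregation_scene()`,
  `generate_invasion_filter()`, `write_scene()`).

All functions take matrices / data frames and return tibbles (or small S3
objects with `tidy()`, `glance()` and `autoplot()` methods), so analyses
compose with the pipe. Coordinates are 0-based `(row, col)` with pixel
centers at integer positions.

## Worked example

Simulate a wild-type-like monolayer, segment it, and quantify localization:

```r
library(epiquant)

scene <- generate_monolayer(
  layout_params(n_cells = 25, packing = "hexagonal", mean_spacing = 20),
  phenotype_membranous(), noise_params(), seed = 1)

nuclei  <- segment_objects(scene$nuclei_image, segmentation_params())
network <- build_network(nuclei)
network
#> cell network: 25 nodes, 64 edges, 40 triangles

map <- scene$cadherin_image |>
  extract_profiles(network) |>
  compensate_profiles()
map
#> profile map: 56 pairs x 100 positions (compensated)

s <- profile_summary(map)
s$peak_positions          # 50  — single dominant peak at the membrane
s$membrane_intensity      # 79.6
classify_localization(s)
#> localization: membranous (membrane enrichment 3, symmetry -)
```

The same pipeline on a perinuclear (mutant-like) scene calls
`perinuclear` (mean-profile maxima near positions 25 and 76, symmetric
about the interface), and the two conditions separate sharply:

```r
mutant <- generate_monolayer(
  layout_params(n_cells = 25, packing = "hexagonal", mean_spacing = 20),
  phenotype_perinuclear(), noise_params(), seed = 2)
mmap <- mutant$cadherin_image |>
  extract_profiles(build_network(
    segment_objects(mutant$nuclei_image, segmentation_params()))) |>
  compensate_profiles()

compare_profile_maps(map, mmap)
#> Wilcoxon signed-rank (normal approx.)
#>   statistic = 874, n_effective = 100, two-tailed p = 1.3872e-08
```

`autoplot(map)` draws the pairs × positions heatmap,
`plot_profile_panels(extracted, compensated)` the two-panel map figure, and
`autoplot(network)` the Delaunay graph. `run_pipeline()` executes the whole
analysis (segmentation → networks → profiles → aggregation → statistics)
from a single YAML/JSON configuration and writes CSV tables plus a
deterministic `results.json`.

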