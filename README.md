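# imctme

Spatial single-cell analysis of the tumor microenvironment from imaging
mass cytometry (IMC), with a companion scRNA-seq stage.

## The problem

Multiplexed tissue imaging of paired tumor and adjacent lung tissue can
reveal whether specific T-cell populations interact in space — for
example, whether activated CD8⁺ T cells expressing the killer-cell lectin
receptor KLRF1 sit near CD4⁺ T cells expressing its ligand AICL, and
whether that interaction is lost inside tumors. Answering this requires a
chain of well-defined computations on per-cell data derived from ion-count
images: spillover-corrected and variance-stabilized marker signals,
Boolean gating into immune compartments, graph clustering, a reproducible
tumor/stroma segmentation, nearest-neighbor distance and neighborhood
statistics, and paired frequency testing across patients. `imctme`
implements that chain as composable, tested functions on tibbles, plus the
matching scRNA-seq steps (count normalization, marker-predicate gating of
T and CD8 cells, Wilcoxon marker ranking, and binned-control module
scores for progenitor-exhausted vs terminally exhausted CD8 states).

The core quantities:

* **Compensation** — per cell, solve `raw = t S` for `t ≥ 0` (non-negative
  least squares), where `S` is the channel spillover matrix; then
  `tfm = asinh(comp / 2)`.
* **Tumor mask** — sum CK18 + αSMA, Gaussian blur (σ = 0.8), Otsu
  threshold (256-bin), ImageJ count-based open (5 iterations, count 1),
  drop objects < 200 px, dilate (9 iterations, count 1), then the exact
  Euclidean distance-to-tumor transform.
* **Neighborhoods** — per reference cell, distance to the nearest member
  of a target cluster in the same ROI (pooled median as summary) and the
  number of target cells within 20 μm (inclusive radius).
* **Cluster frequencies** — per patient × tissue, each cluster's fraction
  of its parent lineage, compared with Wilcoxon/t/Friedman tests and
  Benjamini–Hochberg adjustment.

A synthetic-data generator (`default_scenario()`, `simulate_roi()`,
`simulate_expression()`) produces ground-truth images, masks, cell tables
and expression matrices with the statistical structure the analysis
assumes, so every stage is testable end to end without downloads.

## Worked example

Simulate one adjacent-tissue ROI, run the imaging pipeline, and quantify
the spatial attraction between the KLRF1-like CD8 population and its AICL⁺
CD4 partner:

```r
library(imctme)
library(dplyr)

sc  <- default_scenario(seed = 1)
sim <- simulate_roi(sc, roi_index = 1, tissue = "adjacent", render = TRUE)

cells <- extract_cells(sim$image, sim$mask,
                       patient_id = "P01", tissue_type = "adjacent") |>
  compensate(sc$spillover) |>
  transform_markers(cofactor = 2) |>
  partition_compartments(c(CD19 = 1.2, CD3 = 1.2, CD45 = 1.2))

count(cells, gate)
#> # A tibble: 3 × 2
#>   gate           n
#>   <fct>      <int>
#> 1 B             55
#> 2 T           1103
#> 3 non_immune   347

t_cells <- filter(cells, gate == "T") |>
  cluster_cells(resolution = 0.2, seed = 1)

cluster_profile(t_cells,
                markers = c("CD3", "CD4", "CD8", "KLRG1", "KLRF1", "AICL"))
#>       CD3   CD4   CD8 KLRG1 KLRF1  AICL
#> C01 -0.28  1.04 -1.00 -1.00 -0.58 -0.58     # CD4 T cells
#> C02  0.24 -0.99  1.01 -1.00 -0.58 -0.58     # CD8 T cells
#> C03 -1.37  0.96 -1.00  1.01 -0.57  1.73     # activated AICL+ CD4
#> C04  1.41 -1.00  0.99  0.99  1.73 -0.58     # KLRF1+ CD8
```

The four clusters recover the four simulated T-cell populations exactly
(adjusted Rand index 1 against the generator's truth). Using the truth
labels, the nearest-member distances show the attracted pair in direct
proximity:

```r
t_cells$cluster <- sim$cells$population[match(t_cells$cell_id,
                                              sim$cells$cell_id)]
tidy(compare_neighborhoods(t_cells, "CD8_KLRF1",
                           target_clusters = c("CD4_AICL", "CD4_T")))
#> # A tibble: 2 × 5
#>   target_cluster n_ref_cells n_with_target median_distance_px ...
#> 1 CD4_AICL                45            45               18.6
#> 2 CD4_T                   45            45               23.3
```

Each KLRF1-like CD8 cell lies a median 18.6 px (= 18.6 μm at 1 μm/px) from
the nearest AICL⁺ CD4 cell — closer than to the 6-fold more abundant bulk
CD4 population, the signature of the simulated attraction. Tumor-vs-adjacent
depletion of such a population is tested on paired per-patient frequencies:

```r
freqs <- simulate_cluster_frequencies(n_patients = 10, seed = 4)
wide  <- tidyr::pivot_wider(select(freqs, patient_id, tissue_type, fraction),
                            names_from = tissue_type, values_from = fraction)
tidy(run_test(wide$tumor, wide$adjacent,
              "wilcoxon_signed_rank", alternative = "less"))
#> # A tibble: 1 × 5
#>   method               alternative statistic  p_value     n
#> 1 wilcoxon_signed_rank less                0 0.000977    10
```

All ten patients have a lower tumor fraction, giving the smallest
attainable one-sided signed-rank p-value at n = 10 (1/1024).

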