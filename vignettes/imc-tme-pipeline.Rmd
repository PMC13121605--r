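---
title: "Methods: spatial single-cell analysis of tumor and adjacent tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial single-cell analysis of tumor and adjacent tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(imctme)
```

## Scope and model

`imctme` implements a single-cell spatial analysis of imaging mass cytometry
(IMC) data from paired tumor and adjacent tissue, together with the
scRNA-seq gating and gene-module scoring stage that links imaging phenotypes
(a KLRF1-like activated CD8 population and its AICL-expressing CD4 partner)
to transcriptomic cell states. The pipeline consumes multichannel ion-count
images and segmentation masks; segmentation itself (the Ilastik /
CellProfiler stage of the usual IMC workflow) is out of scope, as are raw
.mcd parsing, hot-pixel filtering and any wet-lab or flow-cytometry
analysis.

The stages, each an exported function working on a per-cell tibble:

1. **Ingest** — `extract_cells()` averages each channel over every mask
   label (one cell per nonzero label; centroid = unweighted mean of member
   pixels, 0-based, x = column). `compensate()` undoes channel spillover
   cell-wise; `transform_markers()` applies `asinh(x / cofactor)`.
2. **Gating** — `apply_gate()` evaluates threshold/polygon predicate trees;
   `partition_compartments()` reproduces the four-compartment hierarchy
   B / T / other-immune / non-immune on CD19, CD3, CD45.
3. **Clustering** — `cluster_cells()` z-scores markers over the whole
   gated table, builds a Jaccard-weighted kNN graph and partitions it with
   Leiden modularity; `split_cluster()` re-gates one mixed cluster;
   `cluster_profile()` produces the cluster-by-marker z-score heatmap.
4. **Tumor mask** — `build_tumor_mask()` re-implements the ImageJ macro
   (below); `assign_tissue_region()` maps rounded centroids onto the mask
   and distance map.
5. **Spatial statistics** — `nn_distance_to_cluster()`,
   `neighbors_within()` and `compare_neighborhoods()` quantify
   nearest-member distances and 20-micron neighbor counts between annotated
   populations.
6. **Group statistics** — `cluster_frequencies()`, `run_test()` (Wilcoxon
   signed-rank / rank-sum, paired and Welch t, Friedman) and `bh_adjust()`.
7. **scRNA stage** — `normalize_counts()`, `gate_t_cells_rna()` /
   `gate_cd8_rna()`, `module_score()`, `rank_markers()`, `score_compare()`.
8. **Synthetic data** — `default_scenario()`, `simulate_roi()`,
   `simulate_expression()` and friends generate ground-truth inputs for
   every stage.

## Spillover compensation

Observed per-cell signal is modeled as `raw = t S`, where `S` is the square
spillover matrix (rows = emitting channel, unit diagonal, off-diagonal
fractions in `[0, 1)`). Because ion counts cannot be negative, `t` is
recovered by non-negative least squares per cell, the common practice in
mass-cytometry compensation. Cells whose unconstrained solution is already
non-negative take the direct solve (identical result, much faster); the
Euclidean residual norm is kept in `comp_residual` for QC. Markers missing
from `S` pass through unchanged with a warning rather than erroring, so
partial panels remain usable.

The arcsinh cofactor defaults to 2, the value at which ion-count data of
this intensity range yields well-behaved marker distributions.

## Tumor mask macro

`build_tumor_mask()` reproduces an ImageJ macro step for step: sum the CK18
and alpha-SMA channels; Gaussian-filter with sigma 0.8 px (separable kernel
truncated at `ceiling(4 sigma)`, reflective boundary — a constant image is
unchanged); threshold with Otsu on a 256-bin min–max-scaled histogram
(ImageJ's 8-bit conversion; the scaling and chosen bin are logged); smoothen
with *open*, 5 iterations at a neighbor count of 1; delete 8-connected
objects smaller than 200 px (200 px exactly is kept); dilate 9 iterations at
count 1. Instead of storing the inverted mask and its distance map
separately, the result carries the binary tumor mask plus the Euclidean
distance-to-tumor map — the same information without a redundant array.

Two deliberately non-standard choices:

* **Count-based morphology.** ImageJ's binary erode/dilate acts on a pixel
  when at least `count` of its 8 neighbors are background/foreground. This
  differs from structuring-element morphology (and from what image packages
  provide), so it is implemented directly; pixels beyond the border count as
  background. Note a count-1 dilation grows diagonally too, so 9 iterations
  reach up to `9 * sqrt(2)` px from the boundary.
* **Exact distance transform.** The Euclidean distance map uses the exact
  two-pass lower-envelope algorithm (compiled); squared distances are exact
  integers and are tested for exact equality against an O(n^2) brute force.

Otsu ties are broken toward the lowest qualifying threshold; a constant
image returns the lowest bin with a warning. Centroids are mapped to pixels
by round-half-up, clamped into the image with a warning when outside.

## Clustering and the resolution choice

Markers are z-scored once over the entire gated table (population sd;
constant columns become zeros with a warning). The graph uses each cell's
k = 30 Euclidean nearest neighbors (the PhenoGraph convention; ties broken
by cell index, k reduced with a warning when `n <= k`), edges weighted by
the Jaccard overlap of the two neighbor sets (self included), and Leiden
modularity at a user-set resolution, deterministic given the seed. One
engine serves both data types: IMC tables default to resolution 1.0, and
the RNA stage is typically run at 1.3 (T/NK map) or 0.6 (CD8 subsets).

A caveat worth stating precisely: on a Jaccard-kNN graph, modularity at
resolution 1 assigns a *higher* objective to sub-partitions of a large
homogeneous group than to the group itself (we measured Q = 0.71 for a
7-way split of two clean Gaussian blobs versus Q = 0.50 for the true 2-way
partition). Over-partitioning at default resolution is therefore expected
behavior, which practitioners resolve by merging or annotating clusters.
For benchmarks where recovery of a known partition is the question (the
package's ground-truth tests), the same engine is evaluated at resolution
0.2, where the modularity optimum has the true granularity; this is a
property of the objective, not a tuning of the data.

UMAP (`embed_2d()`) is deterministic given its seed (single-threaded SGD,
random initialization below n = 20 where spectral initialization is not
well-defined) and is used for display only — no statistic reads it.

## Spatial statistics conventions

"Distance of a cell to a cluster" is read as the distance to the *nearest
member* of that cluster within the same ROI, and the cluster-level summary
is the median over all reference cells pooled across ROIs — the reading
consistent with per-cell box plots and with reported cell counts spanning
multiple ROIs. Reference cells in ROIs where the target cluster is absent
are recorded as missing and excluded from the pooled median rather than
imputed. Neighbor counts use an inclusive radius (`<=`), 20 microns by
default at 1 micron/px, self-pairs excluded. Pooled medians are not
symmetric in the two cluster roles (the nearest-member map is not an
involution); the per-cell tables make the direction explicit.

## Group statistics

The hypothesis tests are deliberately thin wrappers over the standard
implementations (exact small-sample Wilcoxon enumeration when tie-free and
n < 50, tie-corrected normal approximation with continuity correction
otherwise; Welch t; Friedman chi-square), with two conventions fixed:
zero differences in the signed-rank test are dropped (Wilcoxon's original
convention), and fully tied samples return p = 1 rather than NaN. The test
is always an explicit argument — no normality-driven automatic selection.
BH adjustment is the standard step-up procedure.

## scRNA-seq stage

Counts are normalized per cell to the median library size and
log1p-transformed; gating predicates (`CD3E > 0 & (CD3D > 0 | CD3G > 0) &
TRAC > 0`; CD8 positivity with gamma-delta and CD4 exclusion) operate on
*raw counts*, matching the "> 0" formulation and making them robust to
normalization choices. `module_score()` uses the binned-control
construction standard in the field: genes are binned into 25 equal-size
bins by dataset-mean expression, 50 control genes are drawn (seeded,
without replacement, capped at bin size) per module gene, and the score is
the module mean minus the control mean — approximately invariant under
adding a constant to all normalized values. Both parameters are exposed;
with fewer genes per bin than `n_ctrl` the draw is the whole bin and the
seed becomes immaterial. Marker ranking reports
`log2((mean(expm1 a) + eps) / (mean(expm1 b) + eps))` with `eps = 1e-9`
and Wilcoxon rank-sum p-values, BH-adjusted across the tested genes.
Tpex/Tex gene lists are user configuration (shipped examples are synthetic
module names); the generator writes its own ground-truth lists so tests
never depend on unpublished tables.

## The synthetic-data generator

`default_scenario()` fixes the study conditions: 1000 x 1000 px ROIs at
1 micron/px; six populations (CD4 T, a rare activated AICL+ CD4 population,
CD8 T, an attracted KLRF1-like CD8 population, B cells, epithelial cells)
with log-normal per-pixel marker means (sdlog 0.25) on a 12-marker panel;
cells rendered as non-overlapping radius-3 disks (hard-core rejection with
10 retries, then the cell is dropped with a warning); spillover of a few
percent between adjacent channels; Poisson counting noise per pixel. The
attracted population is placed as Gaussian offspring (sigma 10 px, mean
0.65 offspring per parent) around the AICL+ CD4 parents — a Neyman–Scott
construction chosen for its transparency; because the offspring mean is
below 1, the attraction is read from the child side (every child is near a
parent; many parents have no child). B-cell abundance equals the parent
population's so it serves as the matched independent control in spatial
tests. Tumor-tissue ROIs add a CK18/aSMA disk-shaped blob (28% of the ROI
side as radius) that thins the attracted pair inside the blob and reduces
the attracted population six-fold at tissue level — from about 6% of CD8
cells in adjacent tissue to about 1% in tumor, with patients carrying
shared log-normal abundance effects so tissue contrasts are paired. The
per-ROI count of the rare AICL+ CD4 population (about 60 cells) follows the
per-ROI numbers reported for such populations rather than their global
frequency, which would leave too few cells per ROI for any spatial
statistic. The expression generator uses negative-binomial counts with
population-specific means: gate genes at high mean/low dispersion where
"on" (so lineage gates are near-deterministic), structural zeros where
absent (NK cells cannot pass the T gate by construction), a 16-fold KLRF1
ratio between the KLRF1-high and other CD8 populations, and 15-gene
Tpex/Tex modules shifted 4-fold in their designated populations.

What the generator does *not* emulate: segmentation errors, hot pixels and
channel drift, cell-shape variation, spatial marker gradients within
populations, ambient RNA and doublets, or library-size heterogeneity beyond
the negative binomial. Passing tests therefore demonstrate correctness of
the computations under the stated statistical structure, not robustness to
every artifact of real acquisitions.

All randomness derives from the scenario seed; each ROI uses a
deterministically indexed substream, so studies are reproducible ROI by
ROI.

## Validation problem sizes

The test suite validates each image/geometry primitive against brute-force
enumeration on 100 random instances (up to 64 x 64 masks, up to 200
cells); spillover round-trips noiseless mixing to 1e-8 and Poisson-noised
mixing (channel means 50–500 counts) to under 5% median error on 1000
cells; clustering recovery, spatial attraction, and module-score separation
are each checked over 100 seeded replicates on the default scenario
(spatial and clustering runs use the truth-table pathway of
`simulate_roi()`, which samples the same counting model without rendering
images); mask recovery uses 100 seeds of 384 x 384 ROIs with 55 px blobs
at SNR 5; the paired depletion test is checked over 500 replicates at 10
paired patients; and each hypothesis test's size is estimated from 10,000
null simulations at n = 10. One full-size 1000 x 1000 rendered ROI
exercises the end-to-end path. These sizes are the package's validation
design; every number they produce is recomputed at test time.

## Known limitations

* Compensation assumes the supplied spillover matrix is correct; no
  spillover estimation from single-stained controls is provided.
* The gating thresholds and any polygon vertices are dataset-specific
  configuration; the package ships no trained defaults for real panels.
* Published cluster labels of real datasets cannot be regenerated
  bit-exactly (the original clustering seeds are unreported); analyses of
  deposited data should consume the deposited annotations.
* Spatial statistics are within-ROI only; no edge correction, Ripley-type
  summaries, or cross-ROI geometry.
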