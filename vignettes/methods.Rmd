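---
title: "Methods: reconstructing and clustering dry woodland change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing and clustering dry woodland change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drywoodlands)
```

# The problem

Tropical dry woodlands — dry broadleaf forest, savanna, and thorn/xeric
shrubland where woody cover dominates — are poorly served by any single
land-cover product: candidate maps differ in native resolution, class legend,
and error structure. This package implements a complete analysis chain for
reconstructing long-term woodland cover change from such heterogeneous
sources and summarizing it ecologically:

1. **Harmonization.** Every source is reduced to a binary woodland/other map
   (class selection for categorical products, a percent threshold for
   fractional ones) and aggregated to a common analysis grid as *fractional
   cover* — the block mean of the binary map, a value in [0, 1] per cell.
2. **Accuracy screening.** A two-observer point sample provides reference
   cover. For each candidate map, both reference and map are binarized at
   each threshold of a sweep (default 15–22%); an error matrix gives overall
   accuracy (OA) and user's accuracy of the woodland class (UA). A map is
   retained only if OA ≥ 0.70 and UA ≥ 0.90 at its best threshold.
3. **Ensemble.** Retained maps are fused per cell, weighting each map's
   cover by its UA: `WL_E = sum(UA_i * WL_i) / n`.
4. **Change reconstruction.** The contemporary ensemble joins historical
   cover maps into a multi-epoch series (default epochs 1880, 1930, 1975,
   1985, 1995, 2010, 2020). Cells never exceeding 5% cover are masked as
   persistent non-woodland. Change maps are absolute percentage-point
   differences; area accounting telescopes exactly across periods.
5. **Archetypes.** Per-cell cover trajectories, aggregated 10× to a coarse
   grid, are clustered with a one-dimensional self-organizing map (SOM) into
   k prototype trajectories ("archetypes of woodland change"; default k = 6).
6. **Species overlays.** Species ranges rasterized to the coarse grid yield
   richness maps; Pearson correlation of richness with contemporary cover is
   compared between threatened and non-threatened groups, and per-range
   cover trajectories, archetype composition and median richness per
   archetype are tabulated.

Everything runs against a synthetic world with known truth, so each stage has
a measurable recovery target.

# Tunable parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| binarization sweep | 15–22 | percent cover | range over which UA is maximized per source |
| screening floors | OA 0.70, UA 0.90 | proportion | commission control: retained maps rarely call non-woodland "woodland" |
| persistent non-woodland cutoff | 0.05 | cover fraction | "5% or less in every epoch" defines the study domain |
| aggregation factor | 10 | — | analysis grid to coarse (trajectory) grid, the 300 m → 3 km step |
| ensemble mode | `as_printed` | — | divide by n (formula as published); `weight_normalized` divides by ΣUA giving a convex average |
| SOM k | 6 | clusters | diagnostics reported for 3–10; the choice is a config value, never auto-applied |
| SOM schedule | 100 passes, lr 0.05→0.01, radius 0.25→0 over half the passes, 5 restarts | — | see below |
| observer noise | sd 0.03 | cover fraction | realistic disagreement between visual interpreters of high-resolution imagery |
| template noise | sd 0.02 | cover fraction | spatially smoothed cell-level deviation from archetype trajectories |

Thresholds are *inclusive* (`cover >= t`) for binarization, while the
persistence mask uses `cover <= cutoff`: woodland begins strictly above the
cutoff, and a cell exactly at a binarization threshold counts as woodland.
Fractions are stored in [0, 1]; all user-facing thresholds are percents,
converted only at the API boundary.

## Interval fusion

Observers report the 10%-wide interval containing their estimate. An interval
is represented by its midpoint; the fused value is the midpoint average
rounded to the nearest 5%, with exact ties rounded up. Both conventions are
fixed and tested by exhaustive enumeration of all 100 interval pairs.

## Ensemble normalization

The published formula divides the UA-weighted sum by the source count n, so
the "weighted average" shrinks toward zero whenever accuracies are below 1
(three sources with UA 0.9/0.8/1.0 and cover 0.2/0.5/0.8 give 0.46, whereas
the convex weighted average gives 0.512). Which of the two the original
computation used cannot be determined from the text, so both modes are
implemented; `as_printed` reproduces the formula literally and is the
default, and the mode is recorded in the output. At cells where some sources
are nodata, both the sum and the denominator are restricted to the valid
sources.

# The synthetic world

`generate_world()` emulates, with known truth:

- a spatially autocorrelated true fractional-cover surface per epoch, built
  from six archetype templates (three levels of continuous decline, three
  forest-transition shapes) assigned to contiguous Voronoi patches, plus
  moving-average-smoothed Gaussian noise (sd 0.02) clipped to [0, 1];
- source maps at native resolutions with per-source omission/commission flips
  (binary/categorical) or bias plus noise (fractional), so user's accuracy is
  analytically known from the rates and the true prevalence:
  `UA = p(1-om) / (p(1-om) + (1-p)com)`;
- two-observer validation samples with minimum-distance rejection sampling
  (capped at 1000·n attempts) and bounded observer noise;
- rectangular-block ecoregions (default 8);
- species ranges grown as connected patches, threatened ones seeded with
  probability ∝ exp(affinity · cover), non-threatened ones uniformly.

What it deliberately does **not** emulate: sensor physics, cloud or seasonal
artifacts, legend ambiguity between real products, spatially structured
(rather than i.i.d.) classification error, and the sub-cell heterogeneity of
real landscapes. The last point has a visible consequence: because the
synthetic truth is smooth at fine scale, binarizing a mid-cover region at
native resolution saturates whole blocks to 0 or 1, so a binary source's
aggregated cover over-represents cover between the threshold and 1 — real
30 m products average out. A green pipeline test therefore establishes the
*mechanics* (harmonization, screening, weighting, accounting, clustering) and
the statistical contracts, not radiometric realism.

# The SOM and its numerical choices

Trajectories (rows) are clustered by an online SOM on a 1-D chain of k nodes:
best-matching unit by squared Euclidean distance (ties to the lowest node
index), Gaussian neighborhood in node space, linearly decaying learning rate.
Final hard assignments use plain nearest-prototype distance, decoupled from
the training neighborhood. A 2-D node layout is available via
`som_params(topology = "grid")`.

Three defaults deviate from textbook folklore, for a reason the package's own
recovery experiments document:

- **Weak neighborhood (radius 0.25, decaying to 0 over the first half of
  training, winner-only thereafter).** On trajectory data whose clusters are
  far tighter than their separation — exactly what archetype-structured
  landscapes produce — a strong chain neighborhood (the textbook k/2)
  reliably strands "dead" units between clusters and merges nearby cluster
  pairs. The effect is intrinsic: it is invariant to initialization, and a
  k-means oracle on the same data recovers the generator labels perfectly.
  A weak neighborhood keeps the chain's ordering role without the pathology.
- **Distance-weighted (k-means++ style) seeding** from the data rows, so all
  well-separated clusters are represented at initialization with high
  probability while prototypes remain actual data rows.
- **Best-of-5 seeded restarts by quantization error.** Online SOMs converge
  to local optima; restarts are the standard guard, and quantization error
  cleanly separates merged solutions (which pay the full inter-cluster
  distance) from correct ones. Restarts also guarantee in practice that the
  trained quantization error never exceeds its value at initialization.

With these defaults, on 2,500-coarse-cell worlds generated from the six
default templates at noise sd 0.02, assignments match generator labels with
adjusted Rand index ≥ 0.9 in at least 9 of 10 seeds (typically 10/10 with
ARI = 1), and the mean silhouette is maximal at the true k = 6 in ≥ 90% of
seeded runs. The cluster count itself is never chosen automatically:
`select_cluster_count()` reports quantization error, silhouette and empty
clusters per k, and the user sets k in the configuration.

# Other numerical conventions

- **Aggregation of partial-nodata blocks** averages the valid fine cells;
  all-nodata blocks stay nodata; non-divisible dimensions are padded with
  nodata at the bottom/right edge.
- **Change** is the percentage-point difference `(cover2 - cover1) * 100`
  (a drop from 80% to 55% is −25 points); relative change is a separately
  labelled option.
- **Area accounting** defaults to the fractional sum (Σ fraction ×
  cell area); a thresholded count (default 20%, the usual best threshold) is
  provided for sensitivity. Both agree exactly on {0,1}-valued maps. Which
  the original area figures used is unknowable from the text, so neither is
  asserted as "the" published computation — only the arithmetic consistency
  of the published per-epoch areas is an acceptance target.
- **Trajectory summaries** use the population (not sample) SD, with cells as
  the statistical unit.
- **Rasterization of ranges** uses the cell-center rule by default
  (any-overlap available); richness–cover correlations run over all unmasked
  coarse cells by default, since richness 0 is informative (presence-only is
  a switch).
- **Undefined statistics are never silently zero**: UA with no predicted
  woodland is flagged undefined and disqualified from best-threshold
  selection; zero-variance correlations raise an error; empty archetypes
  report `NA` medians.
- **Grids must be nested** (integer cell-size factors, shared origin).
  General reprojection is out of scope and fails with a clear error.
- **Raster I/O** uses the plain-text ESRI ASCII grid format with a JSON
  sidecar for metadata (epoch year, class legend, kind), because no GeoTIFF
  library is assumed available; the format round-trips exactly and keeps all
  artifacts human-readable.

# Determinism

Every generator and the SOM take an integer seed and restore the caller's RNG
state afterwards; `run_pipeline()` derives stage seeds from the master seed,
writes a manifest with parameter values and per-file MD5 digests, and
re-running a configuration reproduces the digests bit for bit.

# Known limitations

- The synthetic error model flips cells independently; spatially correlated
  commission (e.g. plantation edges) would make screening look better than
  reality warrants.
- The accuracy assessment is count-based OA/UA; area-adjusted (stratified)
  estimators from the good-practice literature are a possible extension.
- The ensemble propagates no per-pixel uncertainty and does not debias
  sources.
- Archetype naming and ecological interpretation are left to the user; the
  package reports cluster summaries only.
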