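---
title: "Multiscale reef structural complexity: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale reef structural complexity: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefwave)
```

## The model

A reef DEM mixes two sources of relief: fine-scale roughness from living
benthic cover and broad-scale topography of the calcareous matrix built by
historical accretion. `reefwave` separates them by treating every raster
row as a 1-D elevation profile and applying the maximal overlap discrete
wavelet transform (MODWT). Unlike the decimated DWT, the MODWT is defined
for any signal length, keeps every coefficient series at the signal's
length, and is shift invariant — a colony contributes the same detail
signature wherever it sits along the row.

The additive multiresolution analysis (MRA) re-expresses a profile as
`X = S_J + D_1 + ... + D_J`, where detail `D_j` carries variation at scales
of about `2^j` pixels. The package defines:

* **local component** = `D_1 + ... + D_J` (biotic, fine relief) → its
  per-pixel Ra is the *digital local complexity* (DLC);
* **global component** = `S_J` (underlying matrix) → its Ra is the
  *digital global complexity* (DGC).

Both components live on the source grid, masked wherever the DEM is, and
sum back to the DEM at every processed cell; `verify_reconstruction()`
checks this with the maximum absolute error and a Mann-Whitney U rank test
(equivalence declared at p > 0.05).

### Assumptions

* The DEM has a projected CRS with meter units and square pixels; rotated
  or non-square grids are rejected, not resampled (one standardized
  resolution is assumed upstream).
* Rows are the profile direction. The transform is 1-D by design — the
  method's definition — not a 2-D tensor wavelet; a column-wise pass can be
  emulated by transposing the input if desired.
* Profiles are circularly extended (periodic boundary), the standard MODWT
  convention; a reflection option exists for strongly trending profiles but
  is off by default since components are only interpreted through
  windowed roughness, which is insensitive to the wrap-around seam except
  within a filter width of the run ends.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| Daubechies order | 4 (db4) | — | unstated by the method's source; db4 is the common default for terrain profiles and the MATLAB `modwt` default. Configurable 1–10. |
| Levels `J` | 4 | — | detail scales up to `2^4 = 16` px ≈ 13 cm at 0.008 m pixels; deeper levels add variation below the DEM's resolving power. `DLC = Σ D_1..D_4`, `DGC = S_4`. |
| Evaluation length | 0.05 | m | the Ra window; 5 cm is the minimum digitizable colony diameter. With 0.008 m pixels the window is `round(6.25) = 6` px (half away from zero). |
| Window placement | sliding | — | one Ra per pixel, centered, truncated at run ends so output coverage equals input coverage; `tiled` (disjoint 5 cm blocks) and `strict` (partial windows masked) are available. |
| Rank-test subsample | 100,000 | cells | rank-testing tens of millions of pixels is needless; the subsample is seeded and reported. |
| Minimum run length | `2^J` | px | the maximum admissible MODWT depth for a length-N signal is `floor(log2 N)`; shorter valid runs are skipped and counted rather than processed at a reduced depth, keeping one spec per raster. |

Numerical conventions worth knowing:

* **Daubechies filters** are built by spectral factorization of the
  Daubechies polynomial (minimum-phase root selection), oriented to the
  textbook tabulation and rescaled by `1/√2` to the MODWT convention; the
  test suite pins them to the db1/db2 closed forms and to the
  orthonormality, quadrature-mirror and vanishing-moment identities.
* **Ra's mean line** is the window's arithmetic mean, not a fitted trend —
  the simplest reading of the ISO Ra definition. Ra is therefore invariant
  to adding a constant and absolutely homogeneous, which the suite asserts
  to 1e-10.
* **Chain-method analog** runs along rows (the field method is a linear
  transect): `Σ √(pixel² + Δz²) / chord`, reported per row segment and
  summarized by the median.
* **Rasterization** burns a polygon's code into pixels whose *center* lies
  inside it (even-odd rule, holes honored); overlaps resolve
  later-record-wins with a warning. Pixel centers sit at
  `origin + (index − 0.5) · pixel_size`, north-up.
* **Standard-area crop**: the subset procedure behind a fixed per-reef
  analysis area (e.g. 380 m²) is not specified by the method's source, so
  `crop_to_area()` uses a deterministic convention — the contiguous
  full-width row band whose unmasked area is closest to the target, seeded
  tie-break — documented as a convention, not a reconstruction.
* **Statistics**: Mann-Whitney switches from the exact permutation
  distribution to the tie- and continuity-corrected normal approximation
  above `min(n) = 8`; Kruskal-Wallis applies the tie correction; Dunn's z
  uses the pooled-rank variance with tie term, Bonferroni-adjusted by the
  `k(k−1)/2` pairs. The cover regression log-transforms area with the
  natural log (base does not affect R²). Pixel-scale samples make almost
  any difference "significant"; the subsample option and reported n exist
  for exactly that reason.

## What the synthetic generator emulates — and what it does not

`generate_reef_dem()` builds `base_depth + relief + texture`:

* *relief*: two orthogonal sinusoids (amplitude split evenly, default
  total 0.3 m, wavelength 1.0 m ≫ the `2^J`-pixel cutoff of 0.128 m),
  optionally plus Gaussian bumps — the broad calcareous-matrix topography;
* *texture*: Gaussian-filtered white noise with an L2-normalized kernel,
  so the pointwise sd equals `roughness_sd` (default 0.02 m) at any
  correlation length (default 0.02 m) — the fine biotic roughness;
* a masked border emulating plot-edge nodata.

Grid defaults (500×500 at 0.008 m) mirror the surveyed-plot resolution at a
desk-scale extent. Colony cover is simulated as disk-like polygons
(minimum radius 0.025 m, the 5 cm diameter floor) labelled from the five
AGRRA groups until a target cover fraction is reached.

This stated world is deliberately simple: it has a clean scale separation,
stationary texture, and disk colonies. Real reefs have overhangs collapsed
by the 2-D DEM, non-stationary roughness, reconstruction noise, and
colony shapes far from disks. A green parameter-recovery test therefore
establishes that the pipeline *orders* relief and texture intensities
correctly and that the global component dominates when texture is weak —
it does not certify absolute DLC/DGC values on field data.

Every random draw flows from one explicit seed through an isolated RNG
scope; generators are bit-reproducible and do not disturb the caller's RNG
stream.

## Design choices on genuinely open points

* The method's source is internally inconsistent about the level count
  (a four-level sum formula next to mentions of three detail levels and a
  level-five approximation). The package follows the explicit formula:
  `J` defaults to 4 with `DLC = Σ_{j≤4} D_j`, `DGC = S_4`, and `J` is
  exposed rather than guessed further.
* Whether Ra windows slide per pixel or tile the profile is unstated; both
  exist, sliding is the default (a value is stored at every pixel).
* CRS strings are treated as opaque metadata (plot-local "arbitrary
  projected" coordinates are common); only a plainly geographic,
  degree-unit CRS is rejected.
* Equivalence testing is reported per input raster; pooling across plots
  is left to the caller.

## Environment-driven substitutions

The deployment environment provides no GeoTIFF-capable R package, so
raster I/O uses the ESRI ASCII grid — a standard plain-text GIS raster
format preserving values (17 significant digits), nodata and georeferencing
— with the CRS in a `.prj` sidecar. GeoJSON and CSV cover the vector and
tabular interfaces. The MODWT, rasterization and rank statistics are
implemented in the package and are cross-checked in the test suite against
independent oracles (explicit circulant matrices, hand-enumerated pixel
centers, base R's `wilcox.test`/`kruskal.test` and from-scratch ranking).

## Runtime scaling in the test suite

The acceptance parameter-recovery sweep runs on 256×256 grids (18
decompositions) and the reconstruction criterion on the stated 500×500
grid; the Kruskal-Wallis calibration uses the stated 2,000 null
simulations. The whole suite completes in about half a minute on one CPU.

## Known limitations

* 1-D row-wise decomposition: anisotropic structures aligned with rows
  load differently than those across rows (a per-row constant contributes
  nothing to row-wise Ra).
* `Ra` near run ends uses truncated windows (fewer samples → noisier); use
  `strict` mode when edge bias matters.
* The chain-method analog inherits the DEM's resolution and so is not
  numerically identical to an in-situ chain ratio.
* `crop_to_area()` is a convention (see above); comparisons across
  packages should crop identically before comparing.
* No reprojection or resampling: inputs must already share one grid.
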