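---
title: "Quantifying neuronal uptake of labeled oligomers from confocal Z-stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neuronal uptake of labeled oligomers from confocal Z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligouptake)
```

## The measurement problem

Soluble oligomers of amyloid-beta and Tau applied to cultured hippocampal
neurons are taken up from the extracellular space. The standard readout is
confocal: neurons are immunostained for MAP2 (a somatodendritic marker), the
oligomers carry their own fluorophore, and a Z-stack is acquired per field.
The analysis must then decide, punctum by punctum, whether a fluorescent
spot lies *inside* the neuron volume or merely *decorates its surface* —
a distinction that only the axial (Z) structure of the stack can make,
because in a single XY plane or projection both cases look identical.

`oligouptake` implements that decision pipeline end to end, together with a
ground-truthed synthetic scene generator, so every stage can be validated
without access to raw microscopy data.

## The procedure

For each field the pipeline performs, in order:

1. **Plane-by-plane binarization** of the neuron-marker channel
   (`binarize_marker()`). Each XY plane is thresholded independently
   (Otsu by default) to form the neuron mask.
2. **Neuron instancing** (`label_neurons()`): 26-connected components of
   the mask, optionally split by nuclear seeds; components below
   `min_volume` (50 µm³ default) are discarded as debris. Instances supply
   the per-neuron denominators of every uptake statistic.
3. **3-D spot detection** (`detect_spots()`) in the oligomer channel:
   threshold, connected components (26-connectivity default), then two
   geometric criteria — the spot's maximum-intensity-projection footprint
   area, and its axial extent, which must reach **1.5 µm**.
4. **Axial-overlap classification** (`classify_spots()`): for each spot,
   the fraction of its Z planes in which the neuron mask covers the
   majority of its XY footprint. Overlap **> 65%** means internalized;
   overlap **< 30%** with the spot within `proximity_um` of the mask means
   surface-attached; low overlap far from any neuron is background; the
   30–65% band is *indeterminate* and excluded from both tallies.
5. **Mask multiplication + MIP particle count** (`multiply_mask()`,
   `mip_count()`): the ImageJ-style count of the mask-multiplied channel's
   maximum-intensity projection is reported alongside the 3-D counts.
   Spots separated only in Z merge in the projection, so this count is a
   lower bound; both numbers are kept.
6. **Aggregation and statistics** (`summarize_field()`,
   `compare_groups()`): per-field percentages, spots/neuron, the
   internalization index, and two-group t tests.

### The internalization index

The global uptake summary is

$$ I \;=\; \underbrace{\frac{n_\text{internalizing}}{n_\text{neurons}}}_{\text{fraction of neurons}} \times \underbrace{\bar{s}}_{\text{mean internalized spots/neuron}} $$

Two readings were genuinely open and are both supported:

* **Percentage as fraction.** `internalization_index(91, 5.3)` returns
  4.823, not 482.3. Only this reading reproduces the magnitude of
  published group indices (≈ 4.9 for a 91% / 5.3-spots group), so it is
  the fixed behaviour.
* **Mean over which neurons?** Averaging internalized spots over
  *internalizing* neurons (default) is again the reading consistent with
  published percentage/mean/index triples; averaging over all neurons is
  available via `mean_over = "all"`. Note that under the default reading
  the index algebraically equals total internalized spots divided by total
  neurons, which makes it robust to how the internalizing subset is drawn.

`percent_reduction(ref, test)` is `100 (1 − test/ref)`; it satisfies
`percent_reduction(ref, test) + 100 · test/ref = 100` identically.

## Tunable parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| `min_xy_area` | 2e-4 | µm² | The literal printed criterion (200 nm²) is smaller than one 90-nm pixel (8100 nm²), so as stated it only excludes sub-pixel artifacts. The default stores the literal value rather than silently "correcting" it; the plausible alternative reading of 0.2 µm² (~25 pixels) is one argument away. |
| `min_z_height` | 1.5 | µm | The axial criterion; at the default `dz` = 0.25 µm it demands ≥ 6 planes. This is the workhorse filter: isolated noise voxels never span it. |
| `overlap_internalized` | 0.65 | fraction | Strictly-greater comparison. |
| `overlap_attached_max` | 0.30 | fraction | Strictly-less comparison; the 0.30–0.65 band is indeterminate because no stated rule covers it. |
| `proximity_um` | 0.2 | µm | Operationalizes "close to the surface" for attached spots (~2 pixels); no published number exists. |
| `spot_threshold` | `"otsu"` | — | For real data. Simulation-backed analyses in this package use a fixed threshold chosen from the generator's radiometry (below). |
| `connectivity` | 26 | — | 8-neighbourhood in the 2-D MIP count; matches common particle-analysis behaviour. |
| `dz` default | 0.250 | µm | The acquisition protocol fixes only the XY pixel (90 nm); 0.25 µm is a typical confocal Z step and makes the 1.5 µm criterion span 7 planes. Always overridable by metadata or argument. |

Two deliberate robustness choices:

* **Per-plane Otsu with a global floor.** Otsu always splits a histogram,
  even a unimodal one, so planes above/below the cells would binarize to
  speckle. Each plane's threshold is therefore floored at the whole-channel
  threshold (`floor_global = TRUE`; switch off to get strictly independent
  per-plane thresholds). Flat planes binarize to all-zero.
* **Edge-touching spots are flagged, not dropped** (`edge_touching`):
  their axial extent is truncated by the acquisition, and excluding them
  would bias counts.

## The synthetic scene generator

`simulation_config()` defaults encode the wild-type amyloid-beta regime
reported for this assay: 91% of neurons internalizing, Poisson mean 5.3
internalized spots per internalizing neuron, ~6.9 surface spots per neuron;
a knock-out-like arm uses 73%, 2.9, and 6.5. Per arm, geometry and
radiometry are:

* **Field**: 320 × 320 × 20 voxels at (0.090, 0.090, 0.250) µm =
  28.8 × 28.8 × 5 µm, four neurons per field. Published data give no
  per-field neuron or field counts (only total cells, ~90–130 per
  condition); 20 fields × 4 neurons per arm lands in the same range.
* **Somata**: axis-aligned ellipsoids, XY semi-axes 3–4 µm, Z semi-axes
  1.7–2.2 µm. Cultured hippocampal somata are ~6–10 µm across and
  flattened; a 3.4–4.4 µm soma height also fits the shallow stacks this
  assay uses. Optional thin tubular processes exercise the mask machinery
  but are off by default.
* **Spots**: truncated 3-D Gaussians, footprint radius 0.27 µm, axial
  extent 1.75 µm (7 planes — above the 1.5 µm criterion, matching the
  observation that typical spot heights sit near 1–1.5 µm). Internalized
  spots are sampled strictly inside the soma with margins and re-validated
  at plant time with the package's own overlap rule (planted overlap
  ≥ 0.9); attached spots are placed on the boundary shell and accepted
  only if planted overlap < 0.25 while touching the surface; background
  spots keep ≥ 0.6 µm clearance. Truth classes therefore satisfy the
  classifier's definitions by construction, not by hope.
* **Spot separation**: a 1.5 µm maximin target over candidate positions,
  plus a *hard* support-disjointness constraint (two cylindrical supports
  may not come within a pixel of each other while overlapping in Z), which
  is what actually prevents component merging. In crowded Poisson draws
  the most isolated candidate is accepted, so the 1.5 µm figure is a
  target, not a guarantee.
* **Optics and noise**: anisotropic Gaussian PSF (σ = 0.15 µm XY,
  0.35 µm Z), then Poisson shot noise on the photon-count-like
  intensities (background 5, neuron 80, spot peak 150), then Gaussian
  read noise (SD 3), then rounding to integer counts.
* **Determinism**: one integer seed fixes a field bit-exactly.
  `simulate_experiment()` derives per-field seeds as `seed + i − 1` (arm
  A) and `seed + n_fields + i − 1` (arm B), so arms are independent even
  under identical configs.

For simulation-backed analyses the oligomer threshold is **fixed at 45
counts** — roughly midway between the background ceiling (~20 counts after
noise) and the blurred spot core (~100 counts). A global Otsu threshold on
these extremely unbalanced histograms can land high enough to clip spot
cores below the 1.5 µm criterion, and a data-independent threshold also
keeps the noiseless exactness checks exact (there, `fixed:10`, just above
the flat background of 5, recovers planted supports voxel for voxel).

### What the generator does *not* emulate

Realistic dendritic arbors, spectral bleed-through, stage drift, uneven
illumination, and clustered (non-Poisson) uptake. Passing simulator-backed
tests therefore demonstrates that the *decision rules and statistics* are
implemented correctly and are recoverable under blur and shot noise — not
that segmentation would be robust on arbitrary real microscopy.

## Numerical and degenerate-input choices

* Flat marker planes → all-zero mask planes (empty planes must not join
  neurons across Z).
* Zero-neuron fields → `NA` percentages with a warning, never a silent 0;
  a field whose internalizing subset is empty has mean spots 0 so the
  index is exactly 0.
* Two constant, equal groups → t = 0, p = 1; constant groups with
  different means are refused as degenerate.
* Spot–mask and spot–neuron distances are exact anisotropic Euclidean
  distances computed on local crops (no distance-transform
  approximation).
* Component labeling is breadth-first search in C++; it is checked against
  a brute-force flood-fill oracle over random grids in the test suite.

## Problem sizes used in the checks

The simulator-backed validation runs 20 fields per arm (4 neurons each,
320 × 320 × 20 voxels) under the full noise model, recovering the planted
index reduction of 56.1% within Monte-Carlo error and internalized-spot
recall/precision ≥ 0.9; noiseless exactness uses three 4-neuron fields;
the t-test calibration uses 1000 null replicates of 30 + 30 samples. These
sizes were chosen to estimate each quantity to a few percent.

## Known limitations

* The replication unit for group tests is configurable (per-field default)
  because the published degrees of freedom cannot be reconciled with any
  single obvious unit; per-neuron testing is available by passing neuron-
  level vectors to `compare_groups()` directly.
* The MIP particle count and the 3-D spot count disagree whenever spots
  stack axially; both are reported, and the summary carries the 3-D-based
  statistics.
* OME metadata is written as a companion XML file (`<path>.ome.xml`)
  rather than embedded in the TIFF (the underlying TIFF writer cannot set
  ImageDescription); embedded OME-XML from other writers is honoured on
  read.
* No deconvolution, sub-pixel localization, or splitting of merged spots.
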