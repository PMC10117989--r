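---
title: "Quantifying the modular substructure of isolated postsynaptic densities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the modular substructure of isolated postsynaptic densities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psdtomo)
```

## The problem

Postsynaptic densities (PSDs) are disk-like protein assemblies, typically
200-800 nm across and on the order of 100-190 nm thick when biochemically
isolated, that line the postsynaptic membrane of excitatory synapses.
Cryo-electron tomography of isolated PSDs shows patches of material of
differing electron density, suggesting that the PSD is organized as a
patchwork of *modules* — discrete multiprotein complexes tens of nanometers
across. `psdtomo` implements a complete pipeline to delineate and quantify
this modular organization in reconstructed tomographic volumes:

1. **VOI definition** (`read_contours()`, `rasterize_voi()`): hand-drawn
   closed contours on each tomographic slice, deliberately slightly larger
   than the structure, are rasterized into a 3D volume-of-interest mask.
2. **Denoising by segmentation optimization** (`run_asom()`): a grid search
   over isodensity thresholds and connected-component size filters inside
   the VOI, maximizing a signal-to-noise objective.
3. **Module delineation** (`segment_modules()`): 3D marker-controlled
   watershed on the smoothed density, confined to the denoised PSD mask.
4. **Morphometry** (`measure_psd()`, `measure_modules()`): principal-axis
   measurements — thickness, size, projected area, voxel-count volume.
5. **Trans-PSD modules** (`find_trans_modules()`): modules connected to both
   external surfaces of the PSD across its thickness.
6. **Statistics** (`ks_two_sample()`, `one_way_anova()`, `spearman()`,
   `summarize_groups()`, `estimate_module_mass()`).

A synthetic phantom generator (`generate_phantom()`) provides ground-truth
volumes so that every stage is testable without tomographic data.

## Coordinate and measurement conventions

Volumes are arrays indexed `[z, y, x]` with `z` the tomographic slice axis;
voxels are isotropic and the center of the voxel with 0-based index `i` lies
at `(i + 0.5) * voxel_size_nm`. Volumes, masks and label maps are stored as
MRC2014 files (cell dimensions in Angstrom, mode 2 for densities, mode 1 for
masks and labels, which round-trip bit-exactly). Contour files are JSON
lists of `{"slice": int, "vertices": [[row, col], ...]}` in voxel units.

All object measurements derive from the covariance matrix of the voxel
centers *forming the object's surface* (the 6-connectivity boundary of the
mask, not a triangulated isosurface — a deterministic, mesh-free choice).
Its eigenvectors are the principal axes; the extent along an axis is the
max-minus-min projection of the surface voxel centers plus one voxel, so a
single-voxel object has extent equal to the voxel size rather than zero.
The PSD **thickness** is the smallest extent; a module's **size** is its
largest extent. The **projected area** counts occupied cells of a square
grid with pitch equal to the voxel size, anchored at the centroid, after
projecting every mask voxel center onto the plane of the two non-thickness
axes. **Volumes** are voxel counts times the cubed voxel size, so module
volumes sum exactly to the PSD volume — a conservation law asserted on every
pipeline run.

Whether extents should be measured on surface voxels or on all voxels is not
prescribed by the covariance definition; the difference for an extent
(max - min of projections) is at most one voxel on solid bodies, and the
package uses the surface cloud for both the axes and the extents.

## The denoising objective

The hand-segmented VOI contains the PSD plus reconstruction noise. The
denoiser searches a grid of isodensity thresholds (quantiles 0.50-0.95 of
the within-VOI density, 21 values, making the search contrast-invariant)
crossed with minimum-component-size filters (1 to 500 voxels). For each
pair, the candidate mask keeps VOI voxels at or above the threshold, minus
connected components smaller than the filter. The objective is

> SNR = (voxel count of the largest component) / (summed voxel count of all
> other components),

with `Inf` for a single-component mask. The published method reports SNR
values without a formula; this definition is the simplest one for which a
pre-denoising SNR below 1 means "more noise than structure", and it is
pluggable. Three refinements matter in practice:

* Thresholds at or below the VOI minimum density select the entire VOI and
  perform no segmentation; they are excluded from the search. (This also
  makes the optimization idempotent: re-running it on its own binary output
  returns the same mask.)
* The largest component is never removed by the size filter.
* A candidate is feasible only if its main component retains at least
  `min_main_fraction` (default 0.9) of the main component at the lowest
  *segmenting* threshold, which forbids degenerate "keep a tiny fragment at
  a very high threshold" optima.

Ties go to the lowest threshold, then the smallest filter. Components use
26-connectivity by default: the most permissive choice, which leaves thin
density bridges for the watershed stage to adjudicate rather than cutting
them during denoising.

## Watershed delineation and its two scale parameters

Modules are patches of *density*, not shape lobes, so the watershed floods
the negated Gaussian-smoothed density from h-maxima markers, confined to the
PSD mask (a distance-transform variant is available for binary inputs).
Every mask voxel receives exactly one label; flooding uses a deterministic
priority queue (ties broken by insertion order, seeds visited in linear
index order) and labels are renumbered by descending size, so the partition
is fully reproducible. Labels smaller than `min_module_voxels` (pipeline
default 27 voxels, i.e. a 3-voxel cube) are merged into the neighbor sharing
the largest face-contact area.

Two parameters set the scale of the decomposition:

* `smoothing_sigma_nm` (default 4 nm). The smallest granular substructures
  reported in isolated PSDs are 5-30 nm; smoothing at 4 nm suppresses voxel
  noise while preserving structures above roughly twice that scale.
* `h_depth` (default 0.05 of the smoothed-density range within the mask).
  Markers are the regional-maximum plateaus of the h-maxima transform, so a
  local maximum spawns a marker only if it rises at least `h` above its
  surrounding saddle. The usable window follows from a scale-space argument:
  after 4 nm smoothing, the valleys separating the smallest genuine modules
  retain only about 0.1 of the density range, while the expected maximum of
  the smoothed noise field is near 0.02 of it (the pointwise smoothed-noise
  SD is ~0.005 of the range and the extreme over ~10^5 effectively
  independent kernel volumes multiplies it by ~4). The default 0.05 sits in
  the middle of that window. Raising `h_depth` monotonically reduces the
  label count (a property the tests assert); at 0.2 the smallest module
  pairs of the canonical phantom are merged away.

## Trans-PSD modules

A module is *trans* when it is directly connected to both external surfaces
of the PSD across its thickness. "Both external surfaces" is operationalized
per projected cell: every PSD voxel center is projected onto the plane
orthogonal to the thickness axis and binned into the same grid used for the
projected area; within each occupied cell the voxel with the largest
thickness-axis coordinate joins the top sheet and the smallest joins the
bottom sheet (a one-voxel cell contributes to both). This per-cell-extrema
rule is robust to the curved, lumpy surfaces of real PSDs, unlike a
geometric mid-plane split. A module is trans when it owns at least
`min_contact_voxels` cells in each sheet.

`find_trans_modules()` defaults to a contact threshold of 1 — the literal
reading of "directly connected". The pipeline default is 100 projected cells
(a 20 x 20 nm patch at 2 nm voxels, the footprint of the smallest granular
substructures): a genuine full-thickness connection presents a face contact
that scales with the module's cross-section (hundreds of cells for a
~70-nm-wide module), whereas discretization and segmentation-noise artifacts
form a band one to two cells wide along a module's footprint perimeter (tens
of cells), so a footprint-scale threshold cleanly separates the two regimes
on phantoms.

## What the phantom emulates — and what it does not

`generate_phantom()` builds a disk-shaped aggregate of globular modules with
known labels. Non-trans modules are *vertically stacked pairs* of
equal-radius spheres — an upper and a lower layer, centers offset from the
disk mid-plane by 0.875 of the radius — whose lateral footprints are packed
by rejection sampling (normalized lateral separation between 0.80 and 0.95,
so modules overlap enough to stay connected but keep density valleys between
them). Trans modules are vertical cylinders spanning the full disk
thickness. The two-layer arrangement echoes the layered organization of the
PSD (a membrane-proximal core and a cytoplasmic pallium) and makes the
trans definition geometrically meaningful: per projected column, the top of
the aggregate belongs to an upper-layer module and the bottom to a
lower-layer one, so only the cylinders genuinely reach both surfaces.

Each module carries a radial density profile falling from 1 at its center to
`1 - gap_contrast` at its boundary, and the volume density is the voxel-wise
maximum over modules, so inter-module boundaries are density valleys — the
physical cue the watershed uses. The ground-truth label of a voxel is the
module with the highest profile there.

Default conditions (`default_psd_spec()`): a 400 nm x 130 nm disk envelope
with 30 modules of lognormal diameter (median 50 nm, log-SD 0.45, truncated
to fit a stacked pair inside the thickness), 2 trans cylinders of 35 nm
radius, `gap_contrast` 0.5, additive Gaussian noise of SD 0.1 (10% of the
foreground level, a plausible SIRT-reconstruction contrast-to-noise for a
dense aggregate), and a 2 nm Gaussian blur along z as a cheap surrogate for
missing-wedge anisotropy — on a 96 x 224 x 224 grid of 2 nm voxels. The
published tomograms were recorded at ~0.35 nm pixels and downsampled; a 2 nm
grid keeps the canonical phantom under 256^3 voxels so the full pipeline
runs in about half a minute, while leaving the smallest modules ~5 voxels
across.

Synthetic VOIs (`phantom_voi_contours()`) trace, per slice, one expanded
convex outline around each module cross-section (8 nm margin), emulating an
annotator hugging the structure's silhouette. A single loose hull around the
whole cluster is *not* used: if the structure fills less than half of the
VOI, the lowest threshold quantile (0.50) falls inside the noise and
26-connected noise percolation attaches a large halo to the structure.

What the phantom does **not** emulate: CTF modulation, Fourier-domain
missing-wedge artifacts (only real-space anisotropic blur), filamentous
material, realistic protein shapes, density correlations inside modules, and
partial-thickness module stacks deeper than two layers. Passing the phantom
recovery tests therefore shows that the pipeline is internally consistent
and resolves modular architecture under controlled degradation — not that it
would segment any given experimental tomogram correctly.

Known limitation: module pairs smaller than ~20 nm sit below the 4 nm
smoothing scale; their inter-module valleys can vanish after smoothing, so a
few of the smallest modules may merge (the canonical noiseless phantom
recovers 28-30 of 30 depending on the seed, and noisy runs recover 28-32
with occasional over-segmentation).

## The statistical layer

Group summaries are means with sample SDs (n-1 denominator — the convention
that reproduces the published per-group values from the packaged tables).
The two-sample Kolmogorov-Smirnov D is computed by a direct ECDF sweep; its
p-value is exact (tie-aware permutation enumeration) when `n*m <= 10000` and
asymptotic otherwise. One-way ANOVA is the classical equal-variance F test.
Spearman's rho uses average ranks on ties, with exact p for n <= 9 untied
pairs. p-values are reported with a method note but are not treated as
portable quantities: their exact values depend on software conventions
(exact vs asymptotic, tie handling), so cross-package comparisons should be
made at the significance level (the study's alpha = 0.01), not digit by
digit.

The mass model treats a module as a disk of the given diameter carrying the
PSD's areal mass density (~10 kDa/nm^2): a 50 nm module is then ~20 MDa,
room for well over 100 proteins of average mass 100 kDa.

```{r mass}
estimate_module_mass(size_nm = 50, areal_density_kda_per_nm2 = 10,
                     mean_protein_kda = 100)
```

## Reference tables

Two published summary tables of isolated rat-brain PSDs are packaged as CSV
fixtures (checksum-guarded): per-PSD areas, thicknesses and volumes for six
control and two sonicated PSDs, and per-module volumes and sizes of their
trans-PSD modules. `reproduce_table_results()` recomputes every table-derived
quantity (group means and SDs, trans counts, size and volume ranges, volume
percentages, the mass model) and compares each against the printed value at
the precision it was printed with (two significant figures; whole nm for
sizes).

```{r tables}
rep <- reproduce_table_results()
rep$checks[, c("name", "computed", "reference", "pass")]
```

## Reproducing the end-to-end validation

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(output_dir = "psd_run",
                       phantom = default_psd_spec(), seed = 1)
man <- run_pipeline(cfg)
man$summary
```

The run writes the phantom volume, ground-truth labels and manifest, the VOI
contours, the denoised mask, the label map, per-module and per-PSD CSVs, the
trans-module report and a JSON summary, plus a manifest with MD5 checksums —
identical configurations reproduce identical files bit for bit. The
`scripts/acceptance.R` script at the repository root packages the same
computations (table reproduction, mass model, phantom recovery, ANOVA
calibration) into one JSON report.

## Numerical and degenerate-input choices

* Polygon interiority is even-odd on voxel centers with boundary centers
  counting as inside (generous VOIs match annotator intent); polygons are
  validated as simple on load.
* Anisotropic MRC headers are rejected beyond a 0.1% tolerance — all
  nm-space math assumes one voxel size.
* Label maps are written in 16-bit integer MRC mode (bit-exact round trip);
  more than 32767 labels is an error, not an overflow.
* Coplanar or collinear surface clouds are flagged degenerate instead of
  crashing; a flat sheet still has a well-defined thickness axis (its
  normal), and the trans classifier only requires that the two leading
  covariance eigenvalues be positive.
* Watershed ties (equal priority) are broken by queue insertion order;
  equal-size components are ordered by their smallest voxel index; a merge
  tie (equal boundary area) goes to the smaller label id.
* A flat density relief (or `h_depth = 1`) yields a single-label partition
  with a warning rather than zero labels.
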