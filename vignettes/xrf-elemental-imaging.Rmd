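---
title: "Quantitative XRF imaging of filamentous cyanobacteria: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative XRF imaging of filamentous cyanobacteria: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrfmap)
```

## The scientific problem

Filamentous, nitrogen-fixing cyanobacteria such as *Anabaena* sp. separate
photosynthesis and nitrogen fixation spatially: most cells in a filament are
photosynthetic vegetative cells, and a few differentiate into micro-oxic
heterocysts that host the oxygen-labile nitrogenase. Synchrotron X-ray
fluorescence (XRF) nanoprobes map the elemental makeup of such cells in a
frozen-hydrated state: a focused beam raster-scans the specimen, a full
fluorescence spectrum is recorded at every pixel, and fitted line intensities
are converted to areal concentrations (µg/cm²) against a certified thin-film
standard. The biological readout is quantitative: cytosolic K, Ca and Fe
levels differ between heterocysts and vegetative cells, and vegetative cells
carry micron-scale P/K-rich clusters (presumed polyphosphate bodies) that are
wrapped by larger Ca-rich clusters or associated with irregular Fe hotspots.

This package implements the full analysis chain for such experiments —
per-pixel spectral quantification, cluster segmentation, morphometry,
colocalization statistics, and SIRT fluorescence tomography — together with a
synthetic filament phantom that carries complete ground truth, so that every
stage is testable end to end without beamline data.

## The phantom: what it emulates

`filament_preset()` describes a filament of 4–10 elliptical vegetative cells
(5 µm × 3.5 µm) with one equal-area circular heterocyst mid-filament, touching
at the septa, wrapped in a 345 nm Cl-bearing envelope. Each vegetative cell
carries 2–4 P/K clusters (a K-rich footprint with a concentric smaller P
core), of which roughly half are peripheral and wrapped by a Ca-rich disk and
the rest are associated with an irregular Fe blob; isolated Ca disks and Fe
blobs occur as well; the heterocyst carries no P/K or Ca clusters. Cytosolic
levels are the reference measurements for nitrogen-starved material:
K 0.452 / Ca 0.073 / Fe 0.095 µg/cm² in the heterocyst against
0.277 / 0.029 / 0.027 in vegetative cells, Ca-rich clusters at
1.337 ± 0.64 µg/cm², K cluster diameters 0.99 ± 0.48 µm, mean areas
0.310 / 0.180 / 0.050 µm² for Ca / P / Fe.

```{r preset}
cfg <- filament_preset(n_veg = 4)
cfg
truth <- generate_filament(cfg, seed = 1)
truth
head(truth$registry[, c("cell_id", "family", "element", "n_pixels",
                        "area_um2", "true_mean_conc")])
```

Design choices that were genuinely open, and how they were settled:

* **Size distributions are mean-matched truncated normals.** Footprints are
  drawn from a normal truncated below at 2 pixels, with the location
  parameter solved so that the *post-truncation* mean equals the catalogued
  mean. This matters most for Fe: the catalogued area (0.050 µm², nominal
  SD 0.095) sits so close to the 2-pixel floor that naive truncation would
  realize a mean near 0.11 µm² — the catalogued value would be unrecoverable
  by construction. The cost is that the realized SD is narrower than the
  nominal SD where truncation bites hard (Fe areas, Ca concentrations); the
  mean, which is the quantity under test, is exact.
* **The K diameter and the per-element areas are mutually inconsistent.**
  A 0.99 µm mean diameter implies a mean area near 0.95 µm², several times
  the catalogued K area of 0.200 µm². Both cannot hold for one population.
  The preset drives the K footprint by the diameter distribution (the
  explicitly distributional statement) and the P/Ca/Fe footprints by their
  area means; the nominal K area is kept as metadata
  (`k_area_um2_nominal`) but is not generative.
* **Ca "shells" are filled disks.** A three-dimensional Ca shell around a
  P/K core projects to a filled disk in an areal map, so the generator
  renders PK_Ca clusters as a Ca disk concentric with the P core, drawn as
  core area plus a mean-matched positive increment — guaranteeing the disk
  strictly contains the core and exceeds it in area while realizing the
  catalogued 0.310 µm² mean.
* **Unprinted concentrations.** No reference value exists for K or P inside
  P/K clusters, Fe inside blobs, or cytosolic S and Cl. S and Cl default to
  0.30 and 0.02 µg/cm²; P and Fe boosts are 0.8 µg/cm² (strong contrast).
  The K boost is 0.5 µg/cm² (clusters ≈ 2.8× the vegetative cytosol): the
  two-class intensity convention used for segmentation presumes a specific
  bimodal structure, and this value sits in the window where the full-field
  split separates cells from background *and* the in-cell split separates
  clusters from both cytosol populations, including the brighter heterocyst.
  This is a validity precondition of the measurement convention, chosen
  once and validated over 140 simulated filaments.
* **Ca-rich cluster concentrations have a floor of 0.75 µg/cm²** (~25× the
  vegetative cytosol). "Ca-rich" is defined operationally by an intensity
  split, so the labelled ground-truth population must coincide with the
  segmentable population; clusters generated below the bimodal cut could
  never be measured as Ca-rich and would make the recovered conditional
  mean overshoot the generating mean by construction.
* **Irregular Fe blobs** are grown by seeded random-walk aggregation with
  exactly `round(area/pixel area)` pixels, confined to the host cell.
* **Counting model.** Expected counts are concentration × sensitivity ×
  dwell; elemental sensitivity is a smooth exponential in atomic number
  (`detector_model()`), which makes the log-linear interpolation used in
  calibration exact; Poisson noise is applied per count map or per spectral
  bin. Geometric crowding truncates the very largest K draws (d ≳ 2 µm do
  not always fit a 3.5 µm cell), so the realized K diameter mean sits ~4%
  below the catalogued 0.99 µm; largest-first placement keeps this small.

What the phantom does **not** emulate: detector point-spread blur between
pixels, self-absorption, escape/pile-up peaks, L lines, spatially varying
continuum, sub-pixel partial-volume effects, akinetes, and 3D cell geometry
beyond extruded slices. Passing recovery tests therefore demonstrates the
correctness of the analysis chain under the stated forward model, not
robustness to every artifact of real beamline data.

## Spectral quantification

Per-pixel spectra are modelled as a smooth continuum plus, per element, an
exponentially modified Gaussian (EMG) at the K-alpha energy and a companion
at the K-beta energy locked to a fixed area ratio:

$$f(x) = \frac{A}{2\tau}\,
  \exp\!\Big(\frac{\sigma^2}{2\tau^2} - \frac{x-\mu}{\tau}\Big)\,
  \mathrm{erfc}\!\Big(\frac{1}{\sqrt2}\big(\frac{\sigma}{\tau} -
  \frac{x-\mu}{\sigma}\big)\Big),$$

normalized so the integral equals the area $A$, evaluated in the scaled
complementary error function form (with an asymptotic branch) so it is
stable for any $\sigma/\tau$. The Gaussian width and tail constant are
detector properties shared by all peaks in a spectrum.

`quantify_map()` chains the stages:

1. **Shared line shape**: $(\sigma, \tau)$ profiled by Nelder–Mead on the
   raw field-mean spectrum with smooth baseline columns in the model.
   Fitting the raw mean (rather than a stripped one) avoids imprinting the
   stripping operator's small peak distortion on the width.
2. **Background bootstrap**: SNIP-style peak stripping per pixel
   (`strip_background()` / `snip_matrix()`): iterative min-clipping in the
   square-root counting domain with a window decreasing linearly from 20
   bins over 24 passes. Flat and linear baselines are fixed points.
3. **Amplitudes**: with the shape fixed, the model is linear in the
   per-element K-alpha areas, solved for all pixels at once by least
   squares. A residual-floor correction (two smooth baseline shapes fitted
   on off-peak bins above 1.2 keV, estimated from the field mean so that no
   per-pixel noise couples the element maps to each other) removes the
   small positive pedestal min-clipping leaves on low-count spectra.
4. **Refinement**: the fitted peaks are subtracted and the smoothed
   peak-free residual becomes the new background estimate; six passes
   converge geometrically. On a noiseless cube the recovered maps agree
   with ground truth to ≤ 0.5% relative L2 per element; on noisy data the
   estimates are unbiased with Poisson-propagated variance.
5. **Calibration**: `calibrate_sensitivities()` fits the measured spectrum
   of a certified thin-film standard with the same machinery and converts
   areas to µg/cm² via area / (density × live time); uncovered elements are
   interpolated log-linearly in Z. `quantify_map()` then divides fitted
   areas by sensitivity × dwell.

Numerical details: amplitude solutions are clamped at zero only after the
refinement loop (clamping inside it would bias the background); fit failures
propagate as missing pixels; the line catalog covers Z = 13–30 with K-beta
ratios from standard emission-rate tabulations, shipped as an editable table.

## Segmentation

The cytoplasm is delineated from the K map — K is the most abundant
cytosolic element — by a two-class intensity split of the full field,
morphological closing (radius 1), and removal of components under 25 px.
Cluster/non-cluster splits are then computed per element on the
in-cytoplasm intensities only. `kmeans_1d()` computes the k = 2 partition
*exactly*: in one dimension the optimal two-class partition is a split of
the sorted values, found by a prefix-sum sweep. This is the fixed point
Lloyd's algorithm seeks; Lloyd iterations from quantile seeds were found to
stall inside the dominant intensity mode on low-contrast maps (e.g. Fe),
so the exact solver replaces them for k = 2 (they remain for k > 2). The
reported threshold is the midpoint of the two class means. All masks are
invariant to positive rescaling of the map.

A second, independent boundary comes from a fixed concentration threshold
(`cluster_mask_fixed()`; the package default is cytosol mean + 3 SD, since
no canonical value is printed anywhere). `consensus_mask()` intersects the
two boundaries: the core contains pixels both methods call cluster, and the
symmetric-difference band flags the disputed rim, reducing the
concentration error contributed by ambiguous edge pixels. Connected ROIs
are labelled with 8-connectivity (2 px minimum — single-pixel hits at a
100 nm pitch are noise) in deterministic row-major discovery order.

Display scaling (`percentile_clip()`: 98th percentile for plain display,
99.9th for cluster emphasis) is applied to display products only;
segmentation and quantification always operate on raw concentrations, since
clipping before thresholding could only alter saturated pixels.

## Cluster statistics

`cluster_area()` is pixel count × pixel area (0.01 µm² at 100 nm);
equivalent diameters are $2\sqrt{A/\pi}$. `region_mean_concentration()`
subtracts the median of the off-cell (substrate/ice) pixels — the natural
blank — and clamps the mean at zero. `roi_pearson()` correlates two maps
over an ROI's bounding box rather than only in-cluster pixels, so
anti-colocalization remains detectable; both per-ROI values and a pooled
reduction over all boxes are reported, since either reading of "per-ROI
correlation" is defensible. `overlap_fraction()` reports the overlap
coefficient $|A\cap B|/\min(|A|,|B|)$ — which reads through the fact that
some elemental footprints exceed others in size — alongside the Jaccard
index. `classify_cluster()` assigns the colocalization families: a P/K
core where P and K ROIs mutually overlap at ≥ 0.5 overlap coefficient,
tagged `PK_Ca` or `PK_Fe` by which element overlaps the core (Ca checked
first, matching the peripheral Ca-wrapped morphology), else
`Ca_only`/`Fe_only`/`unclassified`. Family tags are geometric labels only;
no chemical speciation is implied.

`students_t()` wraps the two-sample t-test (pooled variance by default, as
"Student's t-test" conventionally means; Welch by flag; both always
computed) and emits one- and two-sided p-values, since "not significantly
larger" phrasing reads one-sided while the test is conventionally
two-sided. `distribution_summary()` provides the violin-plot quartiles
(linear interpolation) and 1.5 × IQR fences.

```{r analysis}
sim <- simulate_experiment(filament_preset(n_veg = 4), seed = 11)
ana <- analyze_maps(sim$maps[c("P", "K", "Ca", "Fe")],
                    cell_label_map = sim$truth$cell_label_map,
                    cell_kinds = sim$truth$cells$kind)
dplyr::count(ana$clusters, element, family)
head(ana$regions)
```

## Tomography

Fluorescence tomography is acquired by rotating the specimen over an
angular range short of 180° — here 51 projections over −82° to 70°
(3.04° spacing), a missing wedge. `projector_config()` builds an explicit
sparse parallel-beam system matrix by pixel-driven linear splatting; the
forward projector and backprojector share this one matrix, so the adjoint
pairing SIRT depends on holds to machine precision by construction.
`sirt_reconstruct()` iterates

$$x \leftarrow x + C\,A^{\mathsf T} R\,(b - A x),$$

with $R$ and $C$ the inverse row/column sums (zero-weight rows and columns
masked, never divided by), optional nonnegativity clamping (on by default —
concentrations cannot be negative), and a recorded residual history that is
non-increasing on consistent data. Default 100 iterations. Volumes are
reconstructed slice-by-slice from per-scan-row sinograms, matching how
raster-scanned XRF tomography is acquired; no 3D regularization is applied.
Under the missing wedge a disk phantom still reconstructs with correlation
≥ 0.85 against truth (≥ 0.95 with full angular coverage); low-count
elements reconstruct poorly under the wedge, which is characterized but not
"corrected".

## Problem sizes and reproducibility

The recovery harness (`recover_preset()`, also driven by
`scripts/acceptance.R`) uses one spectral filament (6 vegetative cells +
1 heterocyst, ~25k pixels × 500 energy bins at 100 nm / 200 ms) for the
concentration chain — simulate spectra → calibrate on a simulated
thin-film standard → quantify → segment → region statistics — and 13–20
further filaments through the counting forward model for pooled cluster
morphometry (≥ 200 K and Fe clusters) and the pooled consensus Ca
concentration. Pooling the Ca concentration across filaments is a
statistical necessity, not a convenience: one filament holds only ~13
Ca-rich clusters, and with a between-cluster SD of 0.64 µg/cm² a
single-filament mean carries ~11% sampling noise — larger than the
recovery tolerance being checked. Every stochastic step takes an explicit
integer seed, and identical (configuration, seed) pairs reproduce outputs
bit for bit; run manifests record the seed and a configuration hash.

## Known limitations

* The phantom's sharp-edged, noise-free geometry makes segmentation easier
  than on real data with beam blur and partial-volume pixels.
* The continuum model is a single exponential; real spectra carry scatter
  structure that peak stripping must handle without a parametric crutch.
* Mean-matching under hard truncation narrows realized SDs relative to the
  nominal SDs (Fe areas, Ca concentrations).
* The K diameter / K area inconsistency described above means violin-plot
  areas for K reflect the diameter-driven footprint, not the nominal
  0.200 µm².
* Heterocyst identification is an input (cell types are user-supplied
  labels), not an inference from the maps.
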