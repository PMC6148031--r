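---
title: "Quantifying chondrocyte distribution in contrast-enhanced microCT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chondrocyte distribution in contrast-enhanced microCT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

Phosphotungstic acid (PTA) binds proteins far more strongly in muscle, skin
and perichondrium than in cartilage matrix, so in a PTA-stained microCT scan
of a developing limb a cartilaginous element appears as a *dark* capsule
embedded in bright tissue. Chondrocyte nuclei inside the element take up
stain and appear as small *bright* spots, and a thin bright line — stained
perichondral surface plus edge enhancement — runs along the element border.
At about 1 µm isotropic voxels the nuclei are individually resolvable,
which makes three quantities computable per skeletal element: the number
and density of chondrocytes, their distribution along the element axis
(epiphyses versus diaphysis), and the orientation (polarity) of each cell.

`chondroquant` implements that analysis as a chain of small, separately
testable stages:

1. **3D median filter** (`median3d`) to suppress the bright nuclei so the
   segmentation sees only the element outline;
2. **active-contour segmentation** (`init_contour`, `evolve_snake`,
   `segment_element`) of the element, slice by slice with propagation;
3. **transparent-zero masking** (`apply_mask`) of the *original* volume:
   outside voxels set to 0, inside voxels untouched;
4. **K-means intensity classification** (`kmeans_classify`) into
   background, extracellular matrix (ECM) and nucleus classes;
5. **erosion-based blob analysis** (`erode_mask`, `split_blobs`,
   `label_blobs`, `blob_metrics`, `filter_blobs` with the 27-voxel rule,
   `count_cells`);
6. **zonal statistics** (`per_slice_profile`, `detect_zones`,
   `fit_parabola`, `summarize_element`);
7. **polarity mapping** (`deviation_angle`, `local_surface_tangent`,
   `polarity_map`).

`run_pipeline()` composes the stages in this order; each stage is also a
public function operating on explicit containers (`cq_volume`, `cq_mask`,
`cq_classmap`, `cq_labels`, blob tables).

## The synthetic phantom

Real synchrotron volumes of this kind are not redistributable at package
scale, so validation rests on `generate_phantom()`: a capsule (cylinder
with hemispherical caps, axis along z) of weakly-stained ECM containing
bright ellipsoidal nuclei, surrounded by brighter stained tissue, with a
2-voxel bright rim on the inside of the capsule border, then Gaussian PSF
blur and additive Gaussian noise. Ground truth (nucleus centres,
orientations, per-zone densities, the voxelised capsule mask) is returned
alongside.

Default conditions (one number per line, with the reason):

* grid 512 × 256 × 256 voxels at 1.05 µm — the synchrotron voxel size;
* capsule radius 90 µm, length 500 µm — a developing forearm element at
  the imaged stage;
* epiphyses = terminal 20% of the axis length each; the pipeline never
  sees this number and must rediscover the zones from the density profile;
* densities 40,000 cells mm⁻³ (diaphysis) and 80,000 cells mm⁻³
  (epiphyses) — inside the literature range of 30,000–110,000 cells mm⁻³
  and reproducing the observed factor-of-two zonal contrast;
* nucleus semi-axes (4.0, 2.5, 2.5) µm — a mildly prolate nucleus of
  ≈ 105 µm³, comfortably above the 27-voxel minimum size at 1.05 µm
  voxels;
* intensities background 20, ECM 60, nucleus 160, surroundings 180,
  rim 200 (8-bit) — dark cartilage in bright tissue with the bright-border
  artifact, and a nucleus/ECM contrast large relative to the noise;
* PSF σ = 0.7 voxels, noise σ = 8 — mild optical blur and a noise level
  that makes classification non-trivial (the ECM ± 3σ band stays clear of
  the nucleus intensity);
* orientation model: diaphyseal nuclei aligned with the element axis,
  epiphyseal nuclei within 15 µm of the surface aligned with the local
  surface tangent, deeper epiphyseal nuclei isotropic.

Counts are drawn Poisson per zone; centres are placed by rejection
sampling with a hard-core minimum separation of 1.5 × the largest
semi-axis, and each ellipsoid must fit inside the rim-free capsule
interior. The phantom emulates *contrast structure*, not physics: there is
no projection/reconstruction model, no ring or beam-hardening artifacts,
no texture in the ECM, and tissue boundaries are ideal geometry plus blur.
Passing the recovery tests therefore demonstrates that the chain is
mathematically coherent and robust to blur, Poisson placement and
moderate Gaussian noise — not that it is robust to every real-beamline
artifact.

## Design choices and numerics

**Median filter.** Neighbourhood is an axis-aligned ellipsoid ("radius in
all three dimensions"), reflect padding, lower median on even counts so
output values stay in the input value set. The documented default radius
is 10 for real PTA data; phantom-scale runs use radius 3 because the
phantom's noise is milder, and the filter's only job — removing nuclei and
the thin rim from the segmentation input — is already achieved at that
radius. A separable x→y→z variant is provided as a cheaper approximation.

**Snake.** A greedy discrete contour (Williams–Shah family). The external
force is the gradient magnitude saturated at the gradient threshold
(default 30): `min(g, T)/T`. Saturation means every edge at or above
threshold is equally attractive — which is exactly why unfiltered data
fail (nucleus edges compete with the element border on equal terms) and
median-filtered data succeed. Numerical choices: the saturated map is
smoothed with a Gaussian (σ = 2 voxels, then renormalised to maximum 1)
to give the discrete snake a capture range of a few voxels; continuity is
`((d − s)/s)²` against the resampling spacing `s` (not the running mean
distance, so the total energy is well defined across an iteration);
curvature is `|Δ²p|²/(32 s²)` — soft enough that a point can follow an
edge drifting a fraction of a voxel per slice (important along the
hemispherical caps), stiff enough to reject isolated noise pulls. Moves
are sequential and accepted only when the *total* energy strictly
decreases, so the energy trace is non-increasing between the uniform
arc-length resamplings performed every 5 iterations.

**Auto-initialisation.** Otsu threshold, largest connected dark region
(or the one containing the seed point), 3-voxel dilation, convex hull,
resampled. One subtlety: with air/agarose darker than cartilage the
single Otsu split selects the wrong phase, so when a seed point is given
the threshold is raised by recursive Otsu splits of the above-threshold
mass until the seed lies in the dark phase.

**Propagation and termination.** From the initial (default middle) slice
outward in both z directions, each slice initialised by its neighbour's
final contour. A side terminates when the element is absent: contour area
below 20 voxels, collapse below 8 points, or mean raw edge support along
the contour below 0.15 — the last test is needed because a strict-descent
snake on a featureless slice simply freezes rather than collapsing.

**Mask padding.** The median filter erases the thin bright rim, so the
snake converges to the rim's *inner* edge and the raw mask excludes the
border. The published segmentation contained the light border (it had to
be removed later by erosion), and that bright mass is also what lets a
3-class K-means isolate a bright class at all: without it the global
optimum of the within-class sum of squares provably splits the broad ECM
mode rather than isolating the tiny nucleus mode (the nuclei are ~0.5% of
the masked voxels). The pipeline therefore pads the segmentation outward
by 1 voxel (`mask_dilation_voxels`), which keeps the in-mask bright
border ≤ 2 voxels thick — thin enough that one cube erosion deletes it
completely.

**K-means.** Lloyd iterations on scalar intensities over the whole
masked volume (the zero exterior anchors the background class), empty
clusters reseeded at the worst-represented intensity, final classes
renumbered by ascending centroid, ties to the lower class. Because the
class masses are extremely unbalanced, the default initialisation is
`"optimal"`: the exact weighted 1-D k-means computed by dynamic
programming over contiguous partitions of the intensity histogram (in one
dimension the optimal clusters are contiguous in sorted order), followed
by Lloyd polishing. Percentile (1st/50th/99th) and seeded-random inits
are available; percentile-started Lloyd can land in a local optimum that
splits the ECM mode.

**Blob analysis.** Erosion (cube 3×3×3, one pass) splits touching nuclei
and deletes the ≤2-voxel bright border. Counting on the bare eroded
blobs, however, would interact badly with the 27-voxel minimum size: a
~105 µm³ nucleus digitises to ~90–110 voxels, and one cube erosion leaves
only ~10–25 of them — every true cell would be discarded. `split_blobs`
therefore labels the eroded cores and grows each label back over the
pre-erosion mask by a breadth-first, mask-constrained dilation (geodesic
reconstruction). Components that vanish entirely under erosion — the
rim — are never restored; touching nuclei stay split along the BFS
watershed; and blob voxel counts refer to full nucleus extents, so the
27-voxel filter acts on the quantity it was defined for. Counts with and
without erosion then agree for isolated nuclei.

**Zonation.** Per-slice cell density is estimated as the number of
surviving blobs intersecting the slice divided by the slice's cartilage
volume. The estimate is only used for change detection; it is inflated by
each cell's z-extent and biased where the cross-section shrinks, so the
boundary search (i) ignores slices whose cartilage area is below 90% of
the maximum (the rounded tips) and (ii) uses a matched-filter step
statistic — the difference of mean density over the `window` slices right
and left of each position — rather than a single-sample derivative of the
moving average, which at ~7 cells per slice is dominated by Poisson
noise. One boundary is taken per element half, ties resolved toward the
ends; if no change exceeds 1e-12 the whole element is labeled diaphysis
and flagged. The pipeline default half-width is 25 slices, chosen so the
factor-of-two density step stands several standard errors above the
counting noise at phantom-like densities; `detect_zones()` itself
defaults to 10 for generic use.

**Polarity.** Orientation is the principal second-moment axis of each
restored blob — deterministic and computed on the same objects that were
counted. A cell is "polarized" when its elongation `sqrt(λ1/λ2)` is at
least 1.2; deviation angles of rounder cells are reported but flagged
unreliable, since the principal axis of a near-sphere is ill-conditioned.
Deviation is measured to a reference plane (0° in-plane, 90° along the
normal), matching the convention of setting 0° to an anatomical plane.
Surface alignment of superficial cells (centroid within 15 µm of the
surface) uses the normal of a least-squares plane through surface voxels
within 10 µm of the nearest surface point. Orientation-recovery
validation uses a phantom with semi-axes (6.0, 2.75, 2.75) µm: the
orientation-recovery check concerns cells of elongation ≥ 2, which the default
1.6-ratio nuclei cannot produce, and a 2.2 µm minor axis would not
survive the cube erosion.

**Ratio profile and parabola.** Per-slice nucleus area counts only
voxels of size-filtered blobs, so the profile is consistent with the
counts; ECM area is the ECM class. The nuclei/ECM ratio is fitted with
ordinary least squares to a second-order polynomial; with denser
epiphyses at both ends the fit is convex with its vertex in the
diaphysis. The quadratic coefficient is treated as zero (vertex
undefined) below 1e-12.

## Problem sizes used in validation

The test suite runs the full pipeline on two full-size default phantoms
(seeds 42 and 7; 512 × 256 × 256 voxels, ~600 cells each), a mid-size
elongated-nucleus phantom for orientation recovery, and dozens of small
volumes (≤ 16³) where `median3d`, `erode_mask` and `label_blobs` are
compared voxel-for-voxel against brute-force definitional oracles, and
the K-means objective is compared against the exhaustive
contiguous-partition optimum. `scripts/acceptance.R` reruns the full
default-phantom pipeline from scratch and reports the recovered overall
density.

## Known limitations

* The snake tracks one closed contour per slice: elements whose
  cross-section splits (bifurcations) or multiple elements need separate
  runs with their own seed points.
* The intensity-only K-means assumes the nucleus class is separated in
  intensity after masking; heavy texture or strong shading would require
  features beyond scalar intensity.
* Erosion-based splitting separates pairs joined by thin necks; deeply
  interpenetrating nuclei (centre separation below ~1.5 minor diameters)
  remain merged, which loses a few percent of cells at epiphyseal
  densities.
* The per-slice density estimator double-counts cells across slices by
  design; it is suitable for change-point detection, not as an absolute
  per-slice density.
* Zonation assumes the three-zone (epiphysis–diaphysis–epiphysis) prior
  with exactly one boundary per element half.
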