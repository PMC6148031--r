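# chondroquant

Quantitative 3D analysis of chondrocyte distribution in PTA-stained
X-ray microtomography volumes of developing cartilage.

In microCT scans contrasted with phosphotungstic acid (PTA), cartilage
matrix stains weakly and appears as a dark capsule inside bright muscle
and skin, while the chondrocyte nuclei inside it appear as small bright
spots — individually resolvable at ~1 µm voxels. `chondroquant` turns
such a volume into per-element cell counts, densities, zonal profiles and
per-cell orientation statistics:

* **3D median filter** (ellipsoidal neighbourhood, radius 10 default) to
  suppress the bright nuclei before segmentation;
* **active-contour (snake) segmentation** of the cartilaginous element —
  greedy discrete snake with a saturated-gradient external force
  (`min(g, T)/T`, threshold *T* = 30, 50 iterations), propagated slice by
  slice through the stack;
* **transparent-zero masking**: voxels outside the segmented element set
  to 0, inside voxels copied bit-exactly from the *unfiltered* volume;
* **3-class K-means** on voxel intensity → background, extracellular
  matrix (ECM), nuclei;
* **erosion + blob analysis**: one 3×3×3 cube erosion splits touching
  nuclei and deletes the bright border of the element; eroded cores are
  grown back over the original mask (geodesic restore), labeled with
  26-connectivity, measured (volume, centroid, principal axes,
  elongation), and filtered with the minimum-size rule *size > 3 pixels*
  = **27 voxels**; the surviving blob count is the cell count;
* **zonal statistics**: per-slice nuclei/ECM areas and their ratio with a
  second-order polynomial fit (its minimum marks the diaphysis centre),
  and epiphysis–diaphysis boundaries detected from abrupt changes of the
  per-slice cell density;
* **polarity**: per-cell deviation angle from a reference plane
  (0° in-plane, 90° along the normal), polarized-cell flags
  (elongation ≥ 1.2), and alignment of superficial cells with the local
  cartilage surface tangent.

Because the original synchrotron volumes are too large to ship, the
package includes a first-class synthetic phantom generator
(`generate_phantom()`): a capsule of dark ECM with bright ellipsoidal
nuclei at zone-specific densities (40,000 cells mm⁻³ diaphysis,
80,000 cells mm⁻³ epiphyses), a bright border rim, surrounding bright
tissue, PSF blur and noise — with full ground truth for parameter
recovery.

## Worked example

```r
library(chondroquant)

report <- run_pipeline(pipeline_config(phantom = TRUE, seed = 42,
                                       out_dir = "run42"))
print(report)
#> <cq_report>
#>   cells: 567, element volume: 0.01096 mm^3, density: 51746 /mm^3
#>   zone boundaries: z1 = 162, z2 = 430
#>   ratio parabola vertex at slice 255.3
#>   total 201.3 s
print(report$zones)
#>                 zone   volume_mm3 cell_number  density
#>   epiphysis_proximal 0.0030487687         206 67568.26
#>            diaphysis 0.0069670445         284 40763.34
#>     epiphysis_distal 0.0009415832          77 81777.16
```

The phantom drew 595 nuclei; the pipeline recovers 567 of them (−4.7%,
losses are deeply interpenetrating pairs that erosion cannot split) and
an overall density of 51,746 cells mm⁻³ — inside the 30,000–110,000
cells mm⁻³ range reported for cartilage by independent imaging methods.
The epiphyseal densities come out roughly twice the diaphyseal one, as
built into the phantom, and the nuclei/ECM ratio parabola bottoms out at
slice 255, the centre of the diaphysis. `run42/` holds every
intermediate: `filtered.tif`, `mask.tif`, `masked.tif`, `classmap.tif`,
`labels.tif`, `blobs.csv`, `profile.csv`, `summary.json`,
`polarity.csv`, `report.json`.

Individual stages are plain functions on explicit containers:

```r
ph   <- generate_phantom(phantom_spec(seed = 42))
filt <- median3d(ph$volume, radius = 3)
init <- init_contour(filt$data[256, , ], "auto", seed_point = c(127.5, 127.5),
                     slice_index = 255)
mask <- dilate_mask(segment_element(ph$volume, filt, snake_params(), init), 1)
cm   <- kmeans_classify(apply_mask(ph$volume, mask))
blobs <- filter_blobs(blob_metrics(split_blobs(class_binary(cm, 2))), 27)
count_cells(blobs)
#> [1] 567
```

A thin command-line dispatcher over the same functions lives at
`exec/chondroquant` (subcommands `generate`, `filter`, `segment`,
`classify`, `blobs`, `profile`, `polarity`, `run`).

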