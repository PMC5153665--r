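# sogseg

Segmentation and object analysis for genetically labelled volume electron
microscopy.

Genetically encoded EM labels (miniSOG expressed in a cell population,
photo-oxidising DAB into an osmiophilic precipitate) make targeted
structures — mitochondria, the cytosol of projection neurons — appear as
high-contrast objects inside SBEM and FIB-SEM image stacks. `sogseg`
implements the computer-assisted procedures used to pull those structures
out of the volume, for microscopists and image analysts who need the
selection criteria to be explicit and replayable rather than buried in an
interactive session:

* **Bulk segmentation** — select every voxel in a closed intensity range
  `[lo, hi]`, split the mask into 3D connected objects (6/18/26
  connectivity), then discard objects with fewer than `n_min` voxels or
  physical volume below `V_min` (non-specific background; the classic SBEM
  setting is `< 10` voxels, `< 0.0002 µm³`), and objects whose voxel
  intensity population variance exceeds `σ²_max` (highly contrasted
  membrane segments). Every removal is logged with its criterion.
* **Seed segmentation** — 3D region growing from a point seed, constrained
  to `[lo, hi]`: the result is exactly the connected component of the
  thresholded mask containing the seed. Iterative trial series hold `hi`
  at a common maximum and lower `lo` in steps of a fixed fraction
  (typically 0.2–0.4%) of the *true range* — the observed min-to-max
  intensity span — producing nested ROIs that progressively incorporate
  distal neurites, then crossovers and other high-contrast structures.
* **Object analysis** — per-object voxel count, physical volume, intensity
  statistics, centroid, principal axes from the eigen-decomposition of the
  second central moment tensor of the voxel-centre cloud (axis length
  `2·√(5·λ)`, exact for a solid ellipsoid), aspect ratio (major/minor),
  orientation, and a normalised volume index for volume-ranked display.
* **Preprocessing** — 3D non-local means, Gaussian smoothing in physical
  units, 3×3×1-style block binning (mean reducer; voxel size rescales).
* **Synthetic phantoms with ground truth** — SBEM/FIBSEM-like volumes
  (anisotropic voxels, textured background, sub-cutoff speckle,
  high-variance membrane fragments, branching cells with signal drop-off,
  crossover cells, a trachiole just below the labelling range) so every
  procedure is validated against known truth, including object-level
  precision/recall with greedy IoU matching.

All stacks are `(z, y, x)` arrays with voxel sizes in nm; labelled
structures are high intensity (an invert flag on read handles stain-dark
raw data). I/O is multi-page TIFF plus a JSON metadata sidecar.

## Worked example

```r
library(sogseg)

spec <- phantom_preset("fibsem", grid_shape = c(64, 64, 64), rng_seed = 1)
ph <- make_mitochondria_phantom(spec, n_objects = 5,
                                semi_axis_range = c(60, 100),
                                n_speckle = 10, n_membrane_fragments = 3)
seg <- bulk_segment(ph$volume, separating_range(spec),
                    min_voxels = 10, max_variance = (4 * spec$label_sd)^2)
print(seg$log)
#> <filter_log>  {"op":"bulk_segment","lo":190,"hi":255,"min_voxels":10,...}
#>   min_size: removed 10 object(s) (voxel count < 10)
#>   intensity_variance: removed 3 object(s) (population variance > 400)

evaluate_against_truth(seg$labels, ph$truth, "mitochondria", 0.5)
#> <evaluation_report> class 'mitochondria' @ IoU >= 0.5
#>   objects: precision 1.000, recall 1.000 (5 matches)
#>   voxels:  precision 1.000, recall 1.000

head(compute_features(seg$labels, ph$volume)[,
     c("id", "voxel_count", "volume_um3", "intensity_mean", "aspect_ratio")])
#>   id voxel_count volume_um3 intensity_mean aspect_ratio
#> 1  1        1852   0.001852       199.8834     1.505717
#> 2  2        2108   0.002108       199.9929     1.415953
#> 3  3        1559   0.001559       199.8717     1.037436
#> 4  4        2110   0.002110       200.0526     1.133752
#> 5  5        1880   0.001880       199.9548     1.237073
```

The ten sub-cutoff speckles fall to the size filter, the three bimodal
membrane fragments to the variance filter, and the five mitochondria are
recovered exactly — every volume is plain voxel count × voxel volume, and
intensity means sit at the phantom's label mean of 200.

The same stages are available as a command line:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/sogseg.R", package="sogseg"))') \
  simulate --preset mito-sbem --grid 96,96,96 --seed 1 \
  --out volume.tif --truth truth
```

with subcommands `simulate`, `preprocess`, `segment-bulk`, `segment-seed`,
`analyze`, `evaluate` and `pipeline` (single YAML config, byte-identical
outputs for a fixed seed).

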