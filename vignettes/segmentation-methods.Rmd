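---
title: "Segmenting genetically labelled structures in volume EM: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting genetically labelled structures in volume EM: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sogseg)
```

## The problem

A genetically encoded EM label (miniSOG photo-oxidising DAB into an
osmiophilic precipitate) renders a chosen cell population or organelle
class electron-dense. In a stained SBEM or FIB-SEM volume the labelled
structures then occupy a distinct, narrow band of the intensity histogram,
well separated from neuropil background — which is what makes simple,
fully auditable segmentation strategies viable where general EM
segmentation would need learned models. `sogseg` implements two such
strategies plus the object analysis that follows them, with every
selection criterion recorded so the segmentation can be replayed exactly.

Throughout, volumes are `(z, y, x)` arrays with per-axis voxel extents in
nanometres. Indices are 1-based (the native R convention) and the centre
of voxel `i` along an axis of extent `s` sits at `(i - 0.5)·s` nm, so all
physical quantities are invariant to the indexing base. Labelled
structures are *high* intensity in the working representation; raw EM
data in which stain is dark is inverted on read (`read_stack(invert =
TRUE)`).

## Bulk segmentation

Given a closed range `[lo, hi]` (both bounds inclusive — a probe-selected
minimum and maximum), `bulk_segment()` composes:

1. `threshold_range()` — all voxels with `lo ≤ v ≤ hi`;
2. `connected_components()` — 3D labelling under 6-, 18- or
   26-connectivity. The default is 26: corner-adjacent voxels connect, as
   in typical 3D visualisation software. Labels are assigned in the scan
   order of each object's first voxel, so labelling is deterministic;
3. `filter_min_size()` — remove objects with voxel count strictly below
   `min_voxels` *or* physical volume strictly below `min_volume_um3`.
   High-contrast but low-volume objects are non-specific background; the
   classic SBEM setting is `< 10` voxels / `< 0.0002 µm³`, a consistent
   pair at the 3×3×1-binned SBEM voxel (10 × 50 × 18.9 × 18.9 nm³ =
   1.786×10⁻⁴ µm³ ≈ 2×10⁻⁴ at one significant figure);
4. `filter_intensity_variance()` — remove objects whose intensity
   *population* variance (divide by N) exceeds `max_variance`. This
   targets large, highly contrasted membrane segments whose in-range
   voxels are strongly bimodal, unlike compact DAB-filled organelles whose
   intensities are narrowly distributed.

The size filter runs before the variance filter, following the order in
which the criteria are naturally applied (cheap bookkeeping first, then a
statistic). Both filters are idempotent and each removal is logged with
its parameter and reason (`filter_log_table()`), giving a robust record of
the selection criteria used.

No universal `max_variance` exists for real data — it depends on stain,
detector and preprocessing — so the argument has no default in
`bulk_segment()` pipelines on real stacks and must be chosen from the
data. For phantoms generated here, `(4·label_sd)²` cleanly separates the
two populations (see below). Variance is computed on whatever volume is
passed in, i.e. on the preprocessed working volume in the default
pipeline; computing it on raw intensities instead is a matter of passing
the raw grid.

## Seed segmentation and trial series

`grow_from_seed()` performs FIFO flood fill from a seed voxel constrained
to `[lo, hi]`; the result equals the connected component of the
thresholded mask containing the seed, and the test suite asserts exactly
that equivalence against the bulk pipeline on random volumes. A seed
whose own intensity lies outside the range is an error (a mis-placed
seed), except inside a trial series where it yields an empty trial with a
recorded error, mirroring exploratory use.

`run_trial_series()` implements the iterative widening strategy: hold
`hi` at a common maximum and lower `lo` by a fixed step per trial, where
`step = step_fraction × (true-range width)` and the *true range* is the
observed min-to-max span of the working volume (`true_range()`; a flag
substitutes the nominal bit-depth domain). Step fractions of 0.002–0.004
— 0.2–0.4% of the true range — give the fine-grained series in which
trial 1 traces the seeded cell body and primary neurites, later trials
incorporate increasingly distal structures, and sufficiently low ranges
pull in overlapping cells ("crossovers") and non-neuronal high-contrast
structures such as trachioles. The step is computed once per series, not
per trial. Because lowering `lo` only enlarges the thresholded mask, the
ROIs are nested (`roi_k ⊆ roi_{k+1}`) and voxel counts are
non-decreasing; both are asserted per series in the tests.

`multi_seed_trace()` grows several seeds at one shared range; seeds that
land in the same component receive the same object id and the merge is
reported, and only seeded components are labelled.

## Object analysis

`compute_features()` reports per object: voxel count; physical volume
(voxel count × voxel volume — exactly additive by construction);
intensity mean/min/max/population variance; centroid in µm; principal
axis lengths; aspect ratio; orientation. Shape comes from the second
central moment tensor of the voxel-centre point cloud in physical
coordinates (so ~8× anisotropic SBEM voxels do not bias orientation),
unweighted by intensity. A continuous solid ellipsoid of semi-axis `a`
has second moment `a²/5` along that axis, so axis lengths are reported as
`2·√(5·λ)` — the full axis `2a` exactly in the continuous limit. The
convention is calibrated by test rather than asserted: rasterised solid
ellipsoids of ≥ 10⁴ voxels recover full axis lengths within 5% (measured
~0.1%) and a 2:1 aspect ratio within 0.05. Each length is floored at the
smallest voxel extent, since no imaged object is thinner than a voxel —
this keeps aspect ratios finite for collinear voxel sets; a single-voxel
object reports the voxel extents themselves as degenerate axes. Aspect
ratio is major/minor. `rank_by_volume()` adds the normalised volume index
`(v − v_min)/(v_max − v_min)` used for blue-to-red volume-ranked display,
with a single object mapping to 0.

`evaluate_against_truth()` matches predicted to ground-truth objects
one-to-one, greedily by descending IoU, at a configurable threshold;
object precision/recall, voxel precision/recall and per-match relative
volume errors are reported. An empty prediction has precision 1 by
convention (no false positives) and is flagged as such.

## The phantom generator

The phantoms reproduce the statistical structure the procedures assume,
with known per-class truth masks and an object catalogue whose count
always equals the connected-component count of each class mask:

* **Geometry presets** — anisotropic SBEM voxels (6.3 × 6.3 × 50 nm and
  10.5 × 10.5 × 25 nm) and near-isotropic FIB-SEM voxels (10 nm). All
  placement and radii are specified in nm and rasterised per axis.
* **Intensity model** — background `N(100, 10)` plus band-limited texture
  (white noise smoothed to a 100 nm granularity, sd 8 by default);
  labelled voxels from a Gaussian `N(label_mean = 200, label_sd = 5)`
  *clamped* to `[label_mean − 2·label_sd, 255]`. The clamp models the
  saturating density of the DAB precipitate and guarantees by
  construction that the *separating range* `[label_mean − 2·label_sd,
  bit-max]` contains every labelled voxel while background (≥ 7 sd away)
  essentially never enters it — the property both segmentation strategies
  rely on. Volumes are quantised to integer 8-bit values, like real
  exported stacks; this also makes TIFF round trips bit-exact.
  `label_sd = 5` is deliberately small relative to the 65-unit separating
  range so that a bimodal distractor spanning that range has variance
  (~1000) far above a compact object's (~25), giving the variance filter
  a working point at `(4·label_sd)² = 400`.
* **Mitochondria phantom** — randomly oriented solid ellipsoids
  (semi-axes 150–300 nm by default: above the 10-voxel cutoff even after
  3×3×1 binning, volumes in the 10⁻³–10⁻¹ µm³ range of real labelled
  mitochondria), plus two distractor classes: *speckle* (random-walk
  blobs of 1–9 voxels at label intensity — always under the size cutoff)
  and *membrane fragments* (single-slice elliptical sheets whose voxels
  alternate between the bit maximum and the bottom of the separating
  range). Fragment intensities stay inside the range deliberately:
  voxels below the threshold would simply be excluded from the mask and
  could never influence a post-threshold filter, so a high-variance
  distractor must be bimodal *within* the range — which is exactly what a
  strongly contrasted membrane looks like after range selection. All
  objects are placed by uniform rejection sampling with a one-voxel
  bounding-box clearance (hard cap of 1000 attempts per object, then an
  error naming the class), so distinct objects are never 26-adjacent.
* **Neurite phantom** — a soma sphere plus a recursively branching
  capsule tree (depth in segment generations; 0 = soma only), with signal
  drop-off: a segment that has passed `g` branch points has intensity
  mean `label_mean·(1 − dropoff)^g`, and segments above a calibre
  threshold take one extra factor. This emulates the weaker labelling at
  dendritic branch points and in large-calibre profiles that makes seeded
  growth terminate early. Optional crossover cells are independent trees
  whose somata cluster against the primary soma (masks touch; contested
  voxels belong to the earlier-rendered cell and each cell mask is kept
  as one connected object, with displaced voxels counted in the
  catalogue). The optional trachiole is a constant-intensity tube a few
  units *below* the separating range, so a trial series incorporates it
  at the analytically predictable step — observed and predicted trials
  agree exactly in the acceptance checks.

What the phantom does **not** emulate: electron-optical noise statistics,
charging/curtaining artefacts, membrane ultrastructure (synaptic
densities, vesicles), stain gradients across the block face, or stack
misalignment. Passing the recovery tests therefore demonstrates that the
procedures are implemented correctly and behave as specified under the
assumed contrast model — not that the default parameters transfer to any
real specimen; on real data the range, cutoffs and variance threshold
must be chosen from the data, as they were in the original interactive
workflow. No quantitative SNR or label-to-background contrast is
available for the real volumes, so the phantom defaults are chosen for
testability, not fidelity.

## Preprocessing

* `denoise_nlm()` — 3D non-local means, patch 3³, search window 7³
  (recorded in provenance), weight `exp(−max(d² − 2σ², 0)/h²)` with
  `h = σ` by default; `σ = 5` is the working default for SBEM stacks.
  `σ = 0` is the identity; constants are fixed points.
* `gaussian_smooth()` — separable Gaussian with the scale in nm per axis,
  converted through the voxel size; mirror-reflect boundary, under which
  the normalised symmetric kernel conserves total intensity exactly
  (asserted to 10⁻⁶ relative).
* `bin_volume()` — block mean (not sum, so ranges stay comparable across
  binning); trailing voxels that do not fill a block are dropped; the
  voxel size multiplies by the factors. Factors are `(z, y, x)`, so
  in-plane 3×3 binning is `c(1, 3, 3)`.
* `unsharp_mask()` — exposed for presentation parity but off by default
  and excluded from the tested pipeline.

The default pipeline order is denoise-then-bin; both stages are optional
and configurable. Whether to denoise before or after binning is a free
choice here — the two differ only mildly at these scales.

## I/O and reproducibility

Stacks, label volumes and truth masks travel as multi-page TIFF
(deflate, fixed settings) with a JSON sidecar carrying voxel size, bit
depth, axis order, dataset reference and the append-only provenance list;
HDF5 is not provided in this build. Writing quantises to the declared bit
depth; integer-valued volumes round-trip bit-exactly, and two writes of
the same volume are byte-identical. `slice_count()` checks declared
z-section counts against stated depth/step geometry; printed acquisition
tables are off by one in practice, so a one-slice mismatch warns while
larger mismatches fail.

Every stochastic component is a pure function of its parameters and an
integer seed; `run_pipeline()` (and the `pipeline` CLI subcommand) runs
simulate → preprocess → segment → analyze → evaluate from one
configuration and produces byte-identical outputs across runs with the
same seed.

## Numerical choices and test scales

Flood fill and component labelling use FIFO traversal from a
deterministic scan order; the set-valued results are order-independent,
the traversal logs reproducible. Greedy IoU matching breaks ties by
ascending object id. The moment eigen-decomposition uses the symmetric
solver; eigenvalues are clipped at zero before the square root.

The validation suite runs the bulk recovery benchmark at the full 256³
SBEM-preset phantom (50 mitochondria, 200 speckles, 20 membrane
fragments), component-labelling equivalence against a brute-force BFS
oracle on 10⁴ random 3×3×3 masks under all three connectivities, seeded
growth equivalence on random 8³ volumes, 12-trial series on 64×128×128
neurite phantoms, and ellipsoid calibration at ~6.7×10⁴ voxels — sizes
chosen so each property is exercised at meaningful scale while the whole
suite completes in a few minutes on one CPU.

## Known limitations

* No slice-alignment (StackReg-style) or stain-gradient correction;
  volumes are assumed registered.
* Connectivity of the original interactive tools is unknown; 26 is the
  default and 6/18 are exposed.
* Mesh-based surface features (area, curvature) are out of scope; volumes
  are voxel-count based.
* The variance filter assumes membrane-like distractors are *bimodal
  within the selected range*; a membrane uniformly at label intensity is
  indistinguishable from signal by intensity statistics alone.
* Seed placement is manual (a voxel index); no automatic seed proposal.
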