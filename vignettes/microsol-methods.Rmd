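---
title: "Quantifying microglia activation by tridimensional solidity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglia activation by tridimensional solidity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microsol)
```

## The biological readout

Microglia, the resident immune cells of the retina and CNS, change shape
when they activate: resting cells are highly ramified, with long thin
processes radiating from a small soma, while activated cells retract their
processes and become amoeboid. `microsol` quantifies this transition from
confocal z-stacks of Iba1-stained tissue with a single dimensionless shape
descriptor, **tridimensional solidity**: the ratio of a cell's volume to the
volume of its convex hull — the smallest region that (1) is convex and
(2) contains the cell. A round, amoeboid cell nearly fills its hull
(solidity near 1); a ramified cell's hull spans the reach of its processes,
most of which is empty space (solidity near 0). Group-level comparisons are
then made on the mean cell solidity per eye.

## Solidity as a lattice-count ratio

Both "volume" and "convex volume" are realized as **lattice-point counts**:
the number of voxels in the cell, divided by the number of lattice points
lying inside or on the convex hull of the cell's voxel centers. This
discrete definition has two properties a continuous hull volume of voxel
centers lacks:

* a digitally convex object (filled cuboid, digital ball) scores **exactly
  1** — with a continuous hull volume a filled \(n\)-cube would score
  \(n^3/(n-1)^3 > 1\);
* solidity is bounded by 1 and invariant to axis-aligned translation, axis
  permutation, reflection, and to the physical voxel spacing, because
  affine maps preserve hulls and the lattice correspondence.

The hull is built by incremental insertion with visibility/horizon updates
(quickhull-style). Before hull construction, voxels strictly between their
(y, x)-column's z-extremes are dropped — each is a convex combination of
the two kept endpoints, so the hull is unchanged and the vertex candidate
set shrinks sharply for filled objects. Membership uses facet half-space
tests on unit-normalized facets with tolerance 1e-9; boundary points count
as inside, honouring "contains the original region". Degenerate cells fall
back to hulls in their affine span: a single voxel counts 1, collinear
cells count lattice points on their segment, coplanar cells count lattice
points inside the 2D hull polygon. The test suite checks the counts against
an exhaustive, independently coded oracle that enumerates every triple of
points, keeps the planes with all points on one side, and tests every
bounding-box lattice point against those half-spaces.

## The image-processing chain

Each stack passes through, in order:

1. **Background estimation** — grayscale morphological opening (erosion
   then dilation) with a flat digital disk, slice by slice. Opening is
   anti-extensive, so the estimate never exceeds the image. It is applied
   in 2D because background in confocal stacks is dominated by per-plane
   illumination, and the axial step (2.5 um) is far coarser than the
   lateral pixel (~1.3-1.5 um), making a 3D ball ill-shaped. The disk
   radius (default 50 px) must exceed the footprint of a cell; it is the
   scale that separates "cells" from "illumination". The morphology is
   implemented with monotonic-queue running extremes (cost independent of
   the radius) and clipped windows, so a constant image is a fixed point.
2. **Subtraction**, clamped at zero — negative fluorescence is physically
   meaningless and would distort the threshold histogram.
3. **Otsu binarization** — one global threshold per stack from the pooled
   3D histogram (256 bins by default), maximizing between-class variance,
   so a single consistent mask spans all z-planes. The mask keeps voxels
   *strictly above* the threshold; ties go to background, making the
   binarization deterministic. The filter is applied after binarization
   only; no pre-threshold smoothing is added, keeping the measured voxel
   counts interpretable.
4. **Majority (median) denoising** — each voxel takes the strict majority
   of its (2r+1)^3 cube neighbourhood (r = 1 by default). For binary images
   the median and majority filters coincide. Border neighbourhoods are
   clipped; exact ties (possible only there) resolve to background.
5. **Object detection** — connected components under 26-connectivity,
   which preserves the continuity of thin diagonal processes, labelled in
   raster order of first voxels for determinism, then gated by object size
   (default 30 to 1e5 voxels). Clusters of touching cells pass this gate
   deliberately; they are resolved in the next step.
6. **Bright-center seeding and splitting** — somata are the bright centers
   of cells. The background-subtracted intensity is Gaussian-smoothed in
   xy only (sigma 2 px; the z-step is too coarse to smooth across planes
   without merging somata), local maxima are collected inside objects, and
   two cuts make "bright center" operational: a maximum must reach a
   fraction (default 0.75) of its object's smoothed peak, and no two seeds
   may lie within 8 px in xy (greedy thinning, brighter seed wins, raster
   order on exact ties). Every object keeps at least one seed. A seeded
   watershed then floods each object from its seeds, brightest front
   first, constrained to the object's voxels — a partition, so voxel
   counts are conserved. Single-seed objects pass through unchanged.
   The relative-brightness cut is a deliberate addition: without it, noise
   wiggles along dim processes produce spurious local maxima and fragment
   every ramified cell. Intensity maxima (rather than distance-transform
   maxima) define centers because somata are genuinely brighter than
   processes in this staining.
7. **Shape/size filtering** — remaining non-cellular objects are discarded
   if their voxel count leaves [50, 2e4], if their principal-axis
   elongation exceeds 12, or if their extent (count / bounding box) falls
   below 0.02. Elongation is the ratio of the longest to shortest
   principal-axis *length* — square roots of the eigenvalues of the
   physical-coordinate covariance. Using raw eigenvalue ratios would
   discard every genuine cell in a flat-mount stack: stacks are ~25 um
   deep while ramified cells spread ~50 um laterally, putting the variance
   ratio near 50 for perfectly good cells, whereas the length ratio stays
   near 7 and cleanly separates fibers (~40). The covariance gets
   + spacing^2/12 on its diagonal (a voxel is a box, not a point), so
   single-plane objects have finite axial spread rather than an infinite
   ratio.
8. **Measurement and aggregation** — per-cell solidity, then the mean over
   all cells pooled across an eye's lesion images (the alternative,
   averaging lesion means, is available via `aggregate = "lesion-mean"`).
   Cells touching the volume border are excluded from eye means by default
   because truncated processes inflate solidity; the flag is preserved so
   users can include them.

All cutoffs live in `preprocess_params()` / `segmentation_params()` and in
the YAML config consumed by the pipeline commands; every effective value is
echoed to the run log, and unknown config keys are rejected.

## Companion readouts

* **Stained-area density** (flat-mounts): maximum-intensity projection,
  fraction of pixels above a threshold shared within each experiment arm
  (Otsu on the arm's pooled histogram — per-image thresholds would
  confound density comparisons), eye means, then normalization to the
  control arm's grand mean (control averages 100 by construction).
* **OCT ratio**: lesion swelling as (b - c)/c, b the lesion thickness and
  c the adjacent choroid thickness.
* **qRT-PCR expression ratio**: 2^(mean Ct_NOR - mean Ct_GOI). With
  several housekeeping normalizers the Ct values are pooled into one mean
  before the formula; geometric averaging of normalizer expressions would
  differ only by a constant factor per sample set.
* **Group statistics**: Mann-Whitney U with exact enumeration when the
  combined sample size is at most 12 without ties (the regime of typical
  in-vivo group sizes) and a tie- and continuity-corrected normal
  approximation otherwise; Kruskal-Wallis for more than two groups.
  Post-hoc multiple-comparison procedures are out of scope.

## The synthetic-data generator

Every stage is exercised on synthetic Iba1-like stacks with voxel-level
ground truth, generated by `generate_scene()` / `generate_cohort()`:
ellipsoidal somata (spheres in physical um on the anisotropic lattice) with
a smooth Gaussian intensity peak (peak 200, processes 120), random-walk
process tubes whose count/length/width/waviness define the phenotype
(ramified: 6 processes of ~20 um; amoeboid: one short stub and a larger
soma), a linear background ramp (offset 20, amplitude 15), and Gaussian
noise (sd 8, i.e. 4% of the soma peak), clipped at zero and quantized to
integer gray levels. The default acquisition geometry is a 780 um square
field at 512 px (dx = dy = 780/512 um) with a 2.5 um z-path, and cells sit
near one focal depth, as flat-mounted cells do. All generators are pure
functions of a single integer seed; per-image and per-cell seeds derive
from it by a fixed splitting rule, so any sub-object is reproducible.

Two generator choices are dictated by resolution, not realism: processes
are drawn 5-6 um wide and walk within their focal plane. Real microglia
processes are ~1 um — far below what a 2.5 um z-step and ~1.3 um pixels can
represent; thinner synthetic processes would be erased by the prescribed
cube-majority median and would make the ramified phenotype untestable
rather than more faithful. Consequently passing tests demonstrate that the
chain recovers cells and ranks phenotypes correctly *at the sampled scale*;
they do not show robustness to sub-resolution processes, out-of-focus
light, PSF anisotropy or spectral crosstalk, none of which the generator
emulates.

## Problem sizes used by the test and acceptance suites

Simulation-backed checks run at reduced field sizes with the same lateral
sampling class as the full default (and identical z geometry), a choice
made once for the whole suite: segmentation-recovery uses 50 seeded scenes
of 10 cells in a 320 um field at 256 px with centroids at least 60 um
apart; the two-arm cohort uses 5 eyes x 4 lesion images per arm with 5
cells per 240 um / 192 px stack. On these conditions the chain recovers
exactly 10/10 cells with per-cell IoU >= 0.7 against ground truth in all
50 scenes, separates the arms' per-eye mean solidity with an exact
Mann-Whitney p below 0.05, and rank-correlates measured with true per-cell
solidity above 0.9 — the acceptance suite recomputes all of these.

## Numerical conventions and edge cases

* Arrays are (z, y, x), z fastest, matching page-major TIFF layout; "raster
  order" means ascending linear index in that layout.
* Voxel spacing is supplied by the caller or manifest, never parsed from
  TIFF metadata dialects (unreliable across vendors). Multichannel TIFFs
  are rejected rather than silently reduced.
* Otsu on a constant image, an empty control arm in density normalization,
  Kruskal-Wallis on all-identical observations, and seed placement in an
  infeasible field all fail loudly with distinct messages instead of
  propagating NaN.
* Watershed ties (equal priority) and seed-thinning ties (equal
  brightness) break by insertion/raster order, so reruns are bit-identical.
* Eyes left with zero eligible cells are omitted from per-eye tables,
  never reported as NaN.

## Known limitations

Lesion boundaries are not delineated (density is measured on whole
images); there is no deconvolution, flat-field calibration, or adaptive
thresholding; no skeleton/Sholl morphometrics; no learning-based
segmentation; and clusters denser than the seeding distance (8 px) with
near-equal soma brightness may under-split. The generator's phenotype gap
(ramified vs amoeboid true solidity roughly 0.2 vs 0.9) is wider than
biological variation; discriminating subtler shifts would need larger
cohorts than the defaults.
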