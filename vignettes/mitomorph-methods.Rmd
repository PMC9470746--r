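---
title: "Quantifying mitochondrial network morphology with mitomorph"
author: "mitomorph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial network morphology with mitomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomorph)
```

## The problem

Mitochondria continuously fuse and fragment, and the balance between the
two shapes the organelle population into anything from dispersed short
tubules to hyperfused networks. In somatic cells that support the oocyte
(cumulus cells), the state of this network is informative about metabolic
activity, and it is typically read out from two very different kinds of
image: live-cell fluorescence of membrane-potential-dependent dyes
(2D confocal sections of TMRM-stained cells) and volume electron microscopy
(FIB-SEM stacks with nanometre voxels). `mitomorph` implements one coherent
morphometry pipeline for both, together with a synthetic-scene generator
that provides exact ground truth for validation.

The quantities of interest are those standard in the field:

* the **element decomposition** of each connected network component into
  *ends* (skeleton endpoints), *tubules* (maximal junction-free paths) and
  *junctions* (branch points), with an unbranched organelle having exactly
  three elements (two ends, one tubule);
* the **cluster rule**: a component with more than seven elements counts as
  a clustered form, otherwise it is branched (has a junction) or isolated;
* a probabilistic **length distribution** over the underlying mitochondria;
* **connectivity**, a scalar fusion-state summary;
* in 3D, per-object **volumes**, **minimum/maximum Feret diameters**,
  watershed separation of fused clusters, and per-phenotype abundance and
  volume coverage;
* the **Earth-mover distance (EMD)** between length distributions of two
  conditions, with a permutation test.

## Skeletons and elements

Binary masks (8-connected in 2D, 26-connected in 3D) are thinned to a
one-point-wide skeleton by sequential removal of simple points. In 2D a
pixel is removed when its deletion preserves local topology (Yokoi
connectivity number equal to one) and it is not a curve endpoint; four
directional subiterations per cycle keep the result medial. In 3D the
simple-point test uses the standard two-criterion characterization (one
26-connected foreground component among the 26 neighbors, one 6-connected
background component in the 18-neighborhood touching the center), with six
directional subiterations. Both passes fix the candidate border set before
deleting, so erosion cannot cascade along the scan direction.

Because thinning assumes isotropy, 3D volumes are first resampled (nearest
neighbor) to an isotropic grid at the smallest axis spacing — FIB-SEM
voxels are typically twice as deep as they are wide — and all coordinates
are carried in physical micrometres afterwards.

The skeleton becomes a spatial graph: nodes at pixel/voxel centers, edges
between raster neighbors with physical step lengths. Two conventions keep
the graph faithful to the geometry rather than to rasterization artifacts:

* **redundant diagonal edges** are dropped when the same connection exists
  through a less-diagonal intermediate point (otherwise every staircase
  corner becomes a spurious triangle);
* **junction merging**: thinning produces clumps of adjacent degree-3
  pixels at a single biological branch point; all degree-≥3 pixels within a
  chessboard radius of 2 px merge into one junction. Without this the
  element count of a branched shape would depend on the rasterization
  angle, inflating the seven-element cluster rule.

Terminal spurs shorter than `pruneSpurUm` (default 0.1 µm) are pruned:
medial-axis whiskers at that scale are artifacts of boundary roughness, not
branches. The default is configurable and logged in every report.

### Length estimation

Two systematic raster effects need compensation:

* a summed 8/26-connected step length overestimates oblique straight lines
  by up to 8%; chain lengths are therefore measured on a chord-resampled
  polyline (every third skeleton point), which removes the staircase zigzag
  while following genuine curvature. `componentLength()` keeps the raw
  geodesic sum, so the two estimates are separately available;
* the thinned skeleton of a round-tipped object retreats from the tip by
  about one tube radius; each skeleton endpoint therefore stores its
  distance to the object boundary (from an exact anisotropic Euclidean
  distance transform), and pipeline lengths add this tip correction at
  every leaf.

With both corrections, noise-free synthetic tubules of 1–7 µm at
0.1 µm/px are recovered within max(2 px, 5%) at all orientations on a 15°
grid (asserted in the tests).

## The probabilistic structure interpreter

A connected skeleton is ambiguous about the underlying organelles: at each
junction, two incident branches may continue as one mitochondrion, or
separate organelles may terminate there. The interpreter enumerates, at a
junction of degree *d*, every partial matching of the *d* incident branch
stubs (4 matchings for *d* = 3, 10 for *d* = 4 — the involution numbers);
the Cartesian product over junctions defines the decomposition space of the
component. Each matching combination glues skeleton chains into paths;
combinations that close a loop or thread one junction twice do not
correspond to a partition into simple paths and are discarded. A component
that is a pure ring admits no such partition and is reported as a single
cyclic path, flagged.

Each decomposition receives equal weight 1/D within its component, and
every constituent path contributes 1/D as a count; counts accumulate over
all components and are normalized globally. Consequences of this
convention (fixed before any recovery experiments, and encoded in an
independent brute-force oracle in the test suite):

* a component's total mass is proportional to its mean path count, so a
  large cluster contributes more mitochondria than a single tubule — the
  behavior one wants when pooling a whole cell;
* with no junctions anywhere, the distribution reduces exactly to the
  empirical histogram of component lengths.

For a Y with unit arms the four decompositions ({1,1,1} and three {2,1})
give mass 2/3 at 1 µm and 1/3 at 2 µm. Enumeration is capped at
`maxEnumeration` (default 10,000) combinations; beyond the cap,
combinations are sampled uniformly with a recorded seed and the output is
flagged. Distributions are binned at 0.25 µm over [0, 10] µm by default,
the scale of the confocal observations (0.5–7 µm).

**Connectivity** is junctions / (junctions + ends), summed over the
population: 0 for fully fragmented populations, approaching 1 for
hyperfused ones. A population of pure cycles (no ends, no junctions) is
defined as 1 and flagged. This ratio is one of several reasonable
conventions; it is recorded as an assumption in every report, and reported
values should be compared only within analyses using the same convention.

## Phenotypes

Components: clustered iff elements > 7 (so a Y with exactly 7 is *not*
clustered), else branched iff at least one junction, else isolated. The
threshold is a parameter. In 3D the rule gains a second criterion: a
component is also clustered when watershed splitting finds ≥ 2 physically
distinct sub-objects, since a fused pair of round organelles has only three
skeleton elements but is not a single mitochondrion.

Cells: the cell statistic is the weighted median of the pooled length
distribution — robust against one large cluster dominating the mean — and
the label thresholds are 1, 2 and 4 µm for short / intermediate / long /
very long. The original cell assessments of this kind were manual; these
thresholds are an explicit, configurable substitute that makes the
procedure deterministic. The median uses the smallest bin midpoint at which
cumulative mass reaches 0.5; an exact 50/50 split therefore resolves to the
lower bin.

## The 3D arm

Components are labeled with 26-connectivity. For each component:

* **watershed splitting**: seeds are regional maxima of the exact
  anisotropic Euclidean distance transform, merged when closer than
  `seedMinDistanceUm` (default 0.15 µm, the organelle radius scale);
  flooding the negated distance transform assigns every voxel to exactly
  one sub-object. Basins are then merged by a prominence criterion
  (`hMinUm`, default 0.05 µm): two sub-objects stay distinct only if each
  basin's distance-transform peak exceeds their contact saddle by at least
  this depth. The flat ridge of a tube and the slightly deeper pocket at a
  branch junction produce shallow maxima that would otherwise fragment
  genuinely single organelles, while the neck between two fused round
  organelles is a deep saddle and survives;
* **volume** is voxel count × voxel volume, exact arithmetic;
* **Feret diameters**: the maximum is the largest pairwise distance between
  surface-voxel centers (candidates taken as directional extremes over 256
  quasi-uniform directions), the minimum is the smallest directional
  extent; both add one mean voxel diagonal, since voxel-center extents
  understate the physical surface by about half a voxel per side. All
  projections use physical coordinates, so anisotropic stacks measure
  correctly (the tests include a regression guard: measuring a z-aligned
  tube in voxel units would be ~2x off).

The scene report gives per-phenotype abundance (fraction of entities),
volume coverage (fraction of total volume), the size distribution of
isolated forms by maximum Feret diameter (< 1, 1–2, > 2 µm), and the total
volume in µm³.

## Comparing conditions

The 1D EMD between two binned distributions is the integrated absolute
CDF difference, `sum |F1 - F2| * binwidth`, in micrometres; distributions
on different grids are resampled onto a common uniform grid assuming
uniform density within bins. Significance uses a permutation test at the
cell level — cells, not pooled lengths, are the experimental unit — with
pooled per-group CDFs as the statistic and the add-one estimator
`p = (1 + #null ≥ observed) / (1 + nPerm)`, which never returns zero and
is seed-deterministic. Calibration (type-I error within [0.03, 0.07] at
α = 0.05) and power (≥ 0.9 for a +1 µm shift with 20 cells per arm) are
asserted in the acceptance tests over hundreds of simulated repeats.

## The synthetic-scene generator

The generator defines the study conditions for every test:

* 2D objects are capsules: the set of pixels within one tube radius
  (default 0.15 µm) of a centerline, at 0.1 µm/px calibration. The pixel
  size is an assumption — confocal pixel sizes vary by setup — and is
  configurable everywhere. A tubule of requested length *L* is drawn with a
  centerline of *L* − 2r plus hemispherical caps, so the recorded truth is
  the biological tip-to-tip length and matches the tip-corrected pipeline
  estimate. Branched objects carry analytically derived element counts;
  configurations whose tubes would merge away from their attachment points
  are rejected, because the recorded truth would be wrong.
* Rendering follows the standard fluorescence forward model: Gaussian PSF,
  scaled Poisson shot noise (`Poisson(signal * scale) / scale`), additive
  Gaussian read noise and a constant background, all parameters recorded,
  seed-deterministic.
* 3D objects are capsules in physical units on an anisotropic voxel grid,
  defaulting to (0.005, 0.005, 0.010) µm — the FIB-SEM acquisition grid of
  5 nm pixels and 10 nm milling steps. Hemispherical caps avoid the
  skeleton artifacts of flat-ended cylinders. Truth volume is the analytic
  capsule volume πr²L + 4/3 πr³. With `fuse = TRUE`, touching objects share
  one label while the truth retains individual identities for watershed
  validation.

What the generator does *not* emulate: out-of-focus light and the axial
PSF of real confocal stacks, intensity heterogeneity along organelles,
membrane invaginations (cristae), contacts with other organelles, and
segmentation errors of a learned 3D segmenter. Passing tests therefore
demonstrate correctness of the morphometry given a faithful mask, not
robustness to every acquisition artifact.

## Numerical choices and degenerate inputs

* Bin assignment adds a 1e-9 relative epsilon so a length of exactly 1.0
  falls in the [1.0, 1.25) bin despite floating-point representation.
* A single-point skeleton (a round object) is a degenerate isolated
  mitochondrion: two ends, one tubule, length 0 (plus tip correction equal
  to twice its radius when enabled).
* An empty mask skeletonizes to an empty list, but scene-level analyses
  and coverage/report functions on empty inputs raise errors: an empty
  scene has no distribution.
* Otsu thresholding of a constant image is an error; the fixed-threshold
  path requires an explicit threshold.
* Object generation outside image/volume bounds is an error, not a clip:
  silent truncation would corrupt ground truth.
* Problem sizes in the tests (image sides of 128–256 px, volumes of about
  50–140 voxels per axis at 0.02 µm, 200-object recovery experiments, 500
  calibration repeats at 199 permutations) were chosen as the smallest
  scenes in which each property is meaningfully exercised.

## Known limitations

* The interpreter's decomposition space grows with the involution numbers
  of junction degrees; very high-degree junctions are handled by seeded
  uniform sampling rather than full enumeration.
* Chains connecting merged junction pixels are accounted to the junction,
  so a few tenths of a micrometre of skeleton length near each branch
  point is not assigned to any path of the length distribution.
* Watershed prominence merging uses a single global depth threshold; a
  scene mixing very thick and very thin fused organelles may need
  different `hMinUm` values per scale.
* The 3D skeleton of heavily anisotropic, nearest-neighbor-resampled
  volumes can show mild staircase bias along z; lengths are chord-resampled
  but not model-fitted.
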