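# mitomorph

Morphometry of mitochondrial networks from calibrated 2D fluorescence-style
images and 3D volume-EM-style label stacks, for cell biologists quantifying
fusion/fragmentation state — e.g. in cumulus cells, where the network ranges
from scattered short tubules to large fused clusters.

## What it computes

The package skeletonizes binary mitochondrial masks and decomposes every
connected component into the field's element vocabulary:

* **ends** E (degree-1 skeleton nodes), **junctions** J (merged degree-≥3
  clumps) and **tubules** T (maximal junction-free paths). An unbranched
  mitochondrion has 3 elements (2 ends + 1 tubule); a component with more
  than 7 elements is a **clustered** form, otherwise **branched** (J ≥ 1)
  or **isolated**.
* A probabilistic **length distribution**: at a junction of degree *d*,
  incident branch stubs are either paired (one organelle continues through)
  or left unpaired (an organelle terminates), and every combination of
  pairings across junctions is one decomposition of the network into
  organelle paths. All decompositions of a component are weighted equally;
  path counts accumulate over the scene and normalize to a probability mass
  over length bins (0.25 µm over [0, 10] µm by default).
* **Connectivity** = J / (J + E) over the population: 0 when fully
  fragmented, toward 1 when hyperfused.
* Cell phenotype from the weighted **median length** m: short (m < 1 µm),
  intermediate (1–2 µm), long (2–4 µm), very long (≥ 4 µm).
* In 3D: 26-connected labeling, watershed splitting of fused clusters on
  the anisotropic-aware Euclidean distance transform (seeds from regional
  maxima, prominence-merged basins), exact volumes, min/max **Feret
  diameters** with a surface correction, the element/sub-object phenotype
  rule, and per-phenotype abundance and volume coverage.
* Condition comparison by 1D **Earth-mover distance**
  (EMD = Σ |F₁ − F₂| · Δ, in µm) with a cell-level permutation test
  (add-one p-value estimator).

A synthetic-scene generator (capsule tubules, branched shapes, fused
clusters; fluorescence forward model with PSF + Poisson + Gaussian noise;
FIB-SEM-like anisotropic voxel grids at 5/5/10 nm) provides exact ground
truth for every quantity, and the test suite validates the pipeline
end-to-end against it.

## Worked example

```r
library(mitomorph)

# a Y-shaped mitochondrion: 2 um trunk with two 1 um branches
yb  <- generateBranched2D(2, c(1, 1))
img <- renderFluorescence2D(yb$mask, psfSigmaUm = 0.1, poissonScale = 300,
                            gaussianSd = 0.01, background = 0.05, seed = 7)
report <- analyzeScene2D(img)
records(report)
#>   componentId nEnds nJunctions nTubules nElements totalLengthUm lengthUm
#> 1           1     3          1        3         7      4.138478 4.490996
#>   areaUm2 phenotype
#> 1    1.53  branched
report@network$connectivity
#> [1] 0.25
```

One component with 3 ends, 1 junction and 3 tubules — 7 elements, so it is
branched but (at exactly 7) not clustered; connectivity is 1/(1+3) = 0.25.
The tip-corrected length (4.49 µm) approximates the 4 µm of drawn
centerline plus the rounded tips.

The 3D arm, on two spheres (r = 0.2 µm) fused by a neck:

```r
sphere <- function(c0) mitoSpec(rbind(c0, c0 + c(1e-6, 0, 0)), 0.2)
gv <- generateVolume3D(list(sphere(c(0.5, 0.5, 0.5)), sphere(c(0.86, 0.5, 0.5))),
                       voxelSizeUm = rep(0.02, 3),
                       volumeShape = c(50L, 70L, 50L), fuse = TRUE)
rep3 <- analyzeVolume3D(gv$volume)
records(rep3)[, c("nElements", "volumeUm3", "nSubObjects", "phenotype")]
#>   nElements volumeUm3 nSubObjects phenotype
#> 1         3  0.067072           2 clustered
```

The fused pair has only 3 skeleton elements, but watershed finds the two
physical organelles (each recovered within 10% of the analytic sphere
volume), so the component is classified clustered.

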