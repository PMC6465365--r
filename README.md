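# axomorph

Automated 3D segmentation and morphometry of axons in serial block-face
scanning electron microscopy (SBEM) volumes.

Quantitative studies of white matter have traditionally measured axons on
single 2D electron-microscopy sections, implicitly modelling axons as
straight circular cylinders. 3D reconstructions show that this is
precarious: axonal cross-sections are elliptic rather than circular, their
diameter varies substantially along the axis, and a single oblique 2D
section of a tilted axon overestimates its size by a factor of
1/cos(tilt). axomorph implements an automated pipeline that segments the
white-matter ultrastructure of an SBEM stack — myelin, the intra-axonal
space of myelinated and unmyelinated axons, mitochondria, vacuoles, cell
bodies/processes — and quantifies the true 3D morphology of every
myelinated axon, so that group comparisons (e.g. injured vs sham animals)
can be run on per-axon 3D statistics instead of single sections.

## Method at a glance

**Segmentation** is bounded volume growing (BVG) behind edge barriers:
Canny edges per slice (SD √2, hysteresis at 0.25/0.6 of the slice's
maximum gradient), dilated in-plane 3×3, forbid growth; a region grows by
appending every neighbour x with |z(x) − mean(S)| ≤ δ_T (δ_T = 0.1)
against its running mean, capped at ϑ = 10⁶ voxels. Myelin is grown first
(one dark seed, 26-connected, uncapped), seeds for the other structures
are the per-slice distance-transform maxima of the boundary mask, and the
result is refined with SLIC supervoxels (c = 23, ρ = 11, anisotropy-aware
spacing): each large segment claims, serially, every supervoxel it covers
by ≥ 0.8. Rules then annotate the segments: mitochondria are cavities that
close under a 1 µm morphological closing, vacuoles are small and very
bright (< 2×10⁴ voxels, mean ≥ 0.85), an axon is myelinated when its
enclosing supervoxel shell is ≥ 0.7 myelin, and the volume-cap leftovers
become cells by connected components.

**Morphometry** solves the eikonal equation |∇T| F = 1 by multi-stencil
fast marching: T₁ from the axon surface (F = 1) gives the deepest point
x\*; a second map from x\* with speed F₂ = (T₁/T₁(x\*))² finds the two
axon tips; 4th-order Runge–Kutta descent of −∇T₂ at 25 nm steps traces the
sub-voxel centreline, trimmed 1 µm at both ends. Perpendicular
cross-sections on an 8 µm frame at 50 nm resolution are measured by
moment-matched ellipses (minor/major axis, eccentricity = √(1 −
(minor/major)²)) and the equivalent diameter 2·√(area/π); per-axon medians
feed a nested ANOVA (group over animals over axons, F =
MS(group)/MS(animal-in-group)) and a variance-component partition across
cross-section/axon/animal levels. Segmentations are scored against
reference annotations by precision/recall and by weighted Jaccard/Dice
with Hungarian-matched regions, each axon its own region.

A synthetic phantom generator produces SBEM-like volumes (dark myelin
sheaths, bright lumens, dark mitochondria, very bright vacuoles,
membranes, a cell blob, Gaussian noise, 15×15×50 nm voxels) with exact
ground truth, so the whole pipeline is testable without microscope data.

## Worked example

```r
library(axomorph)

ph  <- generatePhantom(phantomSpec(noiseSigma = 0))   # 2.7 x 2.7 x 6 um
cfg <- pipelineConfig(denoise = list(method = "none"),
                      bvg = list(theta = 280000))     # ~1.5x largest axon
res <- runPipeline(ph$volume, cfg)

res$segmentation
ev <- evaluateSegmentation(ph$truth, res$segmentation)
round(c(myelin_wdc = ev$classes$MYELIN$weighted_dice,
        myel_axon_wdc = ev$classes$MYELINATED_AXON$weighted_dice), 3)
res$summary[, c("axon", "length_um", "equivalent_diameter", "eccentricity")]
```

which prints (numbers from this exact run):

```
AxonSegmentation: 180 x 180 x 120 voxels, 25 segments
   MYELIN: 1, MYELINATED_AXON: 4, UNMYELINATED_AXON: 3, MITOCHONDRION: 2, VACUOLE: 2, CELL: 13
  unassigned voxels: 1073 (0.0%)
   myelin_wdc myel_axon_wdc
        0.880         0.918
  axon length_um equivalent_diameter eccentricity
1    3  4.212051            374.2410    0.0000000
2    4  4.232735            482.0438    0.2035455
3    6  4.354600            677.0275    0.2256163
4    7  4.355746            572.5899    0.2341513
```

The four myelinated axons are recovered with weighted Dice 0.92 (myelin:
0.88) against the ground truth; their skeletons run the length of the
volume (≈ 4.2–4.4 µm after 1 µm end-trimming) and the median equivalent
diameters (374–677 nm) track the generating lumen radii. Both seeded
mitochondria are found as cavities and attributed to their parent axons
(review-flagged, as every automated mitochondrion call is).

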