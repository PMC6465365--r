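---
title: "Methods: 3D segmentation and morphometry of axons in SBEM volumes"
author: "axomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D segmentation and morphometry of axons in SBEM volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(axomorph)
```

# Scope and data model

axomorph segments white-matter ultrastructure in serial block-face scanning
electron microscopy (SBEM) volumes — myelin, the intra-axonal space of
myelinated and unmyelinated axons, mitochondria, vacuoles, and cell
bodies/processes — and quantifies the 3D morphology of the myelinated axons.
SBEM stacks are anisotropic: in-plane pixels of roughly 13–18 nm against
50 nm sections, with the slice index being the cutting (z) axis. The package
represents a volume as an `SBEMVolume` (intensities min–max normalized to
[0, 1]; arrays indexed (y, x, z); voxel size in nm), and a segmentation as an
`AxonSegmentation` (integer labels plus a per-segment table of class, size,
parent axon and review flag). Continuous positions (skeletons,
cross-sections) are in nm with voxel centres at `(index - 1) * voxelSize`.

# Segmentation: edge-bounded volume growing

Segmentation proceeds in the order denoise, edge detection, myelin growing,
seeding, serial growing, supervoxel refinement, annotation.

**Denoising** is a pluggable contract (`denoiseVolume`): same shape in and
out, intensities re-clipped to [0, 1]. The default is a small 3D non-local
patch-averaging baseline whose search window respects the z anisotropy;
block-matching transform-domain filters can be plugged in through
`params$external_cmd`. Denoising is not where this pipeline's substance
lies, and on noise-free synthetic volumes the stage can be disabled with no
effect downstream.

**Edges** (`detectEdges`) are Canny contours computed per 2D slice: Gaussian
smoothing (SD $\sqrt 2$ pixels), gradient magnitude, non-maximum
suppression, hysteresis with weak/strong thresholds at 0.25 and 0.6 of the
slice's maximum gradient magnitude. Two numerical choices matter. First,
non-maximum suppression compares against the *bilinearly interpolated*
magnitude one pixel along the true gradient direction; sector-quantized
comparisons leave double-pixel staircase ridges on curved membranes, and
every extra ridge pixel widens the barrier band that later stages must work
around. Second, on a symmetric two-pixel gradient plateau the strict/non-strict
comparison pair keeps exactly one pixel. Raw edges are dilated in-plane with
a 3×3 square element (matched to the ~3× z/x resolution anisotropy, and
configurable); a per-slice threshold normalization is used. A volumetric
mode (3D smoothing, suppression along the full 3D gradient) exists but is
off by default: with 50 nm sections, structure outlines do not continue
smoothly from slice to slice, which is the same reason the dilation is
in-plane only.

**Bounded volume growing** (`bvgGrow`) grows a region from a seed in
batches: every candidate neighbour (6- or 26-neighbourhood) whose intensity
differs from the running region mean by at most $\delta_T = 0.1$ joins in
one iteration, the mean is updated, and candidates rejected earlier remain
candidates (the mean moves). Batch updates make the result independent of
scan order within an iteration. A region reaching the volume cap $\vartheta$
is discarded and its voxels freed; those leftovers are later labelled as
cells. The dark structure (myelin plus mitochondria, jointly `V1`) is grown
first from a single random voxel with intensity ≤ 0.4, 26-connected and
uncapped — one seed suffices because myelin is a connected structure across
consecutive sections. Seeds for everything else come from per-slice
Euclidean distance transforms of the boundary mask `B` (dilated edges ∪
V1): the regional maxima of each slice's transform are the deepest interior
points of the enclosed structures; a plateau contributes its centroid voxel.
Serial growing (`segmentVolume`) processes seeds in slice-major order, skips
seeds claimed by earlier regions, and uses 6-connectivity with
$\vartheta = 10^6$ voxels by default. As a deterministic optimization, a
seed falling inside a previously *discarded* region is skipped when no
region has been accepted since that discard — rerunning the growth would
reproduce the identical discarded region.

$\vartheta = 10^6$ voxels corresponds to roughly 1.5× the volume of the
largest axons at the acquisition scale this default targets; for other
volume sizes the same calibration rule (≈1.5× the largest expected axon)
should be applied, and the phantom-based tests do exactly that.

**Supervoxel refinement.** SLIC supervoxels (`computeSupervoxels`) use the
distance $D = d_{int} + (c/\rho)\,d_{sp}$ with compactness $c = 23$ and grid
step $\rho = 11$; $d_{int}$ is measured on a 0–255 grey scale (the scale the
compactness constant balances against) and $d_{sp}$ in scaled voxel
coordinates. The per-axis scale defaults to $(1, 1, v_z/v_x)$ so a 50 nm
section step counts its true physical length against the fine in-plane
grid; supervoxels then come out compact in physical space. Iterations are
capped at 10 with a 1e-3-voxel centre-shift tolerance, and connectivity is
enforced by merging stray fragments into adjacent supervoxels — the
standard SLIC practice where the originating description is silent.

`refineLabels` then visits large segments (≥ 5×10³ voxels) in ascending id
(the serial creation order). A supervoxel overlapped at least 0.8 by the
segment — ties at exactly 0.8 count — and not already claimed by an earlier
segment is attached *wholly*; this is how edge-barrier voxels and small
fragments are absorbed. One deliberate design choice: segments keep the
voxels the growing stage assigned even where the covering supervoxel is not
claimed. The strict alternative (replacing each segment by the union of its
claimed supervoxels) strips the boundaries of thin structures wholesale:
every supervoxel touching a myelin sheath boundary carries the dilated edge
band, claim fractions there sit around 0.55–0.78, and a replacement rule
deletes most of the sheath (we measured myelin Dice collapsing to ~0.2 on
noise-free phantoms). Augment-and-claim keeps the published rule's purpose —
absorbing small volumes and labelling edges — without the destructive side
effect. Segments still below 5×10³ voxels afterwards are dropped.

**Annotation.** Mitochondria appear as cavities in the axon segments
(they are dark and get swept into `V1` or dissolve as small fragments).
`detectMitochondria` closes each large segment morphologically with a 1 µm
Euclidean ball — dilation and erosion via anisotropy-aware distance
transforms, with the volume padded by the radius so the outside counts as
complement — and takes the difference to the original as candidates,
snapped to supervoxels by the same 0.8 rule. Cavities with inradius below
1 µm close; larger ones do not. Every candidate carries `review_flag = TRUE`
— a cavity can equally be a myelin fold, and the final call is deliberately
left to proof-reading, represented here by `applyReview` overrides rather
than an interactive step. Myelin is then redefined as `V1` minus all
mitochondria. A segment is a vacuole iff it is small (< 2×10⁴ voxels) and
very bright (mean ≥ 0.85). Remaining segments are axon candidates: the
supervoxels sharing a face (6-connectivity) with the segment form its
enclosing shell, and a shell myelin fraction ≥ 0.7 (inclusive) makes the
axon myelinated; calls within ±0.05 of the threshold, and axons with an
empty shell (volume-border contact), are review-flagged. Unassigned voxels
— the regions that exceeded $\vartheta$ — become cells by 26-connected
components; components below the small-volume threshold stay unlabelled
rather than becoming spurious cells.

# Morphometry: eikonal skeletons and perpendicular cross-sections

The centreline of one axon (its intra-axonal space, mitochondria included,
vacuoles excluded, internal holes filled) is the minimum-cost path between
the two axon tips through the deepest interior point:

* $T_1$: arrival time from the axon surface at unit speed (the
  anisotropy-aware distance-to-surface map); its argmax $x^*$ is the
  deepest interior point. Surface voxels are mask voxels 6-adjacent to a
  non-mask voxel *inside* the array — faces cut by the volume border do not
  count, so tubes running through the stack keep open ends.
* $F_2 = (T_1 / T_1(x^*))^2$, clamped below at $10^{-3}$: a speed near 1
  mid-axon and near 0 at the surface, so fronts and minimum-cost paths hug
  the middle.
* $T_2$ from $x^*$ at speed $F_2$; its argmax is the first endpoint, and
  $T_3$ from there gives the second.
* The path is traced from each endpoint by 4th-order Runge–Kutta descent of
  $-\nabla T_2 / |\nabla T_2|$ at 25 nm steps (gradients trilinearly
  interpolated from central differences), joined at $x^*$, and trimmed by
  1 µm of arc length at both ends — the endpoints lie at the axon surface
  and the first micrometre is the approach to the interior.

Two numerical choices here. The endpoint argmax runs over the *core*
(voxels at least half the maximal interior depth): with a near-zero surface
speed the costliest arrivals overall are the shallow voxels anywhere on the
boundary — on supervoxel-blocky masks every pocket is an arrival-time spike
— whereas among core voxels the surface-push cost is bounded and the
along-tube travel dominates, so the axial tips win robustly. Because a core
endpoint already sits $T_1(e)$ inside the surface, the end trimming removes
$1\,\mu m - T_1(e)$ of arc at that end: the same physical micrometre of
axon tip is dropped either way. And backtracking stops within half a
(coarsest) voxel of $x^*$, with a stall guard that snaps the last couple of
voxels when the interpolated gradient degenerates to plateau noise near the
global minimum.

The eikonal solver itself (`solveEikonal`) is a fast-marching scheme on the
anisotropic grid. The default "msfm" mode combines the axis stencil with the
plane-diagonal stencils that are orthogonal in physical coordinates given
the spacing, evaluates each with second-order one-sided differences where
two upwind values exist, and takes the minimum over stencils. Each
first-order difference is paired with the trapezoidal slowness of its edge
and each second-order difference with the slowness at the target — the
pairing that keeps variable-speed profiles free of first-order quadrature
drift. Point sources are initialized exactly in a small ball (five in-plane
voxels) to remove the source-singularity error, which otherwise advects
along characteristics. On a 50³ free-space benchmark the scheme stays
within ~1.4% of Euclidean distance at radii ≥ 10 voxels (first-order:
~12%), and within ~3% of a refined-graph Dijkstra oracle under smooth
variable speed. The oracle itself deserves a note: a 26-connected graph
metric overestimates Euclidean lengths by up to ~13% regardless of
refinement, so the test oracle uses a 4×-refined grid with moves up to
three voxels per axis (primitive offsets), bounding its own metrication
error below 1%.

Cross-sections are sampled at every skeleton point on an 8 µm × 8 µm frame
at 50 nm spacing, oriented by the local tangent (central differences over a
±5-point window; single 25 nm steps are too noisy). The binary axon mask is
interpolated trilinearly, thresholded at 0.5, and only the connected
component at the frame centre is kept. The in-plane frame axes come from a
deterministic Householder-style construction — the moments are rotation
invariant, so any fixed basis is valid and determinism aids testing. Each
section is measured through its normalized second central moments: the
moment-matched ellipse gives minor/major axes (4·√eigenvalue) and
eccentricity, and the equivalent diameter is that of the circle with the
section's area. Pixel moments include the per-axis cell-variance term
(cell²/12), so rasterized shapes converge to their continuous moments. The
per-axon summary is the median of each measure along the skeleton
(cross-section distributions are multimodal, so medians are preferred to
means), and axons shorter than 5 µm are excluded from group statistics —
a threshold meant as roughly one third of the stack depth at the target
acquisition geometry.

# Evaluation and statistics

`precisionRecall` and `weightedRegionOverlap` quantify a segmentation
against reference annotations: tissue-level precision/recall per class, and
region-level weighted Jaccard/Dice where *each axon is its own region*.
Regions are matched one-to-one by maximizing total Dice (an O(n³) Hungarian
assignment; unequal counts padded with zero-Dice dummies), and the weighted
means use reference-size weights, unmatched reference regions contributing
zero. Region-level matching makes these metrics deliberately harsh on
split-and-merge errors. Evaluation can run on full volumes or selected z
slices (manual annotations are typically sparse), and the report records
which.

`nestedAnova` implements the hierarchical design: group (fixed) over
animals (random, nested) over per-axon medians. Sums of squares come from
sequential model comparison — equivalent to type-II for a fully nested
design — and the group F statistic uses the animal-within-group mean square
as its denominator, the expected-mean-squares construction for a random
nested factor. `varianceComponents` partitions cross-section-level variance
into cross-sectional, axonal and animal levels by method-of-moments on the
unbalanced nested EMS equations; negative moment estimates are truncated at
zero (raw values retained) before converting to percent. Because the full
design matrix at study scale is enormous, components are estimated on
random 10⁴-measurement subsamples, ten times, and reported as mean ± SD.
`volumetrics` reports Myelin* (myelin volume over myelin plus myelinated
intra-axonal volume), the thickness-free aggregate g-ratio √(1 − Myelin*),
and densities of myelinated axons and mitochondria per µm³ of non-cellular
volume, each object counted once.

# The phantom generator

`generatePhantom` builds SBEM-like volumes with ground truth so every stage
is testable without microscope data. The default spec is a 2.7 × 2.7 × 6 µm
volume at 15 × 15 × 50 nm voxels: four myelinated axons (lumen radii
200–340 nm, sinusoidally varying along the axis, laterally wiggling
centrelines) whose 170–210 nm sheaths touch so myelin forms one connected
structure; two unmyelinated axons; two intra-axonal mitochondria; two
~0.55 µm vacuoles; and a cell-body blob large enough to exceed the scaled
volume cap. Class intensity means follow the contrast ordering of the real
data (myelin 0.20 ≈ mitochondria 0.22 < axoplasm 0.60 < vacuole 0.92, cell
0.45, background 0.75), thin dark membranes (0.35, 35 nm) wrap unmyelinated
axons, vacuoles and the cell — without membranes no edge contour forms
around low-contrast structures and they would never be seeded, which does
not match real tissue, where membranes are the most visible boundaries.
Noise is additive Gaussian (default σ = 0.08) clipped to [0, 1], generated
from a fixed seed.

What the phantom does *not* emulate: detector physics and correlated noise,
the point-spread blur of real block-face imaging (boundaries here are hard
steps), myelin delamination and pockets, branching axons, and densely
packed neighbouring axons filling all extracellular space. Passing tests on
phantoms therefore demonstrates the machinery — growing, refinement, rules,
skeletons, measures, statistics — under controlled geometry with known
truth, not segmentation accuracy on real tissue.

The sheath thicknesses sit at the chunky end of realistic (per-axon
g-ratios 0.60–0.68 against an aggregate ~0.7): at 15 nm pixels a sheath
must be a dozen pixels thick for any edge-bounded method to retain a
sensible interior once a ~2-pixel barrier band is carved from each side, and
merged adjacent sheaths in real SBEM data are of exactly this scale.

# Problem sizes and determinism

The test suite and the acceptance script size their simulations for a
single-CPU run: eikonal benchmarks at 50³/20³, skeleton fixtures of one to
two million voxels, the full phantom at 3.9 M voxels, variance-component
recovery at 5 animals × 250 axons × 250 cross-sections with 10⁴-row
subsamples, and 500 null simulations for the type-I error check. Every
random draw (myelin seed, phantom noise, subsampling, slice selection) goes
through an explicitly passed seed; reruns are bit-identical.

# Known limitations

* The serial growing order and the single myelin seed make the output
  depend on the seed in principle; on well-separated phantoms the result is
  seed-invariant, but on ambiguous data it need not be.
* Supervoxel claiming resolves competition by creation order, not by
  overlap magnitude; a supervoxel 0.85-covered by a later segment can be
  claimed by an earlier one at 0.80.
* The skeletonizer assumes an unbranched tube with exactly two tips;
  branching inputs fail with diagnostics rather than splitting.
* Mitochondria detection is a geometric cavity rule; at this resolution a
  myelin fold is indistinguishable from a mitochondrion, hence the
  mandatory review flags.
* HDF5 containers are not read or written; volumes travel as multi-page
  TIFF, tables as CSV.
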