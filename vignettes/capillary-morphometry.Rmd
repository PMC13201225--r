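---
title: "Quantitative 3D morphometry of capillary ultrastructure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative 3D morphometry of capillary ultrastructure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmorph3d)
```

## The problem

Brain capillaries are built from two cell types — endothelial cells (ECs)
that line the lumen and pericytes (PCs) that wrap them from outside — both
ensheathed in a basement membrane (BM). Serial-section scanning EM resolves
their ultrastructure at nanometre scale: peg-and-socket junctions in which
one cell pushes a cytoplasmic finger into a pocket of the other, thin BM
sheets whose thickness varies across the surface, bright electron-lucent
pockets (ELPs) within the BM and at the EC–PC interface, and an ER network
that approaches the pericyte plasma membrane. `vesselmorph3d` turns a dense
voxel annotation of a capillary segment (a 26-class integer label volume at
anisotropic voxel pitch, by default 8 × 8 × 33 nm) into these measurements,
and ships a synthetic phantom generator with exact ground truth so every
stage can be validated end to end.

All geometry is computed under the physical anisotropy of the grid. The
central primitive is an exact Euclidean distance transform that weights
each axis by its pitch (`anisotropicEDT`, a separable parabolic-envelope
algorithm, not a chamfer approximation): a one-voxel step along z is
exactly 33 nm. Exactness is tested against an all-pairs brute-force oracle.

## From semantic prediction to final labels

A raw 7-class semantic segmentation (background/cytosol, BM, lumen, nuclei,
ER, mitochondria, undetermined) is post-processed in four stages:

1. **Exterior removal** (`removeExterior`). Per slice, everything 4-connected
   to the image border outside the outer BM ring becomes background. Slices
   whose ring is open are repaired by morphological closing with a radius of
   at most 3 px; anything unrepairable is reported, never guessed.
2. **Cytosol filling** (`fillCytosol`). Interior voxels carrying no other
   prediction are cytosol.
3. **Cell typing** (`assignCellTypes`). Per slice, an 8-connected cytosol
   region touching the lumen is EC, otherwise PC; a 3D pass then relabels
   each 26-connected component by its across-slice majority, which recovers
   peg cross-sections that are detached from the lumen in individual
   sections. Organelles inherit the cell type of the cytosol around them.
4. **Junction and peg relabeling** (`relabelJunctionsAndPegs`). BM bridged
   by a per-slice morphological closing of the EC mask (radius 3 px) lies
   between EC on both sides and becomes the EC–EC junction class; this
   covers junctions of an EC with neighbours and with itself. Pegs are
   found by protrusion analysis: the residue of a per-slice opening
   (radius 6 px, slightly above the expected peg radius) of each cell's
   mass (cytosol plus organelles), restricted to voxels deeper than 2.5 px
   from the opened core. A residue component is a peg when it is solid (it
   contains a disk of inscribed radius ≥ 2.5 px), is mostly detached from
   its own cell (≤ 25% of its voxels touch own-cell mass), and lies within
   2.5 in-plane pitches of the other cell — or, for EC components adjacent
   to the junction class, of EC again across the junction (an EC–EC peg).
   ER and mitochondria enclosed in a peg move to the peg-organelle classes
   and count towards its volume.

The depth, solidity and detachment thresholds were chosen so that opening
residue produced by curved boundaries, the junction slit, socket margins
and organelle-pinched cytosol is rejected while embedded shafts are kept;
they are exposed as arguments. Peg metrics follow fixed definitions: volume
is voxel count × voxel volume; z length is slice span × 33 nm; the maximal
x–y diameter is the largest per-slice Feret diameter plus one in-plane
pitch, so a single-voxel footprint reads one pitch rather than zero and the
aspect ratio (z length / diameter) is always defined.

## Surface measurements

**Pericyte coverage** (`pcCoverage`) traces the outer boundary contour of
a smoothed EC mask (PC pegs filled in, EC pegs removed; junction voxels
filled too, since an open slit would add spurious uncovered perimeter).
Junction seams and socket wedges that still interrupt the shell are
bridged by a per-slice closing (18 px by default) before tracing, and any
contour pixel that touches the lumen is excluded as luminal. A boundary
pixel is covered when the nearest PC voxel in its slice lies within the
coverage radius: the slice's estimated EC–PC interface BM thickness
(twice the 0.95 quantile of the cell-distance field over interface BM
pixels) plus 1.25 px. Two digital-geometry corrections matter at desk
scale: each covered run is trimmed by the geometric edge overshoot
`sqrt(r² − d₀²)` at both ends, and the percentage is computed over arc
length rather than pixel count (digital contours carry more pixels per
radian on diagonal stretches). With these choices the planted arc
fraction of phantoms is recovered to within about one percentage point
from 20% to 100% coverage; the radius remains configurable because the criterion
on real data is a judgement call.

**BM thickness** (`bmThicknessSurface`) samples the anisotropic distance
from the cell mask at outer-perimeter BM voxels (BM or BM-ELP voxels
6-adjacent to background). **Surface domains** (`partitionSurface`) assign
each outer-surface voxel to the nearest of PC soma, PC process, or EC
(non-covered), with ties broken soma > process > non-covered. On phantoms
the soma mask is ground truth; on real data it defaults to PC voxels within
1 µm of the PC nucleus (`somaMaskFromNucleus`) because "soma" has no
operational definition in the annotation. **ELP volume per area**
(`elpVolumePerArea`) assigns each ELP component to the domain nearest its
centroid — pockets at a domain edge could arguably be split, but the
centroid rule is deterministic and total — and divides by the domain's
exposed-face area (each surface voxel contributes the area of its
background-facing faces, the standard voxel surface estimator).

## Peg position and nucleus proximity

The PC edge coordinate system (`buildEdgeCoordinates`) traces each PC
section's boundary, keeps the lumen-facing part (pixels nearer the lumen
than the exterior), and measures arc length along it; a pixel's position is
its distance to the nearer arc endpoint, so the largest available position
is half the arc length. Socket indentations are closed over (radius 7 px)
so the coordinate runs across socket mouths. Arc length is measured on a
moving-average-smoothed polyline (window 5 px) rather than with raw chain
codes: thinning and boundary output is staircase-jagged, and chain-code
weights overestimate such chains by up to ~35% on diagonal stretches,
whereas the smoothed estimator keeps digital-circle perimeters within a few
percent. Each PC-EC peg maps to the nearest lumen-facing boundary pixel in
its centroid slice; observed and available positions share 0.1 µm bins,
are probability-normalized, and are pooled (not averaged per vessel) for
the distribution plots. Peg-to-EC-nucleus proximity
(`pegNucleusProximity`) samples the PC-peg distance field on the nucleus
surface and counts pegs within one in-plane pitch (8 nm) of it — the
operational meaning of "no visible cytoplasm between".

## ER contact and interface lucency

The PC membrane surface is split into lumen-facing, abluminal and socket
categories (`categorizePcSurface`): socket voxels lie within 2 px of an EC
peg, and the remaining voxels are lumen-facing when the lumen is closer
than the exterior (the per-slice medial split of the section). ER contact
(`erContactStats`) is a nearest-PC-ER distance of at most one in-plane
pitch, the same tolerance as nucleus contact, set through one argument.

The EC–PC interface (BM and BM-ELP voxels within 8 px of both cells; the
EC–EC junction class is deliberately not part of it) is thinned per slice
to a one-pixel centerline, branches shorter than 5 px are pruned, and the
chain is ordered and measured (`skeletonizeInterface`). Image intensity is
sampled along it, each centerline voxel is attributed to an EC-peg, PC-peg
or non-peg domain (within 2 px of the respective peg classes), and the ELP
fraction is the percentage of voxels whose intensity strictly exceeds 180
of 255 (`elpFractionByDomain`); a voxel at exactly 180 does not count.

## Profiles and statistics

`axialClassAreas` reports per-slice cross-sectional areas by class group;
summing a group's areas times the section pitch reproduces its volume
exactly, which is tested. `nucleusProfile` centres the per-slice nucleus
area profile on the volume centroid and differentiates it after a
5-slice moving average (raw first differences at 33 nm are too noisy); for
two-lobed nuclei the reported landmark is the minimum of the rate-of-change
curve between the two area maxima, and unimodal profiles report `NA`
rather than a spurious dip. `groupCompare` is a rank-based Kruskal–Wallis
test with tie-corrected Dunn pairwise follow-up and Holm adjustment — the
post-hoc procedure is a documented choice, since per-vessel group
comparisons (n = 3 vessels in the motivating data) come from commercial
software that does not name one. Per-vessel datapoints are means over all
voxels of a surface domain; peg volumes and aspect ratios are pooled across
vessels.

## The phantom generator

`generatePhantom` builds a z-oriented tube: lumen, EC annulus, interface
BM, a PC arc of prescribed angular coverage with a soma bulge (thicker PC,
thinner overlying BM), an outer BM shell with a prescribed thickness field,
and an "S"-shaped EC–EC junction seam (absent in seamless mode). Pegs are
z-elongated cylinders embedded in the recipient cell behind a one-voxel BM
(or junction-class) sheath and connected to the donor by a one-slice neck
carved across the interface — this realizes sockets while keeping the two
cells' cytosol strictly separated by membrane classes everywhere, which the
cell-typing stage depends on and which is tested. EC-EC pegs additionally
turn the wedge between the junction seam and their shaft into junction
material (the recipient's socket); pegs are planted at least two opening
radii apart, clear of the volume's z ends, and EC-EC pegs occupy staggered
z slots on the two seam sides so facing sockets never cut each other's
neck. Defaults (lumen radius
440 nm, EC 120 nm, interface 32 nm, PC 120 nm, BM 100 nm / 50 nm over the
soma, coverage 64%, peg radius 40 nm over nine 33 nm sections, giving an
aspect ratio just under 2) describe a scaled-down capillary whose
cross-sectional proportions and class relationships match the motivating
data; phantom axial extents (20–40 sections, ~0.7–1.3 µm) and in-plane
radii are an order of magnitude below a real 30 µm vessel segment so that
a full analysis runs in seconds. Presets `v1like` (64% coverage, EC-EC
pegs outnumbering EC-PC ~5:1), `v2like` (83%, two-lobed PC nucleus) and
`v3like`/`seamless` (84%, one EC, no junction) carry the per-vessel
structure at proportionally reduced peg counts.

The grayscale rendering draws each class from a normal distribution (BM
90 ± 15) clipped below 179, and ELP voxels from Uniform(200, 240), so the
180 threshold separates them by construction; only the threshold itself is
prescribed by the analysis, the class intensity models are the phantom's
own. The ER is a tubule network of polylines at one-third PC depth rooted
in a radial trunk on the nuclear envelope; with a socket bias `b`, a
socket-hugging tubule is added per EC peg with probability 1 − 1/b, which
creates a known contact enrichment for recovery tests. Identical seeds give
bytewise identical volumes.

What the phantom does **not** emulate: real EM texture, imaging artifacts
or section misalignment, tapering cell terminations (arc ends and the soma
bulge end in voxelized steps wrapped in BM), Golgi and the two
"undetermined" organelle classes, branching vessels, and multiple PC somas.
Passing recovery tests therefore demonstrates the correctness of the
measurement implementations under controlled geometry, not robustness to
annotation errors in real material.

## Numerical choices and degenerate inputs

* Distances are exact; contact tolerances (one in-plane pitch) and peg
  shells (two pitches) are stated in pitch units and scale with spacing.
* 3D connectivity is 26-neighbourhood, per-slice connectivity is
  8-neighbourhood (4-neighbourhood for background/flood questions, the
  standard duality), everywhere.
* Empty source masks make distance fields undefined and raise errors; a
  vessel without PC reports 0% coverage and an all-`non_covered` surface;
  a PC that fully wraps a slice has no edges and is skipped (and counted)
  by the edge coordinate system; pegs with no adjacent arc are excluded
  and reported.
* Single-voxel peg footprints read one pitch of diameter; the aspect ratio
  never divides by zero.
* All randomness is seeded and scoped: generators restore the caller's RNG
  state.

## Limitations

The peg detector is tuned for shaft-like pegs at the 40–80 nm scale of the
default spacing; exotic peg shapes (strongly branched or sheet-like) would
need different solidity criteria. The EC-EC peg criterion (a solid,
detached protrusion adjacent to the junction class) is a best-effort
operationalization — complex junction folds are excluded by the solidity
and detachment filters, but no annotation-free criterion can be perfect,
and components failing it are left as cytosol rather than guessed. ELP
recovery from labels alone is impossible after semantic degradation
(class 17 collapses into BM); `detectELPs` re-detects them from image
intensity using the 180 threshold and a minimum size of 8 voxels, and is
an extension of the original annotation schema.
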