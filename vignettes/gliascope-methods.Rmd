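---
title: "Measuring microglial reactivity: models and methods in gliascope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring microglial reactivity: models and methods in gliascope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliascope)
```

Microglia respond to injury and disease by retracting their branched
processes and adopting a rounded, ameboid shape; the same transition
reorganizes their microtubule array from a non-centrosomal to a radial,
centrosome-anchored configuration, and redirects vesicle traffic. gliascope
turns the bespoke measurements behind these observations into a tested,
reusable package: single-cell segmentation of stained microglia,
morphometric profiling, microtubule plus-tip comet tracking, and radial
intensity statistics, each validated against ground-truthed synthetic data
and independent brute-force oracles.

## Stained-section segmentation

Chromogenic (DAB) staining renders microglia dark on a light background.
Preprocessing converts RGB input to 8-bit grayscale by ITU-R 601 luminance,
inverts it so signal is bright, removes smooth background with a rolling-ball
step (grayscale opening with a disc of radius 50 px; EBImage's grayscale
morphology operates on a [0, 1] scale, so the opening runs on the rescaled
image), and smooths with a Gaussian of sigma 1 px. Color deconvolution is
deliberately not used: the procedure being reproduced converts directly to
grayscale.

Segmentation is two-staged. Somata stain darker than processes, so seed
regions are the 8-connected components of pixels at or above

\[ Th_1 = I_{max} - f_1 \cdot I_{SD} \]

with an area of at least 300 px. Cells are then grown by a seeded watershed:
flooding proceeds from the seeds in order of decreasing intensity, only
pixels at or above

\[ Th_2 = I_{mean} + f_2 \cdot I_{SD} \]

are assignable, and supra-threshold structures not connected to any seed stay
background — this is what excludes orphaned branches of cells whose somata
lie outside the section. Finally, only labels strictly larger than 900 px are
kept. All three statistics ($I_{max}$, $I_{mean}$, $I_{SD}$) are computed on
the preprocessed image of the analyzed field; whether the original procedure
computed them per ROI or per image is not documented, and per-input-image is
the assumption here.

Parameter defaults: $f_1 = 2$ and $f_2 = 0.5$ (both dimensionless, exposed in
the configuration because they are tuned per staining batch in practice);
seed area floor 300 px; cell area floor 900 px; rolling-ball radius 50 px;
smoothing sigma 1 px. The "area maxima" seed detector is interpreted as
supra-$Th_1$ components with an area floor — the plateau-maximum behavior of
the original plugin is not documented beyond its threshold formula, and this
interpretation is the verifiable one.

Numerical determinism: flooding ties (equal intensities) are broken
first-in-first-out by insertion order, so a fixed input always yields the
same label map, and on images with distinct intensities the flood is provably
identical to the textbook formulation "repeatedly assign the globally
highest-intensity unlabeled pixel above $Th_2$ adjacent to a labeled pixel"
— which is exactly how the test oracle recomputes it. Degenerate inputs: a
constant image has no structure ($Th_1$ would equal every pixel) and returns
an empty seed map; a seed sitting below $Th_2$ keeps its seed pixels but
cannot grow.

## Culture segmentation

Fluorescent (CellMask) images of cultured microglia are bright-on-dark and
lack the strong soma/process contrast of DAB, so seeding uses intensity
topology instead: every regional maximum whose *dynamics* — the minimal
intensity drop separating it from a higher maximum — reaches h becomes one
seed. The default h of 10 000 follows the original fixed setting and is
interpreted on the native 16-bit scale; the bit depth was not documented, so
the value is configurable and should be rescaled (h ≈ 39 per 8-bit gray
level) for 8-bit data. Dynamics are computed by a union-find sweep over
pixels in decreasing intensity order, with merges at equal peak values
resolved toward the earlier-created component; the seed is the plateau of the
surviving maximum (growing the seed to the full h-domain changes nothing,
because the watershed claims that domain first anyway). The watershed floor
is 10× the per-image minimum intensity, the area floor 200 px, and "object
splitting off" is read literally: one region per surviving seed, no post-hoc
shape-based splitting.

Per-well aggregation pools all cells from all fields of view of a well (5–9
technical replicates per well in the reference assay design), averages them, and
divides by the mean over the wells of the untreated reference group. Wells
without cells are flagged and excluded from group means.

## Morphometrics

All descriptors are computed on the binary mask of each label, in pixels and
(via the calibration, default 0.46 µm/px for sections) in micrometers:

- **Perimeter** uses the 4-direction Crofton formula (intercept counts along
  rows, columns and both diagonals, spacing 1 and $1/\sqrt2$). This is the
  estimator used by the morphometry library the original measurements relied
  on, and it is accurate to ~0.5% on a rasterized disc, where pixel-edge
  counting would be ~27% high. A digitized disc of radius 50 px measures
  circularity 0.992.
- **Circularity** is $4\pi A/P^2$, clipped to 1 so the ramification index
  $RI = 1 - $ circularity stays in $[0, 1)$. Holes are filled before the
  perimeter is measured (staining gaps should not inflate it); the flag is
  exposed.
- **Inscribed radius** is the maximum of the Euclidean distance transform —
  exact for "radius of the largest disc fitted into the shape".
- **Feret diameter** is the maximum pairwise distance between convex-hull
  vertices of the pixel *corner* points, so a 10×20 px rectangle measures
  $\sqrt{10^2+20^2} = 22.36$ px rather than the center-to-center 21.0.
- **Geodesic diameter** is the longest shortest path between mask pixels with
  step weights 1 and $\sqrt2$, computed by iterated farthest-point Dijkstra
  propagation started from the distance-transform maximum and the four
  bounding-box extremities, iterating until the diameter stops growing. On
  every random mask tested it equals the all-pairs shortest-path value to
  machine precision. Note that the 8-connected chamfer metric exceeds
  Euclidean distance by up to ~8% at intermediate angles — a digitized disc
  of radius 20 has geodesic diameter 42.97, not 40 — which is inherent to the
  definition, not an implementation artifact.

Group summaries are hierarchical: cells are averaged per section, then
section means per animal, so unbalanced cell counts between sections do not
weight the animal mean. Cell density is the label count divided by the
analyzed area in mm².

Resolution caveat: intercept-based perimeters (like any digital boundary
estimator) are estimator-limited on 1-px-thin structures, so circularity is
scale-stable for resolved shapes (re-rasterized at 2× resolution, a disc's
circularity changes < 2%) but blocky pixel replication of a thin-branched
mask adds genuine staircase boundary.

## Comet tracking

Growing microtubule plus-ends appear as moving fluorescent comets. Detection
filters each frame with a zero-mean Laplacian-of-Gaussian kernel at sigma =
radius$/\sqrt2$ (default radius 0.4 µm), keeps 8-neighborhood local maxima
above the detection threshold, and refines positions with a quadratic fit
followed by two iterations of a Gaussian-weighted centroid of the positive
response — on synthetic single comets at SNR 5 this localizes to ~0.25 px
RMSE (0.018 px without noise). The kernel is amplitude-calibrated: a matched
Gaussian spot of peak amplitude A gives a response of A, so thresholds are in
gray units of spot amplitude and are tuned per movie to the expression level,
as in the reference workflow.

Linking is the LAP design without merging or splitting: per consecutive frame
pair, a one-to-one assignment minimizing total distance among pairs within
1.5 µm (maximum-cardinality bipartite matching with a non-link option, solved
by the Jonker–Volgenant algorithm on a padded square cost matrix of squared
distances); then gap closing joins track ends to later track starts within
0.5 µm and at most 4 frames, greedily by ascending distance. Tracks are kept
with ≥ 4 spots and confinement ratio (net displacement / path length, the
tracker-standard meaning, as the original does not state a formula) ≥ 0.8,
which excludes stationary autofluorescent puncta and crossing-corrupted
zigzags alike.

Direction uses the manually supplied centrosome position: a track is outward
iff its last spot is strictly farther than its first ($d_n > d_0$); an exact
tie counts as inward. Speed is path length divided by elapsed time between
first and last spot (per-track mean step speed; at SNR 5 the localization
jitter inflates path length, giving a ~5–8% upward speed bias on 0.09 px
steps — an inherent property of path-length speeds at this SNR, quantified by
the recovery tests). Both net displacement and path length are reported,
since "displacement" is ambiguous in the reference readouts. An optional
helper estimates the centrosome as the intensity-weighted densest bin of
track origins; it is an extension, clearly flagged, not part of the
reproduced procedure.

## Radial intensity statistics

The centrosome enrichment ratio divides the mean intensity of a 20×20 px ROI
on the centrosome by the mean of three equally sized cytoplasmic ROI means.
The dispersion readout builds a radial profile of integrated density in 1-px
half-open rings $[r, r+1)$ around the MTOC (each pixel assigned by its
center-to-center distance; ring densities sum exactly to the profiled
intensity) and reports the radius at which the cumulative fraction reaches
80%, linearly interpolated inside the crossing ring to remove 1-px
quantization. For an isotropic Gaussian of width sigma the analytic value is
$\sigma\sqrt{2\ln 5} = 1.794\,\sigma$; the measured value on a sigma = 10 px
field is 18.06 px. Whether the original profile was restricted to a cell mask
is not stated; a mask argument is optional and off by default, as is constant
background subtraction (diffuse background inflates r80).

## Synthetic data: what it emulates, and what it does not

No raw microscopy data accompany the reference workflow, so every claim the
tests make is about performance on phantoms built to match the stated imaging
conditions:

- **Section phantoms**: 12 cells on a 512×512 field at 0.46 µm/px; somata of
  radius 13 ± 0.8 px (truncated at 2.5 sd — the fixed 300/900 px thresholds
  of the reproduced procedure encode a cell-size regime, and the generator
  stays inside it), 5–7 branches per cell drawn as bounded-turning random
  walks of 40–70 px at 4 px width; gray levels 100/150/220
  (soma/branch/background, dark-on-light), additive Gaussian noise of sd 6 —
  5% of the 120-gray soma contrast. Somata are placed on a jittered grid
  (plain rejection sampling jams at this density) and branches truncate
  rather than touch a neighbor, so each cell is one 8-connected ground-truth
  label. Ameboid phantoms enlarge the soma (18 ± 2 px) and nearly remove
  branches, mirroring reactive de-ramification.
- **Comet movies**: 0.11 µm/px (typical 100× confocal; the original pixel
  size is not stated), 1 frame/s, Gaussian comets of sigma 2.6 px — matching
  the 0.4 µm detection radius — at amplitude 100 over background 10 with
  noise sd 20 (SNR 5, the lower edge of usable plus-tip data), speeds drawn
  from 0.1 ± 0.02 µm/s, lifetimes 20–50 frames, and headings fixed at
  nucleation (comets run along straight microtubules; they do not re-aim at
  the centrosome every step). Outward comets start near the centrosome,
  inward ones at larger radius, so the distance to the centrosome is monotone
  along every true track.
- **Radial fields**: isotropic Gaussians plus optional noise.

Phantoms deliberately omit: uneven illumination and stain gradients beyond
what the rolling ball removes, overlapping cells in z, out-of-focus light,
Poisson (signal-dependent) noise, comet shape anisotropy, and track
merging/splitting. Passing tests therefore demonstrate correctness of the
algorithms under the stated statistical structure, not robustness to every
artifact of real slides or movies.

## Validation design and problem sizes

The test suite validates each core algorithm against an independent oracle
implemented along a different route: the watershed against a repeated
global-argmax flood (200 random images up to 64×64, up to 4 seeds, exact
label-map identity), h-maxima seeding against a level-set recomputation of
dynamics (100 random images up to 32×32), the geodesic diameter against
all-pairs shortest paths on the pixel graph (igraph; masks up to 600 px), and
LAP linking against exhaustive enumeration of matchings (100 instances, up to
6 spots per frame). Recovery tests run five section phantoms at the default
conditions (count error and per-cell IoU against ground truth) and nine comet
movies (three replicate movies at outward fractions 0, 0.5 and 1; direction
fraction, speed and track count against ground truth, averaged over the three
replicates of a condition). These sizes keep the full suite around three
minutes while exercising every code path; `scripts/acceptance.R` recomputes
the same quantities from scratch at the same sizes.

## Known limitations

- The seed detector's plateau semantics and the dynamics bit-depth are
  documented interpretations of under-specified plugin settings; both are
  parameterized.
- Perimeter-derived descriptors are estimator-dependent at the few-percent
  level; comparisons should use one estimator consistently.
- Path-length speeds carry an SNR-dependent positive bias (see above);
  net-displacement speeds would be less biased but are not what the emulated
  readout reports.
- The pipeline is 2D; volumetric (two-photon) morphology is out of scope.
- No stain deconvolution, slide tiling, or machine-learning segmentation.
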