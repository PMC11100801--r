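---
title: "Quantifying microglial state, morphology, and phagocytosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial state, morphology, and phagocytosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package measures

Developmental microglia studies quantify a small set of imaging endpoints
over and over: how many microglia are in a field, how mature they look
(TMEM119 intensity within the Iba1 cell mask), how ramified they are
(Sholl profiles), how much lysosomal machinery they carry (CD68 volume
inside the cell), how much synaptic material sits inside those lysosomes
(VGlut2 inside CD68 inside Iba1), how single cells score on RNA-FISH
puncta (cell typing, activity calls, target density), how many synapses a
field contains (VGlut2/PSD95 colocalization), plus qPCR and ELISA
normalizations and animal-level statistics.  In most published work these
steps live inside interactive tools (Ilastik, IMARIS, Fiji, SynBot) whose
parameters are partly unreported.  `microquant` re-implements every one of
these quantification steps as deterministic, scriptable, unit-tested R
functions, and pairs them with a seeded synthetic-microscopy generator
whose ground truth is exact at the voxel level, so that each stage can be
validated by recovery rather than by eye.

The package deliberately does **not** claim numerical equivalence with the
interactive tools it replaces: the trained pixel classifier is replaced by
classical thresholding, surface meshes by voxel masks.  The *contracts*
(binary pixel class → objects → counts; nested channel masking → volumes)
are preserved and tested.

# The measurement model

**Cell masks and volumes.** All images are grids indexed `(channel, z, y,
x)` with physical voxel sizes `(dz, dy, dx)` in micrometres; voxel centres
sit at `(index − 1) × voxel_size`.  A structure's volume is its voxel
count times the voxel volume — no mesh smoothing, so volumes are exactly
recomputable from the masks.  Connected components use 26-connectivity in
3D (8-connectivity in 2D), matching common object-segmentation defaults.

**Thresholding.**  Three rules are provided.  *Otsu* (between-class
variance maximization) is the default for dense channels such as Iba1 and
DAPI, where the stained fraction of voxels is a few percent or more.
*Fixed* applies a user constant.  *Midpoint* — halfway between the median
and the maximum intensity — is the pipeline default for sparse channels
(CD68, VGlut2, FISH puncta).  The reason is statistical: when the
foreground occupies a vanishing fraction of voxels (well below 1%), the
between-class variance of a background split can exceed that of the true
foreground/background split, so global Otsu may cut *inside* the
background noise.  The midpoint rule is deterministic, parameter-free and
lands between the background mode (≈ the median) and the brightest true
signal whenever any foreground is present.  `threshold_channel()` can
also compute any rule *within* a parent mask, mirroring the
masked-channel workflow of surface-rendering tools.

**Phagocytic capacity and engulfment.**  Capacity is
`100 × volume(CD68 ∧ cell) / volume(cell)`; engulfed synaptic volume is
`volume(VGlut2 ∧ CD68 ∧ cell)`, reported raw and normalized to cell
volume (`engulfed_norm`).  Because each inner mask is formed by
conjunction with the outer one, the chain
`engulfed ≤ lysosome ≤ cell` holds for *any* input, which a
1000-case randomized property test asserts.  Per-cell computation runs on
the cell's bounding box padded by 2 µm; a test asserts bbox results equal
whole-field results (conjunction is local, so they must).

**Soma centre.**  The raw centroid of a branched cell can fall outside
the cell.  The soma centre is instead the medoid of the deepest-interior
core: the connected set of voxels whose chamfer distance-to-background is
within 10% of the maximum, containing the deepest voxel.  The chamfer
transform uses 26-neighbour physical-offset weights (two raster passes);
singleton axes contribute no out-of-plane background, so 2D masks are
handled correctly.

**Sholl analysis.**  2D only, on the maximum-intensity projection of the
cell mask, as the assay is defined: Zhang–Suen thinning produces a
1-pixel, topology-preserving skeleton, and for each radius `r` the
intersection count is the number of 8-connected runs of skeleton pixels
in the ring band `[r − w/2, r + w/2)`.  The band thickness `w` equals the
pixel diagonal: an 8-connected path advances the radius by at most
`p·√2` per step, so this is the thinnest band a crossing process cannot
jump over, and a thicker crossing still counts once because its in-band
pixels form one run.  Ring spacing defaults to 1 µm starting one spacing
beyond the estimated soma radius (the assay description states neither,
so these are package defaults, logged per run); rings that exceed the
image border are flagged `clipped`, never silently truncated.
Correctness is pinned two ways: star phantoms with `k` arms must give
exactly `k` at every ring inside the arms for `k = 1..8`, and profiles on
random-walk skeletons must equal a brute-force oracle that bins every
pixel by distance and clusters by union-find.

**Hi/Mid/Lo heterogeneity.**  Marker mean gray values within each cell
mask are normalized to the same cell's Iba1 MGV (division by default;
subtraction exists behind an option — the source assay does not state the
operator).  Cutoffs are derived once on the pooled all-animals
distribution, never per group, to avoid manufacturing group differences.
Two rules: *tertile* (33.3/66.7 percentiles) as the reproducible default,
and *valley* for visibly multimodal data.  The valley rule smooths with a
Sheather–Jones-bandwidth kernel density and merges adjacent maxima unless
a genuine valley lies between them; because sampling noise makes the
valley depth of truly separated (≥ 4 sd) components overlap the depth of
unimodal wiggles, the merge threshold relaxes in steps (75%, 85%, 95% of
the smaller flanking peak) until three modes survive, and data whose
density supports no three modes at any depth is rejected.  The two
deepest surviving antimodes become the cutoffs.  Classification ties inward: a value on
a boundary is Mid.  The joint CD68-Hi/TMEM119-Lo call is labelled
"phagocytic, non-homeostatic", CD68-Lo/TMEM119-Hi "homeostatic".  The
sampling plan — 4 cells per image, 3 images, 12 cells per animal — is
enforced in strict mode and merely warned about in relaxed mode.

**RNA-FISH scoring.**  Nuclei are segmented from DAPI; puncta are
thresholded components inside a size window (default 1–60 voxels,
rejected objects logged) and assigned to the nucleus containing their
centroid; unassigned puncta are tallied, so assigned + unassigned =
detected always.  Cell typing requires a margin of `min_margin` puncta
(default 3; the source's adjusted threshold is unreported) between VGlut1
and Gad2 counts, with ties ambiguous — excluded from type averages but
logged.  The activity call is Fos⁺ iff
`fos_count > 6 × dapi_volume / median_volume`, strictly: exactly 6 puncta
at the median cell size is Fos⁻.  Linear scaling of the threshold with
relative nucleus volume is this package's reading of "adjusted for cell
size"; a fixed density cut is available via the arguments.  Target
density is puncta per µm³ of DAPI volume, averaged over non-ambiguous
cells per animal and type.

**Synapse colocalization.**  Puncta in the pre- and postsynaptic channels
are matched one-to-one — greedily, best pair first (largest voxel overlap
or smallest centroid distance, ties to the lower index) — so one large
punctum can never count several synapses and
`n_colocalized ≤ min(n_pre, n_post)`.  Voxel overlap is the default
criterion; a centroid-distance criterion with radius `r` is available.
Counts are checked against exhaustive brute-force matchers on random
fields.

**Assays and statistics.**  `2^−ΔΔCt` with the reference gene (18S) and
control-group centring; Ct triplicates are averaged after discarding
replicates more than 0.5 cycles from the triplicate median (stated
triplicates, unstated outlier rule — this package's choice, logged).
ELISA: `(pg/mL × 100) / (mg/mL × 1000)` = pg analyte per 100 mg total
protein.  Statistics always run on unweighted animal means (the animal is
the unit of analysis).  `group_compare()` encodes the sex-first contract:
fit the full factorial including sex; if sex shows no main effect at
α = 0.05, refit pooled; report the final ANOVA and Sidak-adjusted
pairwise contrasts of the comparison factor via estimated marginal means.
The ANOVA/emmeans machinery is standard and delegated; only the
aggregation, pooling and nesting contracts are bespoke and tested.

# The synthetic-data generators

The generators are first-class, tested code: they define the study
conditions every recovery test runs under.

* **Microglia volumes** (`generate_microglia_volume`): spherical somas
  (radius 2.5 µm) with persistent-random-walk processes (tube radius
  0.4 µm) on a dark background; lysosomal blobs (radius 0.8 µm) placed
  inside cells to a target volume fraction (default 5%); synaptic puncta
  (radius 0.3 µm) with exactly `round(engulfed_fraction × n)` centroids
  inside lysosomes.  Intensities are piecewise-constant (background 20,
  foreground 150) plus Gaussian noise (sd 10), quantized to integer grey
  levels like camera counts — at this SNR (13 σ contrast) classical
  thresholds succeed deterministically, which is the point: tests measure
  the pipeline's logic, not its noise robustness.  Somas are placed with
  pairwise separation `max(4·r_soma, 2·(r_soma + L_process) + 0.5 µm)` so
  whole cells can never touch (the segmentation module deliberately does
  not split touching cells).  Engulfment fields use the 60×-like voxel
  grid `0.33 × 0.1 × 0.1` µm; counting fields (`config_counting`) the
  20×-like `1 × 0.5 × 0.5` µm with 19 planes.  For a fixed seed the
  engulfed punctum set is *nested* across increasing `engulfed_fraction`
  (candidates are drawn once, then a prefix is used), so true engulfed
  volume is monotone by construction, and each generator call consumes an
  RNG stream derived from `(seed, stage)`, making outputs bit-identical
  per seed and stages independently reproducible.
* **FISH fields** (`generate_fish_field`, `config_fish`): non-touching
  DAPI spheres (radius 3.5 µm, a typical neuronal nucleus, with room for
  the largest drawn puncta counts) on a `0.5 × 0.3 × 0.3` µm grid; per-cell
  counts per channel drawn negative-binomially (`size = fish_dispersion`,
  default 8; `Inf` = Poisson) with type-dependent means — excitatory
  target mean 10 vs inhibitory 5, the two-fold in-vivo condition.  Puncta
  centres are drawn from an eroded nuclear core and spaced so rasterized
  puncta can never be 26-connected; detected counts therefore equal
  placed counts, and the truth records what was actually placed if a
  nucleus saturates.
* **Synapse fields** (`generate_synapse_field`, `config_synapse`):
  planted colocalized pairs overlap by construction (centroid offsets
  below 0.6 punctum radii); all other puncta are isolated by ≥ 3 µm.
* **Sholl star phantoms** (`generate_sholl_phantom`): a filled soma disc
  plus `k` Bresenham-rasterized 1-pixel arms — an analytic oracle, since
  every ring strictly between soma edge and arm tip must cross exactly
  `k` processes.
* **Tables** (`generate_assay_table`, `simulate_group_study`,
  `generate_intensity_mixture`): Ct triplicates with known fold changes;
  animal-level group studies with a 30% between-animal coefficient of
  variation (a typical spread for imaging endpoints, and the noise level
  at which the stated 6-animals-per-group, two-fold-effect design has
  ~90% power); three-component Gaussian intensity mixtures with labels.

**What the generators do not emulate** — and hence what passing tests do
not show about real data: optics (PSF, depth-dependent blur, bleaching),
touching or overlapping cells, irregular nucleus and soma shapes,
autofluorescence and intensity gradients, chromatic shifts between
channels, and segmentation ambiguity in general.  Recovery results
certify the measurement logic downstream of segmentation, and
segmentation only in the easy, well-separated regime.

# Numerical choices and degenerate inputs

Grey levels are integers in `[0, 65535]`, so TIFF round trips are
bit-exact.  Otsu on a constant image is an error, as is an empty mask in
a mean-gray or capacity computation, a zero protein concentration, a
missing voxel size without an override (no silent defaults), an animal
with ≠ 12 cells in strict mode, and a design with a single-level factor.
Cutoff derivation needs ≥ 9 finite values; the valley rule errors when
fewer than two antimodes exist (unimodal data).  Distance ties in
centroid matching break to the lower punctum index; the minimum object
size defaults to a 2 µm-radius sphere at the field's voxel size.

Problem sizes in the tests and acceptance script (10 engulfment fields of
~10 cells; 30 sweep fields of 4 cells; 80 counting fields up to 50 cells;
10 FISH fields of 400 nuclei; 500 null and 200 power simulations) were
chosen as the smallest designs at which the recovery bands are tight, so
the full validation runs comfortably on a laptop core.

# Known limitations

Zhang–Suen thinning is the classical raster algorithm; like all
thinning it can shorten open line ends by a pixel or two, which is why
exactness tests keep a margin at arm tips.  The chamfer distance
transform is a 26-neighbour approximation to Euclidean distance (within
a few percent); it positions soma centres, it is not a measurement
output.  The greedy one-to-one matcher is a maximal, not maximum,
matching — adequate and deterministic for well-separated puncta, and
validated against brute force on the fields it is used for.  The
heterogeneity cutoffs reproduce a *rule*, not the unpublished manual
values of any particular study.  Nothing in this package has been tuned
against, or compared to, Ilastik, IMARIS or SynBot outputs on real
images; such equivalence is explicitly not claimed.
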