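---
title: "Quantifying inflammatory lung disease from micro-CT and H&E sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inflammatory lung disease from micro-CT and H&E sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungquant)
```

## The measurement problem

Inflammatory interstitial lung disease replaces aerated alveolar space
with cells, matrix and edema. On CT this shows up as a rightward shift of
the lung's density histogram: healthy murine lung is dominated by the
partial-volume interface between alveolar air and epithelium, while
infiltrated lung accumulates voxels at soft-tissue density. lungquant
turns that observation into a small number of volumetric outcomes —
weighted mean density, total, aerated and tissue volume — and pairs them
with an automated histomorphometric readout of matched H&E sections so
the imaging biomarker can be validated against tissue ground truth with
rank correlations.

## CT segmentation

The lung is extracted by seeded region growing (`seeded_region_grow()`):
the 6-connected component of voxels within a Hounsfield window, grown
from a seed placed in a bronchus. The defaults, −1000 to −150 HU, admit
alveolar air and the air/epithelium interface spectrum but not
soft-tissue organs, so the grown region stops at the mediastinum and
chest wall. We use face connectivity rather than 18- or 26-connectivity:
corner-connected leaks across one-voxel diagonal contacts are the main
failure mode of wand-style growth, and face connectivity is the
conservative choice. The oracle tests fix this behaviour by comparing
against a brute-force breadth-first flood fill on random grids.

Because consolidated tissue falls outside the window, the grown region
has holes at lesions and speckle where alveolar-wall voxels exceed
−150 HU. `refine_mask()` repairs this with a fixed sequence — dilation
(`grow_r`), erosion (`shrink_r`), 3D hole filling, then morphological
smoothing (closing followed by opening, `smooth_r`) — all with the
face-connected unit ball applied iteratively. The sequence is fixed
because the tools themselves do not commute; the defaults
(`grow_r = shrink_r = smooth_r = 1`, hole filling on) are the mildest
setting that closes single-voxel speckle while leaving the pleural
boundary in place. Hole filling treats any background component that
cannot reach the grid boundary as lung; consequently a cavity is only
recovered if it is genuinely enclosed, which is also why the phantom
keeps its lesions off the conducting-airway wall (see below).

### Airway exclusion

Conducting airways transport air without exchanging gas, so they are
removed before densitometry. `extract_airways()` grows the lumen from a
trachea seed within the lung mask (air ceiling `air_hu_max = -400` HU)
and assigns every lumen voxel an inscribed-sphere diameter from the
exact Euclidean distance transform:

`local_diameter_um = (2 * d - 1) * voxel_edge_um`

where `d` is the distance to the nearest non-air voxel centre, in voxel
units. The −1 makes a single-voxel tube measure exactly one voxel edge
(35 µm at the reference resolution). For the >200 µm size exclusion the
relevant quantity is the branch's calibre, not the distance of a voxel
from the wall, so `exclude_large_airways()` works on the *local
thickness*: each voxel carries the diameter of the largest inscribed
sphere that covers it. On a tube this propagates the centreline diameter
to the entire lumen, so a wide branch is excluded as a unit while a
140 µm bronchiole survives untouched. Discretization makes the measured
diameter of a digitized cylinder up to about one voxel smaller than its
geometric diameter; branches within a voxel edge of the cutoff
(~210 µm at 35 µm voxels) can therefore land on either side, which is
the resolution limit of the measurement, not a tunable.

Left and right lungs normally separate into distinct connected
components once the main airway is gone; `split_left_right()` assigns
components by the side of their centroid relative to the carina's
sagittal plane (the mean left-right coordinate of the airway mask). If
residual air bridges the lungs the function refuses to guess: it either
partitions by a user-supplied sagittal plane or fails explicitly.

## Densitometry

All downstream outcomes derive from a histogram of masked voxel
intensities with 2001 one-HU bins spanning −1000 to 1000 HU
(`build_histogram()`). Values outside the domain are clamped to the edge
bins; non-integer HU rounds to the nearest bin with ties going to even.
The weighted mean density is the count-weighted average of bin centres.

The aerated/tissue threshold is derived from the control cohort
(`derive_threshold()`): control histograms are pooled by summing counts
bin-wise and the pooled weighted mean is rounded to integer HU (ties
away from zero). Pooling voxel counts weights animals by lung size;
averaging per-mouse means instead (`method = "mouse_mean"`) and the
pooled mode (`method = "mode"`, the most abundant density) are available
because the two readings coincide only when the control histograms are
similar in shape. On the reference acquisition this procedure yields
−256 HU, the density of the air/epithelium interface; on other scanners
or phantoms the derived value differs and that is expected — the
procedure, not the constant, is the method.

`partition_volumes()` splits the histogram at the threshold: voxels
strictly below are aerated, voxels at or above are tissue. The
threshold bin represents the interface itself and is assigned to
tissue; the convention is fixed and matters only for the single bin.
Conservation (`aerated + tissue = total`, fractions summing to 1) is
exact by construction and asserted over random histograms in the tests.
Volumes are reported in voxels and in mm³ (`voxels × (edge/1000)³`).

Dose is summarized by the standard CT dose index: `ctdi()` integrates a
measured axial dose profile over ±50 mm by the trapezoid rule and
divides by `N × T`; `ctdi_w()` combines centre and peripheral values
with weights 1/3 and 2/3. No dose-profile model is fitted.

## Histomorphometry

H&E sections are classified pixel-wise into Blue (hematoxylin-stained
nuclei), Pink (eosin-stained cytoplasm, matrix and red cells) and White
(air space) inside a manually outlined lung ROI. `train_classifier()`
fits one Gaussian per category in RGB space from at least 15 manually
selected training pixels per category (a warning is raised at exactly
15), with a ridge of `1e-3` on the covariance diagonal so constant-color
training sets remain invertible. Classification is the posterior argmax
with equal priors by default; exact ties break deterministically in the
order Blue > Pink > White. A box mode (per-channel training ranges with
nearest-mean fallback) is provided for fidelity to range-based
commercial tools, but the Gaussian discriminant is the primary rule and
is what the density-evaluation oracle in the tests checks exactly.

Empty arteries lose their red cells during processing and classify as
White; `reclassify_regions()` applies the manual correction, relabelling
White pixels inside marked vessel regions as Pink and reporting exactly
how many pixels changed. `quantify_areas()` converts label counts to
areas, sums Blue + Pink into tissue area, and normalizes by the total
ROI area; sections below a minimum total lung area are flagged excluded
rather than dropped. The inclusion floor defaults to 15 mm²: the
literal figure of 15 µm² quoted for the reference workflow is below a
single pixel at slide-scanner resolution and is interpretable only as a
typo, but it remains selectable (`min_total_area_um2 = 15`). Per-animal
summaries (`aggregate_animal()`) average absolute areas over the three
sections and recompute fractions from summed areas, since averaging
per-section fractions would weight sections inversely to their size.

## Cohort statistics

Outcomes from small rodent cohorts are rarely normal, so the factorial
analyses run on ranks: `shapiro_wilk_gate()` reports the Shapiro-Wilk
test and recommends rank transformation at p < 0.05, and
`two_way_anova_ranked()` fits `rank(value) ~ genotype * age` with Type
II sums of squares (Type III by flag) plus Tukey HSD contrasts. When
only the genotype effect is present, `bonferroni_timepoint_tests()`
compares genotypes within each timepoint by pooled-variance t tests on
ranks, declaring significance at α/k = 0.05/4 = 0.0125 for the
four-timepoint design (Welch by flag).

One calibration caveat is documented rather than hidden: with five
animals per group, the pooled t statistic on within-timepoint ranks is a
monotone function of the rank sum, whose permutation distribution only
offers levels in steps of 2/252. The achievable level nearest the
0.0125 cut is 4/252 ≈ 0.0159, so the family-wise error of the corrected
procedure sits near 0.06 rather than 0.05 at these sample sizes. The
acceptance check therefore allows three binomial standard errors of
Monte-Carlo slack around 0.05; the inflation is a property of t
references on ranks at n = 5, not of the implementation.

Cross-modality validation uses Spearman's ρ on the raw, untransformed
per-animal values (`spearman_cor()`, left lung only): the Pearson
correlation of tie-averaged ranks, with an exact permutation p-value for
n ≤ 9 and the `t = ρ√((n−2)/(1−ρ²))` approximation above that.
`correlate_ct_histology()` joins the per-animal CT and histology tables
and reports the five standard pairs (total vs total, tissue vs
Blue+Pink, aerated vs White, and the two normalized pairs).

## What the phantoms emulate — and what they do not

`generate_ct_phantom()` builds a body-density block containing two
ellipsoidal lungs, a trachea that bifurcates once into the two lungs
(soft-tissue wall, open distal tips), an alveolar interior drawn
voxel-wise as air (−850 ± 60 HU) or interface tissue (−256 ± 60 HU,
`alveolar_wall_fraction = 0.25`), a one-voxel interface shell standing
in for the pleural partial-volume layer, and ellipsoidal inflammatory
lesions (−50 ± 40 HU) merged until a target fraction of the parenchyma
is covered. All HU are clamped to the physical −1000…1000 range, as a
scanner would. The class means straddle the −256 HU interface value so
threshold derivation, the aerated/tissue split and the airway exclusion
are all exercised with known answers; the wall fraction of 0.25 puts the
lesion-free tissue fraction in the range reported for healthy murine
lung. Every mask the generator paints is returned as ground truth, and
the recorded fractions are exact counts of the painted classes.

Two deliberate identifiability constraints: lesions keep a two-voxel
clearance from the airway wall (a lesion fused to the wall tube is no
longer an enclosed cavity and could not be recovered by hole filling —
in a real scan the analyst would catch this manually), and the
inter-lung gap scales with the grid so radius-1 smoothing cannot fuse
the lungs. The phantom does not emulate scanner physics (noise is
additive Gaussian, no beam hardening or scatter), anatomical airway
trees beyond one bifurcation, lobar anatomy, cardiac or residual
respiratory motion. Passing the recovery tests therefore demonstrates
that the pipeline measures what the generator painted at realistic
contrast and noise — not that it is robust to every artifact of in vivo
acquisition.

`generate_he_phantom()` thresholds a smooth random field at the target
quantile, so the Blue/Pink/White composition is hit exactly before
noise; nuclei come from a finer field inside tissue, and optional
vessel lumens are carved out of tissue, painted white, and flagged in
the truth for reclassification tests. Stain variability across slides
and scanners, chromatic aberration and out-of-focus blur are not
modelled, which is why the package deliberately leaves stain
normalization out of scope.

`generate_cohort()` draws a latent inflammation burden per animal
(genotype excess of 2 within-cell SD by default, optional age trend) and
maps it to CT tissue volume and histology tissue area through monotone
exponential transforms with independent readout noise. The noise is
sized so the cohort-level Pearson correlation of the latents equals
`2·sin(π·ρ_true/6)` — the bivariate-normal value whose Spearman
correlation is `ρ_true` — making the `rho_true` argument directly the
expected Spearman coefficient, including under group structure.

## Numerical choices and degenerate inputs

* Voxel indices are 1-based `(z, y, x)` in R convention; world positions
  are `index × voxel_edge_um`.
* Histogram rounding: nearest integer, ties to even (IEEE); threshold
  rounding: nearest integer, ties away from zero.
* An out-of-window seed yields an empty mask, not an error; an empty
  refined mask warns; an empty ROI or all-zero histogram is an error
  because no downstream quantity is defined.
* Covariance ridge `1e-3` (0–255 intensity scale) is small enough not to
  perturb well-conditioned training sets and large enough to make
  constant-color categories classifiable.
* `derive_threshold` is invariant to histogram order and to splitting an
  animal's histogram into parts with the same bin-wise sum (pooling is a
  sum); both invariances are asserted in the tests.
* Exact Spearman permutation enumerates all n! rank permutations for
  n ≤ 9 (≤ 362 880 rows), beyond which the t approximation is used.

## Problem sizes used by the test suite

The suites run on grids chosen to keep the full pipeline comfortably
inside a routine check while leaving every stage non-trivial: 72×60×72
voxel CT phantoms (about 311k voxels, lungs of ~39k voxels) across
lesion fractions {0, 0.1, 0.2, 0.4} × 3 seeds, 160×160 H&E phantoms
across 20 seeds × noise σ ∈ {0, 4, 8}, 200 replicate cohorts of 43
animals for the correlation calibration, and 1000 null cohorts for the
family-wise error check. Region-growing oracle equivalence is exhaustive
on 200 random 8×8×8 grids.

## Known limitations

* No lobe-level anatomy, vessel segmentation or gating logic; left/right
  is the finest anatomical split.
* DICOM series are not read directly — convert to an HU-valued NIfTI
  first; the rescale arithmetic is available as `apply_hu_rescale()`.
* The histology classifier uses raw RGB only; compartment-specific
  pathology (perivascular vs peribronchiolar) is out of scope.
* Airway diameters are resolution-limited to about one voxel edge, as
  described above.
* The reference threshold of −256 HU is scanner- and cohort-specific;
  cross-study use should re-derive the threshold from local controls,
  which is exactly what `derive_threshold()` automates.
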