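# lungquant

Quantification of interstitial lung disease (ILD) in small-animal chest
micro-CT, with matched automated H&E histomorphometry and the statistics
that validate one against the other.

ILD replaces aerated alveolar space with cells, matrix and edema. In a
chest CT this shifts the lung's Hounsfield-unit (HU) histogram to the
right. lungquant implements the full measurement chain for preclinical
studies (e.g. TNF-transgenic mouse models of rheumatoid-arthritis lung
disease):

* **Segmentation** — seeded region growing in a −1000…−150 HU window
  from a bronchus seed ("magic wand"), morphological refinement
  (grow/shrink/fill-holes/smooth), conducting-airway extraction with
  distance-transform diameter measurement, exclusion of airways wider
  than 200 µm, and left/right separation at the carina.
* **Densitometry** — per-lung histograms over 2001 one-HU bins; weighted
  mean density x̄ = Σwᵢxᵢ / Σwᵢ; an aerated/tissue threshold derived as
  the pooled weighted mean of the control (WT) cohort (−256 HU on the
  reference data); total / aerated / tissue volumes and normalized
  fractions; CTDI dose summaries (CTDI = ∫±50mm D(z)/(N·T) dz,
  CTDIw = ⅓ center + ⅔ peripheral).
* **Histomorphometry** — Bayesian (Gaussian-discriminant) classification
  of H&E RGB pixels inside a lung ROI into Blue (nuclei), Pink
  (cytoplasm/ECM/red cells) and White (air); manual vessel
  reclassification; areas, Blue+Pink tissue area and normalized
  fractions per section and per animal.
* **Cohort statistics** — Shapiro-Wilk normality gate, rank
  transformation, two-way (genotype × age) ANOVA with Tukey HSD,
  Bonferroni-corrected within-timepoint t tests (α = 0.05/4 = 0.0125),
  and Spearman correlations between CT and histology outcomes on raw
  values (left lung).
* **Phantoms** — synthetic CT volumes and H&E slides with exact ground
  truth (lung/airway/lesion masks, class fractions), plus a paired
  cohort generator with a calibrated Spearman correlation, so every
  stage is testable without animal data.

## Worked example

```r
library(lungquant)

# A diseased phantom: 20% of the parenchyma covered by infiltrates
ph  <- generate_ct_phantom(ct_phantom_spec(lesion_fraction = 0.2), rng_seed = 42)
res <- quantify_ct(ph$volume, seed = ph$truth$trachea_seed)

# Threshold derived from a control (lesion-free) animal, then applied
wt  <- generate_ct_phantom(ct_phantom_spec(), rng_seed = 1)
thr <- derive_threshold(list(quantify_ct(wt$volume, wt$truth$trachea_seed)$histograms$whole))
partition_volumes(res$histograms$whole, thr)
#> <volume_outcomes 'whole_lung'> threshold -625 HU
#>   weighted mean density: -491.9 HU
#>   total:       35198 vox      1.51 mm3
#>   aerated:     16520 vox      0.71 mm3  (46.9%)
#>   tissue:      18678 vox      0.80 mm3  (53.1%)
ph$truth$tissue_fraction
#> [1] 0.541
```

The measured tissue fraction (53.1%) recovers the generator's
lesion-plus-wall truth (54.1%) to about one percentage point; the
derived threshold (−625 HU) is the pooled control weighted mean for this
phantom's air/interface contrast — on real scanner data the same
procedure yields the −256 HU interface density.

```r
# Matched histology: classify a synthetic H&E section and quantify areas
he  <- generate_he_phantom(he_phantom_spec(noise_sd = 4), rng_seed = 42)
clf <- train_classifier(sample_training_pixels(he$slide, he$truth$labels, 30,
                                               rng_seed = 43))
quantify_areas(classify_slide(he$slide, he$roi, clf), min_total_area_um2 = 0)
#> <histo_area_outcomes>
#>   Blue        2560.0 um2  (10.0%)
#>   Pink       10240.0 um2  (40.0%)
#>   White      12800.0 um2  (50.0%)
#>   tissue (Blue+Pink)      12800.0 um2  (50.0%)

# Imaging vs histology across a 43-animal cohort
ch <- generate_cohort(rho_true = 0.85, n_total = 43, rng_seed = 42)
s  <- spearman_cor(ch$pairs$ct_value, ch$pairs$histo_value)
#> Spearman rho = 0.886 (p = 3e-15, n = 43)
```

The recovered Blue/Pink/White fractions match the generator's 10/40/50
composition, and the cohort correlation machinery estimates ρ near its
calibrated target.

A thin CLI wrapping the same functions ships in `inst/cli/lungquant`
(subcommands `segment`, `quantify-ct`, `quantify-histo`, `correlate`,
`simulate`, `run`); `run_pipeline()` is the programmatic equivalent and
writes outcome CSVs, masks, label maps and a provenance record.

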