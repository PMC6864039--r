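# multiscaleMRI

Voxel-wise statistical mapping of microscopic and molecular brain-tumor
properties — IDH1 mutation status, MGMT promoter methylation, cellular
necrosis, and microvascular proliferation — from five co-registered MR
contrasts (T1w, post-gadolinium T1w, T2w, T2-FLAIR, ADC). The package is
aimed at methodologists in voxel-level radiogenomics: it implements the full
pipeline from biopsy-labeled voxels to family-wise-error-controlled
whole-brain parametric maps, with every stage exported and tested, and a
seeded synthetic phantom cohort that supplies the voxel-level ground truth
clinical data cannot.

## The method

Biopsy cores, localized in the image space, define spheres of radius
`(3V/4π)^(1/3)` whose voxels inherit the core's four binary pathology
outcomes (untested outcomes are recorded negative — the *triage* rule).
Contrasts are normalized to the mean of an uninvolved white-matter reference
region. The pipeline then runs three stages:

1. **Screening** — an inclusion-weighted maximum-likelihood logit of each
   outcome on the five contrasts (weights are inverse class fractions),
   with Huber–White robust standard errors, a joint 5-df Wald χ² and
   McFadden's pseudo-R².
2. **Classification** — an inverse-distance-weighted k-nearest-neighbor
   classifier in the 5-D contrast space, run leave-one-patient-out. Each
   voxel's class probability is compared with the cohort background
   distribution q by the two-cell Pearson statistic
   `χ² = (p−q)²/q + ((1−p)−(1−q))²/(1−q)` (df = 1), and p-values are
   corrected per patient by Benjamini–Hochberg at α = 0.05. The neighbor
   count k is tuned to maximize sensitivity subject to a mean accuracy
   ≥ 0.95.
3. **Whole-brain maps** — χ² maps over the full brain mask, Gaussianized to
   z-fields, with spatial smoothness estimated from first differences
   (`FWHM = h·sqrt(4 ln2 · var f / var Δf)`), and cluster-level inference
   from Gaussian random field theory (expected Euler characteristic,
   RESEL-based cluster-size tail) controlling FWER at 5%.

## A worked example

```r
library(multiscaleMRI)

cohort <- generateCohort(defaultPhantomSpec(seed = 1))  # 29 patients, 64^3
fmn <- cohortFeatureMatrix(cohort)
loo <- runSubhyp2(fmn$fm, kGrid = c(100L, 200L, 400L, 800L, 1600L, 3000L))
loo$summary
#>   outcome k_opt acc n_sig      sens
#> 1    IDH1   100   1  2166  6.891214
#> 2    MGMT    NA  NA     0  0.000000
#> 3    CNEC   100   1  2542 27.598109
#> 4     MVP  3000   1  2531 27.586207
```

Read: on this synthetic cohort the two rare molecular outcomes behave like
the published clinical pattern — IDH1 reaches perfect accuracy over its
significant voxels with single-digit per-patient sensitivity (only the two
truly positive patients light up), MGMT (one positive patient, undetectable
under leave-one-out) is the no-detection row with zero significant voxels at
every k, and MVP selects the largest k in the grid. Whole-brain maps at
`k_opt` then recover the true tumor volumes of positive patients:

```r
kOpt <- setNames(loo$summary$k_opt, loo$summary$outcome)
maps <- runSubhyp3(fmn$fm, fmn$normalized, kOpt[!is.na(kOpt)],
                   patients = c(19L, 26L),
                   truth = lapply(cohort, `[[`, "truth"))
round(maps$perPatient$dice, 3)
#> [1] 0.999 1.000 ...
```

A Dice overlap of ≈ 1 means the surviving FWER-corrected clusters coincide
with the simulated tumors, while the brains of truly negative patients stay
dark. `vignettes/multiscale-mapping.Rmd` walks through the model, every
tunable parameter, and the design decisions; `inst/scripts/multiscale-map.R`
is a thin command-line front end (`simulate`, `subhyp1`, `subhyp2`,
`subhyp3`, `all`) over the same functions.

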