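Package: multiscaleMRI
Title: Statistical Multiscale Mapping of Microscopic Tumor Properties from Multiparametric MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Voxel-wise prediction of microscopic and molecular tumor properties
    (IDH1 mutation status, MGMT promoter methylation, cellular necrosis,
    microvascular proliferation) from five co-registered MR contrasts (T1w,
    post-contrast T1w, T2w, T2-FLAIR, ADC). Biopsy-core spheres localized in
    the image space label training voxels; an inverse-distance-weighted
    k-nearest-neighbor classifier run in a leave-one-patient-out design yields
    per-voxel class-membership probabilities, which a Pearson chi-square
    transform against cohort background probabilities converts to parametric
    maps. Family-wise error is controlled per patient by Benjamini-Hochberg
    and, for full-brain maps, by Gaussian random field theory cluster
    inference (smoothness/RESEL estimation and expected Euler characteristic).
    Includes inclusion-weighted logistic regression screening with robust
    standard errors, a seeded synthetic phantom cohort generator with voxel
    ground truth, and NIfTI input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
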