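#' @useDynLib multiscaleMRI, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats pchisq pnorm qnorm plogis rnorm runif rbinom rlnorm sd var
#' @importFrom utils read.delim write.table
NULL

#' Names of the five MR contrasts
#'
#' The five co-registered contrasts the model consumes, in canonical order:
#' T1-weighted, post-gadolinium T1-weighted, T2-weighted, T2-FLAIR, and the
#' apparent diffusion coefficient map.
#'
#' @return Character vector of length five.
#' @export
contrastNames <- function() c("T1w", "T1w-post", "T2w", "T2-FLAIR", "ADC")

#' Names of the four microscopic outcome variables
#'
#' IDH1 mutation status, MGMT promoter methylation status, cellular necrosis,
#' and microvascular proliferation.
#'
#' @return Character vector of length four.
#' @export
outcomeNames <- function() c("IDH1", "MGMT", "CNEC", "MVP")

# lower-case column names used in feature matrices, aligned with outcomeNames()
outcomeColumns <- function() c("idh1", "mgmt", "cnec", "mvp")
contrastColumns <- function() c("t1w", "t1wpost", "t2w", "flair", "adc")

#' Spherical region of interest
#'
#' A sphere in world (scanner) coordinates, used both for the white-matter
#' normalization reference and for biopsy-core sampling volumes.
#'
#' @slot center Numeric length-3 world coordinate of the center (mm).
#' @slot radius Positive radius (mm).
#' @export
setClass("SphereROI", representation(center = "numeric", radius = "numeric"))

setValidity("SphereROI", function(object) {
  if (length(object@center) != 3L || !all(is.finite(object@center)))
    return("center must be a finite length-3 coordinate (mm)")
  if (length(object@radius) != 1L || !is.finite(object@radius) || object@radius <= 0)
    return("radius must be a single positive length (mm)")
  TRUE
})

#' Construct a SphereROI
#'
#' @param center Numeric length-3 world coordinate (mm).
#' @param radius Positive radius (mm).
#' @return A [SphereROI-class] object.
#' @examples
#' SphereROI(c(0, 0, 0), 5)
#' @export
SphereROI <- function(center, radius) {
  new("SphereROI", center = as.numeric(center), radius = as.numeric(radius))
}

#' A single MR contrast volume
#'
#' One scalar 3-D field with its voxel geometry.
#'
#' @slot name One of [contrastNames()].
#' @slot data 3-D numeric array.
#' @slot spacing Voxel size triple (mm), strictly positive.
#' @slot origin World coordinate (mm) of the center of voxel (1,1,1).
#' @export
setClass("ContrastVolume",
         representation(name = "character", data = "array",
                        spacing = "numeric", origin = "numeric"))

setValidity("ContrastVolume", function(object) {
  if (!(object@name %in% contrastNames()))
    return(sprintf("unknown contrast name '%s'", object@name))
  if (length(dim(object@data)) != 3L) return("data must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be strictly positive on all three axes")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be a finite length-3 coordinate (mm)")
  TRUE
})

#' Construct a ContrastVolume
#'
#' @param name One of [contrastNames()].
#' @param data 3-D numeric array.
#' @param spacing Voxel size triple (mm).
#' @param origin World coordinate of voxel (1,1,1) center (mm). Defaults to
#'   centering the grid on the world origin.
#' @return A [ContrastVolume-class] object.
#' @export
ContrastVolume <- function(name, data, spacing = c(1, 1, 1), origin = NULL) {
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * spacing
  new("ContrastVolume", name = name, data = data,
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' Co-registered multiparametric volumes for one patient
#'
#' Holds the five contrasts (on one shared grid), the brain mask, and the
#' white-matter reference sphere used for intensity normalization.
#'
#' @slot patientId Integer patient identifier.
#' @slot contrasts Named list of five [ContrastVolume-class] objects
#'   (names = [contrastNames()]), all on an identical grid.
#' @slot brainMask Logical 3-D array on the same grid.
#' @slot wmROI [SphereROI-class] marking uninvolved white matter.
#' @slot normalized Logical flag: have contrasts been divided by their
#'   white-matter means?
#' @export
setClass("PatientVolumeSet",
         representation(patientId = "integer", contrasts = "list",
                        brainMask = "array", wmROI = "SphereROI",
                        normalized = "logical"))

setValidity("PatientVolumeSet", function(object) {
  cn <- contrastNames()
  if (length(object@contrasts) != 5L || !setequal(names(object@contrasts), cn))
    return(sprintf("exactly five contrasts required: %s", paste(cn, collapse = ", ")))
  if (!all(vapply(object@contrasts, is, logical(1), "ContrastVolume")))
    return("contrasts must be ContrastVolume objects")
  ref <- object@contrasts[[cn[1]]]
  for (nm in cn[-1]) {
    cv <- object@contrasts[[nm]]
    if (!identical(dim(cv@data), dim(ref@data)))
      return(sprintf("grid mismatch: %s is %s but %s is %s", nm,
                     paste(dim(cv@data), collapse = "x"), cn[1],
                     paste(dim(ref@data), collapse = "x")))
    if (!isTRUE(all.equal(cv@spacing, ref@spacing)) ||
        !isTRUE(all.equal(cv@origin, ref@origin)))
      return(sprintf("geometry mismatch for contrast %s", nm))
  }
  if (!identical(dim(object@brainMask), dim(ref@data)))
    return("brain mask must share the contrast grid")
  if (!is.logical(object@brainMask)) return("brain mask must be logical")
  mskvals <- ref@data[object@brainMask]
  for (nm in cn) {
    if (any(!is.finite(object@contrasts[[nm]]@data[object@brainMask])))
      return(sprintf("non-finite values inside brain mask for contrast %s", nm))
  }
  TRUE
})

#' Construct a PatientVolumeSet
#'
#' @param patientId Integer patient id.
#' @param contrasts Named list of 3-D arrays or [ContrastVolume-class] objects;
#'   names must be [contrastNames()].
#' @param brainMask Logical 3-D array on the same grid.
#' @param wmROI [SphereROI-class] for the white-matter reference.
#' @param spacing,origin Geometry applied to plain-array contrasts.
#' @param normalized Whether intensities are already on the white-matter scale.
#' @return A [PatientVolumeSet-class] object. The white-matter sphere must
#'   intersect the brain mask.
#' @export
PatientVolumeSet <- function(patientId, contrasts, brainMask, wmROI,
                             spacing = c(1, 1, 1), origin = NULL,
                             normalized = FALSE) {
  contrasts <- contrasts[contrastNames()]
  missing <- contrastNames()[vapply(contrasts, is.null, logical(1))]
  if (length(missing))
    stop("missing contrast ", paste(missing, collapse = ", "))
  contrasts <- lapply(contrastNames(), function(nm) {
    x <- contrasts[[nm]]
    if (is(x, "ContrastVolume")) x else ContrastVolume(nm, x, spacing, origin)
  })
  names(contrasts) <- contrastNames()
  obj <- new("PatientVolumeSet", patientId = as.integer(patientId),
             contrasts = contrasts, brainMask = brainMask, wmROI = wmROI,
             normalized = normalized)
  wm <- sphereMask(wmROI, gridGeometry(obj))
  if (!any(wm & brainMask))
    stop("white-matter ROI does not intersect the brain mask")
  obj
}

#' Biopsy core with pathology outcomes
#'
#' A spherical sampling volume centered at the biopsy needle tip, carrying the
#' four binary pathology outcomes and their provenance. Outcomes a pathologist
#' elected not to test ("triaged") are recorded negative by study convention.
#'
#' @slot patientId Integer patient id.
#' @slot sphere [SphereROI-class]; its radius equals
#'   [radiusFromVolume()] of `coreVolume`.
#' @slot coreVolume Core volume from the pathology report (mm^3).
#' @slot outcomes Named integer vector (0/1) over [outcomeNames()].
#' @slot provenance Named character vector, "tested" or "triaged".
#' @export
setClass("BiopsySample",
         representation(patientId = "integer", sphere = "SphereROI",
                        coreVolume = "numeric", outcomes = "integer",
                        provenance = "character"))

setValidity("BiopsySample", function(object) {
  on <- outcomeNames()
  if (length(object@coreVolume) != 1L || !is.finite(object@coreVolume) ||
      object@coreVolume <= 0)
    return("coreVolume must be a single positive volume (mm^3)")
  if (!isTRUE(all.equal(object@sphere@radius,
                        radiusFromVolume(object@coreVolume), tolerance = 1e-6)))
    return("sphere radius must equal radiusFromVolume(coreVolume)")
  if (!identical(names(object@outcomes), on) ||
      !all(object@outcomes %in% c(0L, 1L)))
    return("outcomes must be a named 0/1 vector over the four outcomes")
  if (!identical(names(object@provenance), on) ||
      !all(object@provenance %in% c("tested", "triaged")))
    return("provenance must be 'tested' or 'triaged' per outcome")
  if (any(object@provenance == "triaged" & object@outcomes == 1L))
    return("a triaged outcome is always negative")
  TRUE
})

#' Construct a BiopsySample
#'
#' @param patientId Integer patient id.
#' @param center Needle-tip world coordinate (mm).
#' @param coreVolume Core volume (mm^3); defines the sphere radius.
#' @param outcomes Named character vector over [outcomeNames()] with values
#'   `"pos"`, `"neg"`, or `"triaged"` (raw pathology-report tokens), passed
#'   through [applyTriageRule()].
#' @return A [BiopsySample-class] object.
#' @export
BiopsySample <- function(patientId, center, coreVolume, outcomes) {
  tri <- applyTriageRule(outcomes)
  new("BiopsySample", patientId = as.integer(patientId),
      sphere = SphereROI(center, radiusFromVolume(coreVolume)),
      coreVolume = as.numeric(coreVolume),
      outcomes = tri$flags, provenance = tri$provenance)
}

#' Cohort-wide background class distribution
#'
#' The voxel-wise expected distribution of one outcome over all biopsy-labeled
#' voxels in the cohort; the expected cell probabilities of the Pearson
#' chi-square transform.
#'
#' @slot outcome One of [outcomeNames()].
#' @slot pPos,pNeg Class probabilities (sum to one).
#' @slot nPos,nNeg Voxel counts the probabilities derive from.
#' @export
setClass("BackgroundDistribution",
         representation(outcome = "character", pPos = "numeric", pNeg = "numeric",
                        nPos = "numeric", nNeg = "numeric"))

setValidity("BackgroundDistribution", function(object) {
  if (object@nPos < 0 || object@nNeg < 0 || object@nPos + object@nNeg <= 0)
    return("voxel counts must be nonnegative with a positive total")
  if (abs(object@pPos + object@pNeg - 1) > 1e-12)
    return("pPos + pNeg must equal 1")
  if (abs(object@pPos - object@nPos / (object@nPos + object@nNeg)) > 1e-12)
    return("pPos must equal nPos/(nPos+nNeg)")
  TRUE
})

#' Construct a BackgroundDistribution from voxel counts
#'
#' @param outcome One of [outcomeNames()].
#' @param nPos,nNeg Positive / negative voxel counts.
#' @return A [BackgroundDistribution-class] object.
#' @examples
#' BackgroundDistribution("MVP", 3122, 143909)
#' @export
BackgroundDistribution <- function(outcome, nPos, nNeg) {
  p <- nPos / (nPos + nNeg)
  new("BackgroundDistribution", outcome = outcome, pPos = p, pNeg = 1 - p,
      nPos = as.numeric(nPos), nNeg = as.numeric(nNeg))
}

#' Inverse-distance-weighted k-nearest-neighbor model
#'
#' Training points live in the 5-D normalized-contrast space; no further
#' feature scaling is applied (the white-matter normalization puts all five
#' contrasts on a common scale).
#'
#' @slot trainPoints Numeric n x 5 matrix of normalized contrasts.
#' @slot trainLabels Integer 0/1 vector aligned with the rows.
#' @slot k Neighbor count, `1 <= k <= n`.
#' @export
setClass("TrainedWKNN",
         representation(trainPoints = "matrix", trainLabels = "integer",
                        k = "integer"))

setValidity("TrainedWKNN", function(object) {
  n <- nrow(object@trainPoints)
  if (n < 1L) return("training set must be non-empty")
  if (length(object@trainLabels) != n) return("labels must align with points")
  if (!all(object@trainLabels %in% c(0L, 1L))) return("labels must be 0/1")
  if (object@k < 1L || object@k > n) return("k must satisfy 1 <= k <= n")
  TRUE
})

#' Construct a TrainedWKNN model
#'
#' @param trainPoints Numeric matrix (rows = training voxels).
#' @param trainLabels 0/1 vector.
#' @param k Neighbor count.
#' @return A [TrainedWKNN-class] object.
#' @export
TrainedWKNN <- function(trainPoints, trainLabels, k) {
  new("TrainedWKNN", trainPoints = as.matrix(trainPoints),
      trainLabels = as.integer(trainLabels), k = as.integer(k))
}

#' Voxel-wise chi-square statistic map
#'
#' Pearson chi-square statistics comparing predicted class probabilities with
#' the cohort background distribution, either over the biopsy voxels of one
#' patient or across the whole brain.
#'
#' @slot outcome One of [outcomeNames()].
#' @slot values Numeric vector (biopsy space) or 3-D array (brain space) of
#'   chi-square values; `NA` outside the brain mask for brain maps.
#' @slot df Degrees of freedom (1 for the two-cell Pearson transform).
#' @slot background The [BackgroundDistribution-class] used as expected.
#' @slot k Neighbor count used in the prediction.
#' @slot space `"biopsy"` or `"brain"`.
#' @export
setClass("ChiSquareMap",
         representation(outcome = "character", values = "ANY", df = "numeric",
                        background = "BackgroundDistribution", k = "integer",
                        space = "character"))

setValidity("ChiSquareMap", function(object) {
  v <- object@values
  if (any(v[is.finite(v)] < 0)) return("chi-square values must be nonnegative")
  if (object@df < 1) return("df must be >= 1")
  if (!object@space %in% c("biopsy", "brain")) return("space must be biopsy/brain")
  TRUE
})

#' Significance decision for a family of voxel tests
#'
#' @slot pValues Per-voxel p-values.
#' @slot reject Logical rejection flags.
#' @slot threshold The realized p-value cutoff (0 when nothing is rejected).
#' @slot correction `"BH"` or `"RFT"`.
#' @slot alpha Nominal level.
#' @export
setClass("SignificanceResult",
         representation(pValues = "numeric", reject = "logical",
                        threshold = "numeric", correction = "character",
                        alpha = "numeric"))

#' Smoothness of a statistical field
#'
#' Per-axis FWHM of the effective spatial autocorrelation kernel, estimated
#' from first spatial differences, with the derived RESEL count.
#'
#' @slot fwhm Per-axis FWHM (mm).
#' @slot resels Mask volume divided by the FWHM product.
#' @slot dlh Determinant-based roughness scalar, `(4 ln 2)^{3/2} / prod(fwhm)`.
#' @slot nMaskVoxels In-mask voxel count.
#' @slot spacing Voxel size (mm).
#' @export
setClass("SmoothnessEstimate",
         representation(fwhm = "numeric", resels = "numeric", dlh = "numeric",
                        nMaskVoxels = "numeric", spacing = "numeric"))

setValidity("SmoothnessEstimate", function(object) {
  if (any(object@fwhm <= 0)) return("fwhm must be positive on each axis")
  if (object@resels <= 0) return("resels must be positive")
  TRUE
})

#' Random-field-theory cluster inference result
#'
#' @slot clusters data.frame with columns `label`, `size` (voxels), `peakZ`,
#'   `peakChi2`, `peakI`, `peakJ`, `peakK`, `p` (cluster-level corrected).
#' @slot fwerThreshold The FWER level applied.
#' @slot survivors Labels of clusters with `p <= fwerThreshold`.
#' @slot labelArray Integer 3-D array of component labels (0 = background).
#' @slot zThreshold Cluster-forming threshold on the z scale.
#' @export
setClass("ClusterTable",
         representation(clusters = "data.frame", fwerThreshold = "numeric",
                        survivors = "integer", labelArray = "array",
                        zThreshold = "numeric"))

setValidity("ClusterTable", function(object) {
  cl <- object@clusters
  if (nrow(cl)) {
    if (any(cl$size < 1)) return("cluster sizes must be >= 1")
    if (any(cl$p <= 0 | cl$p > 1)) return("cluster p-values must lie in (0, 1]")
  }
  if (!all(object@survivors %in% object@clusters$label))
    return("survivors must be a subset of cluster labels")
  TRUE
})

#' Inclusion-weighted logistic regression fit
#'
#' Maximum-likelihood logit of one binary outcome on the five normalized
#' contrasts, with rows weighted by the inverse of their class inclusion
#' probability and Huber-White robust standard errors.
#'
#' @slot outcome Outcome name.
#' @slot coefficients Length-6 vector (intercept + five contrasts).
#' @slot robustSE Length-6 robust standard errors.
#' @slot vcovRobust 6 x 6 sandwich covariance.
#' @slot vcovModel 6 x 6 model-based (inverse information) covariance.
#' @slot loglikFull,loglikNull Weighted Bernoulli log-likelihoods.
#' @slot waldChi2,waldP Joint 5-df Wald test of the contrast coefficients.
#' @slot pseudoR2 McFadden pseudo R-squared, `1 - loglikFull/loglikNull`.
#' @slot nObs Row count.
#' @slot converged Logical; FALSE signals a capped-iteration / separation fit.
#' @export
setClass("LogitFit",
         representation(outcome = "character", coefficients = "numeric",
                        robustSE = "numeric", vcovRobust = "matrix",
                        vcovModel = "matrix", loglikFull = "numeric",
                        loglikNull = "numeric", waldChi2 = "numeric",
                        waldP = "numeric", pseudoR2 = "numeric",
                        nObs = "integer", converged = "logical"))

setValidity("LogitFit", function(object) {
  if (object@loglikFull < object@loglikNull - 1e-6)
    return("full-model log-likelihood cannot fall below the null model's")
  if (object@pseudoR2 < -1e-12 || object@pseudoR2 >= 1)
    return("pseudo R2 must lie in [0, 1)")
  if (object@waldChi2 < 0) return("Wald statistic must be nonnegative")
  if (any(object@robustSE < 0)) return("robust SEs must be nonnegative")
  TRUE
})

#' Phantom cohort specification
#'
#' Parameters of the seeded synthetic cohort generator. Defaults
#' ([defaultPhantomSpec()]) emulate the 29-patient study population: see the
#' methods vignette for the provenance of each value.
#'
#' @slot nPatients Number of patients.
#' @slot dim Grid dimensions (voxels).
#' @slot spacing Voxel size (mm).
#' @slot noiseSD Per-contrast noise standard deviation after smoothing, on the
#'   white-matter-normalized scale.
#' @slot smoothingFWHM Spatial FWHM of the noise autocorrelation (mm).
#' @slot brainRadius Brain-mask sphere radius (mm).
#' @slot wmCenter,wmRadius White-matter reference sphere (mm).
#' @slot tumorCenterBase,tumorCenterJitter Tumor center distribution: base
#'   location plus a uniform jitter radius (mm).
#' @slot tumorRadiusRange Uniform range of tumor radii (mm).
#' @slot signature 4 x 5 matrix of per-outcome contrast offsets
#'   (rows = [outcomeNames()], columns = [contrastNames()]).
#' @slot prevalence Named true-positive probability per outcome; positive
#'   counts are fixed at `round(prevalence * nPatients)`.
#' @slot triageRate Named marginal probability the outcome goes untested
#'   (always on a true-negative patient) per outcome.
#' @slot volumeFactor Named multiplier shrinking the sampled core volumes of
#'   patients positive on the outcome (the clinical cohort's positive
#'   specimens were much smaller than its negative ones).
#' @slot coresPerPatientMean,coresPerPatientSD Clipped-normal core count.
#' @slot coreVolumeMeanLog,coreVolumeSDLog Log-normal core volume (mm^3).
#' @slot seed Integer root seed; a fixed seed yields an identical cohort.
#' @export
setClass("PhantomSpec",
         representation(nPatients = "integer", dim = "integer",
                        spacing = "numeric", noiseSD = "numeric",
                        smoothingFWHM = "numeric", brainRadius = "numeric",
                        wmCenter = "numeric", wmRadius = "numeric",
                        tumorCenterBase = "numeric", tumorCenterJitter = "numeric",
                        tumorRadiusRange = "numeric", signature = "matrix",
                        prevalence = "numeric", triageRate = "numeric",
                        volumeFactor = "numeric",
                        coresPerPatientMean = "numeric", coresPerPatientSD = "numeric",
                        coreVolumeMeanLog = "numeric", coreVolumeSDLog = "numeric",
                        seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (object@nPatients < 1) return("nPatients must be >= 1")
  if (length(object@dim) != 3L || any(object@dim < 8L))
    return("grid must be 3-D with at least 8 voxels per axis")
  if (any(object@spacing <= 0)) return("spacing must be positive")
  if (object@noiseSD <= 0) return("noiseSD must be positive")
  if (object@smoothingFWHM < 0) return("smoothingFWHM must be nonnegative")
  on <- outcomeNames()
  if (!identical(names(object@prevalence), on) ||
      any(object@prevalence < 0 | object@prevalence > 1))
    return("prevalence must be named probabilities over the four outcomes")
  if (!identical(names(object@triageRate), on) ||
      any(object@triageRate < 0 | object@triageRate > 1))
    return("triageRate must be named probabilities over the four outcomes")
  if (!identical(names(object@volumeFactor), on) ||
      any(object@volumeFactor <= 0 | object@volumeFactor > 1))
    return("volumeFactor must be named multipliers in (0, 1] over the outcomes")
  if (!identical(dim(object@signature), c(4L, 5L)))
    return("signature must be a 4 x 5 matrix (outcomes x contrasts)")
  if (max(object@tumorRadiusRange) + object@tumorCenterJitter +
      sqrt(sum(object@tumorCenterBase^2)) > object@brainRadius)
    return("tumor cannot extend beyond the brain mask")
  TRUE
})
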