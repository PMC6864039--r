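#' @describeIn SphereROI-class Compact display.
#' @param object Object to display.
#' @export
setMethod("show", "SphereROI", function(object) {
  cat(sprintf("SphereROI: center (%.2f, %.2f, %.2f) mm, radius %.2f mm\n",
              object@center[1], object@center[2], object@center[3],
              object@radius))
})

#' @describeIn PatientVolumeSet-class Compact display.
#' @param object Object to display.
#' @export
setMethod("show", "PatientVolumeSet", function(object) {
  geom <- gridGeometry(object)
  cat(sprintf("PatientVolumeSet: patient %d, grid %s at %s mm, %s\n",
              object@patientId, paste(geom$dim, collapse = "x"),
              paste(format(geom$spacing), collapse = "x"),
              if (object@normalized) "WM-normalized" else "raw intensities"))
  cat("  contrasts:", paste(names(object@contrasts), collapse = ", "), "\n")
  cat(sprintf("  brain mask: %d voxels\n", sum(object@brainMask)))
})

#' @describeIn BiopsySample-class Compact display.
#' @param object Object to display.
#' @export
setMethod("show", "BiopsySample", function(object) {
  cat(sprintf("BiopsySample: patient %d, core %.1f mm^3 (r = %.2f mm)\n",
              object@patientId, object@coreVolume, object@sphere@radius))
  lab <- ifelse(object@provenance == "triaged", "triaged(neg)",
                ifelse(object@outcomes == 1L, "pos", "neg"))
  cat(" ", paste(sprintf("%s=%s", names(lab), lab), collapse = ", "), "\n")
})

#' @describeIn BackgroundDistribution-class Compact display.
#' @param object Object to display.
#' @export
setMethod("show", "BackgroundDistribution", function(object) {
  cat(sprintf("BackgroundDistribution %s: p+ = %.4f (%d / %d voxels)\n",
              object@outcome, object@pPos, round(object@nPos),
              round(object@nPos + object@nNeg)))
})

#' @describeIn ChiSquareMap-class Compact display.
#' @param object Object to display.
#' @export
setMethod("show", "ChiSquareMap", function(object) {
  v <- object@values[is.finite(object@values)]
  cat(sprintf("ChiSquareMap %s (%s space): %d voxels, df = %g, k = %d\n",
              object@outcome, object@space, length(v), object@df, object@k))
  cat(sprintf("  chi2 range [%.3g, %.3g], background p+ = %.4f\n",
              min(v), max(v), object@background@pPos))
})

#' @describeIn SmoothnessEstimate-class Compact display.
#' @param object Object to display.
#' @export
setMethod("show", "SmoothnessEstimate", function(object) {
  cat(sprintf("SmoothnessEstimate: FWHM (%.2f, %.2f, %.2f) mm, %.1f resels over %d voxels\n",
              object@fwhm[1], object@fwhm[2], object@fwhm[3],
              object@resels, object@nMaskVoxels))
})

#' @describeIn ClusterTable-class Compact display.
#' @param object Object to display.
#' @export
setMethod("show", "ClusterTable", function(object) {
  cat(sprintf("ClusterTable: %d clusters above z = %.2f, %d surviving FWER %.2g\n",
              nrow(object@clusters), object@zThreshold,
              length(object@survivors), object@fwerThreshold))
  if (nrow(object@clusters))
    print(utils::head(object@clusters[order(object@clusters$p), ], 5))
})

#' @describeIn LogitFit-class Compact display.
#' @param object Object to display.
#' @export
setMethod("show", "LogitFit", function(object) {
  cat(sprintf("LogitFit %s: n = %d, Wald chi2(5) = %.2f (p = %.3g), pseudo R2 = %.4f%s\n",
              object@outcome, object@nObs, object@waldChi2, object@waldP,
              object@pseudoR2,
              if (object@converged) "" else " [NOT CONVERGED]"))
})

#' @describeIn PhantomSpec-class Compact display.
#' @param object Object to display.
#' @export
setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d patients, grid %s at %s mm, seed %d\n",
              object@nPatients, paste(object@dim, collapse = "x"),
              paste(format(object@spacing), collapse = "x"), object@seed))
  cat(sprintf("  noise SD %.3g (FWHM %.1f mm), signature max |offset| %.2f\n",
              object@noiseSD, object@smoothingFWHM, max(abs(object@signature))))
})
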