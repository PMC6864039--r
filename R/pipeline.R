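#' Whole-brain RFT-corrected mapping (sub-analysis 3)
#'
#' For each requested patient and each outcome with a defined `k_opt`:
#' builds the whole-brain chi-square map from the leave-one-patient-out
#' model, Gaussianizes it, estimates its smoothness, runs random-field-theory
#' cluster inference at the FWER level, and scores accuracy/sensitivity over
#' the patient's biopsy voxels. A per-patient Benjamini-Hochberg correction
#' over the same biopsy voxels at the same k is co-computed so the two
#' corrections can be compared like for like.
#'
#' @param fm Pooled feature matrix.
#' @param volumes List of normalized [PatientVolumeSet-class] objects indexed
#'   by patient (e.g. `cohortFeatureMatrix()$normalized`).
#' @param kOpt Named integer vector of neighbor counts per outcome (`NA`
#'   skips the outcome with a warning, mirroring untuned outcomes).
#' @param patients Patient ids to map (default: all in `fm`). Whole-brain
#'   maps cost about a minute per patient at 64^3; see the vignette.
#' @param alpha FWER level.
#' @param zThreshold Cluster-forming threshold.
#' @param connectivity Cluster connectivity (26 or 6).
#' @param truth Optional list of per-patient truth lists (as produced by
#'   [generateCohort()]) for Dice overlap scoring.
#' @param outputDir Optional directory; when given, the chi-square map,
#'   z-field, surviving-cluster map (NIfTI) and cluster table (TSV) are
#'   written per patient and outcome.
#' @param chi2Scale Pseudo-count scale of the Pearson transform (see
#'   [runSubhyp2()]).
#' @return List with `summary` (per-outcome: k, mean ACC, total significant
#'   biopsy/brain voxels, RFT and BH sensitivities, pooled Dice),
#'   `perPatient` (long data.frame), and `clusterTables`.
#' @export
runSubhyp3 <- function(fm, volumes, kOpt, patients = NULL, alpha = 0.05,
                       zThreshold = defaultClusterForming(), connectivity = 26,
                       truth = NULL, outputDir = NULL, chi2Scale = 1) {
  outcomes <- names(kOpt)
  stopifnot(all(outcomes %in% outcomeNames()))
  if (is.null(patients)) patients <- sort(unique(fm$patient_id))
  backgrounds <- lapply(outcomes, function(oc) backgroundDistribution(fm, oc))
  names(backgrounds) <- outcomes
  rows <- list(); ctabs <- list()

  for (id in patients) {
    pvs <- volumes[[id]]
    stopifnot(pvs@patientId == id)
    geom <- gridGeometry(pvs)
    test <- fm[fm$patient_id == id, , drop = FALSE]
    bidx <- test$voxel_i + (test$voxel_j - 1L) * geom$dim[1] +
      (test$voxel_k - 1L) * geom$dim[1] * geom$dim[2]
    for (oc in outcomes) {
      k <- kOpt[[oc]]
      if (is.na(k)) {
        warning("no k_opt for outcome ", oc, "; skipping")
        next
      }
      map <- wholeBrainMap(fm, pvs, oc, k, backgrounds[[oc]], chi2Scale)
      z <- chi2FieldToZ(map)
      supra <- !is.na(z) & pvs@brainMask & z > zThreshold
      if (any(supra)) {
        # a map with no supra-threshold voxels (or a flat one, e.g. a patient
        # whose every prediction equals a degenerate extreme) has nothing to
        # cluster, and a flat field has no estimable smoothness
        sm <- estimateSmoothness(z, pvs@brainMask, geom$spacing)
        ct <- clusterInference(z, pvs@brainMask, sm, zThreshold, alpha,
                               connectivity, chi2Field = map@values)
      } else {
        sm <- NULL
        ct <- new("ClusterTable",
                  clusters = data.frame(label = integer(0), size = integer(0),
                                        peakZ = numeric(0), peakChi2 = numeric(0),
                                        peakI = integer(0), peakJ = integer(0),
                                        peakK = integer(0), p = numeric(0)),
                  fwerThreshold = alpha, survivors = integer(0),
                  labelArray = array(0L, dim = dim(z)), zThreshold = zThreshold)
      }
      surv <- survivingClusterMask(ct)
      ctabs[[paste(id, oc, sep = ".")]] <- ct

      pPos <- attr(map@values, "pPos")[bidx]
      truthLab <- test[[outcomeColumns()[match(oc, outcomeNames())]]]
      rejRFT <- surv[bidx]
      accRFT <- if (any(rejRFT))
        mean(as.integer(pPos[rejRFT] > 0.5) == truthLab[rejRFT]) else NA_real_

      # matched BH correction over the same biopsy voxels at the same k
      pBio <- chi2ToP(map@values[bidx], df = 1)
      rejBH <- bhReject(pBio, alpha)@reject
      accBH <- if (any(rejBH))
        mean(as.integer(pPos[rejBH] > 0.5) == truthLab[rejBH]) else NA_real_

      dice <- NA_real_; truePos <- NA
      if (!is.null(truth)) {
        truePos <- truth[[id]]$trueLabels[[oc]] == 1L
        if (truePos) {
          tm <- truth[[id]]$tumorMask
          dice <- 2 * sum(surv & tm) / (sum(surv) + sum(tm))
        }
      }
      rows[[paste(id, oc, sep = ".")]] <- data.frame(
        patient_id = id, outcome = oc, k = k,
        n_biopsy = length(bidx),
        n_sig_rft = sum(rejRFT), n_sig_bh = sum(rejBH),
        n_sig_brain = sum(surv),
        acc_rft = accRFT, acc_bh = accBH,
        sens_rft = 100 * sum(rejRFT) / length(bidx),
        sens_bh = 100 * sum(rejBH) / length(bidx),
        fwhm = if (is.null(sm)) NA_real_ else mean(sm@fwhm),
        resels = if (is.null(sm)) NA_real_ else sm@resels,
        true_positive = truePos, dice = dice)

      if (!is.null(outputDir)) {
        pd <- file.path(outputDir, sprintf("patient_%03d", id))
        dir.create(pd, recursive = TRUE, showWarnings = FALSE)
        base <- tolower(gsub("[^A-Za-z0-9]", "", oc))
        writeNiftiVolume(ifelse(is.na(map@values), 0, map@values),
                         file.path(pd, paste0("chi2_", base, ".nii.gz")),
                         geom$spacing, geom$origin)
        writeNiftiVolume(ifelse(is.na(z), 0, z),
                         file.path(pd, paste0("z_", base, ".nii.gz")),
                         geom$spacing, geom$origin)
        writeNiftiVolume(ifelse(is.na(map@values) | !surv, 0, map@values),
                         file.path(pd, paste0("chi2_", base, "_rft.nii.gz")),
                         geom$spacing, geom$origin)
        ctab <- ct@clusters
        ctab$survives <- ctab$label %in% ct@survivors
        write.table(ctab,
                    file.path(pd, paste0("clusters_", base, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  perPatient <- do.call(rbind, rows)
  rownames(perPatient) <- NULL
  summary <- NULL
  if (!is.null(perPatient) && nrow(perPatient)) {
    summary <- do.call(rbind, lapply(split(perPatient, perPatient$outcome),
                                     function(d) {
      poolDice <- if (!is.null(truth) && any(d$true_positive %in% TRUE)) {
        dp <- d[d$true_positive %in% TRUE, , drop = FALSE]
        mean(dp$dice)
      } else NA_real_
      data.frame(outcome = d$outcome[1], k = d$k[1],
                 acc = mean(d$acc_rft, na.rm = TRUE),
                 n_sig = sum(d$n_sig_rft), n_sig_brain = sum(d$n_sig_brain),
                 sens = mean(d$sens_rft), sens_bh = mean(d$sens_bh),
                 acc_bh = mean(d$acc_bh, na.rm = TRUE),
                 dice = poolDice)
    }))
    rownames(summary) <- NULL
  }
  list(summary = summary, perPatient = perPatient, clusterTables = ctabs)
}

#' Run the three sub-analyses end to end
#'
#' Convenience wrapper: builds the cohort feature matrix, runs the logistic
#' screen, the leave-one-patient-out kNN optimization with BH correction,
#' and whole-brain RFT mapping at the selected k per outcome.
#'
#' @param cohort Cohort list ([generateCohort()] / [readCohort()]).
#' @param kGrid Neighbor-count grid for the optimization.
#' @param alpha Significance level (both corrections).
#' @param accFloor Accuracy floor for the k selection.
#' @param zThreshold RFT cluster-forming threshold.
#' @param patients Patients to map in the whole-brain stage (default all).
#' @param outputDir Optional output directory for NIfTI/TSV artifacts.
#' @return List with `screen`, `loo`, `maps` components.
#' @export
runPipeline <- function(cohort, kGrid = defaultKGrid(), alpha = 0.05,
                        accFloor = 0.95, zThreshold = defaultClusterForming(),
                        patients = NULL, outputDir = NULL) {
  cfm <- cohortFeatureMatrix(cohort)
  screen <- runSubhyp1(cfm$fm)
  loo <- runSubhyp2(cfm$fm, kGrid, alpha, accFloor)
  kOpt <- stats::setNames(loo$summary$k_opt, loo$summary$outcome)
  truth <- lapply(cohort, function(p) p$truth)
  haveTruth <- !any(vapply(truth, is.null, logical(1)))
  maps <- runSubhyp3(cfm$fm, cfm$normalized, kOpt, patients = patients,
                     alpha = alpha, zThreshold = zThreshold,
                     truth = if (haveTruth) truth else NULL,
                     outputDir = outputDir)
  list(screen = screen, loo = loo, maps = maps, featureMatrix = cfm$fm)
}
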