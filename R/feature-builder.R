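#' Apply the triage-to-negative labeling rule
#'
#' Raw pathology tokens become binary flags with provenance: `pos` maps to
#' 1/tested, `neg` to 0/tested, and `triaged` (the pathologist elected not to
#' run the assay) to 0/triaged — untested outcomes are recorded negative by
#' study convention.
#'
#' @param outcomes Named character vector over [outcomeNames()] with values
#'   in `pos`, `neg`, `triaged`.
#' @return List with `flags` (named 0/1 integer vector) and `provenance`
#'   (named character, "tested"/"triaged").
#' @examples
#' applyTriageRule(c(IDH1 = "pos", MGMT = "triaged", CNEC = "neg", MVP = "triaged"))
#' @export
applyTriageRule <- function(outcomes) {
  on <- outcomeNames()
  outcomes <- outcomes[on]
  if (any(is.na(outcomes)))
    stop("outcomes must be named over ", paste(on, collapse = ", "))
  bad <- setdiff(unique(outcomes), c("pos", "neg", "triaged"))
  if (length(bad))
    stop("unknown outcome token: ", paste(bad, collapse = ", "))
  flags <- ifelse(outcomes == "pos", 1L, 0L)
  prov <- ifelse(outcomes == "triaged", "triaged", "tested")
  names(flags) <- on; names(prov) <- on
  list(flags = flags, provenance = prov)
}

featureMatrixColumns <- function() {
  c(contrastColumns(), "patient_id", outcomeColumns(),
    paste0("prov_", outcomeColumns()))
}

#' Extract labeled voxel records from biopsy spheres
#'
#' One record per in-sphere voxel per core: the five normalized contrast
#' values at the voxel, the patient id, the core's four binary outcome flags
#' with provenance, and the voxel index. Voxels covered by two overlapping
#' cores appear once per core, preserving the specimen-to-voxel mapping.
#'
#' @param pvs A normalized [PatientVolumeSet-class].
#' @param samples List of [BiopsySample-class] objects for this patient.
#' @return data.frame with columns `t1w, t1wpost, t2w, flair, adc, patient_id,
#'   idh1, mgmt, cnec, mvp, prov_*`, plus `core`, `voxel_i`, `voxel_j`,
#'   `voxel_k`. Warns (with the patient id) on a core whose sphere rasterizes
#'   to no voxels.
#' @export
extractBiopsyVoxels <- function(pvs, samples) {
  if (!pvs@normalized)
    stop("volumes must be normalized to white matter before feature extraction")
  geom <- gridGeometry(pvs)
  cn <- contrastNames()
  out <- vector("list", length(samples))
  for (s in seq_along(samples)) {
    smp <- samples[[s]]
    if (smp@patientId != pvs@patientId)
      stop("biopsy sample patient id does not match the volume set")
    msk <- withCallingHandlers(
      sphereMask(smp@sphere, geom),
      warning = function(w) {
        warning("patient ", pvs@patientId, ", core ", s, ": ",
                conditionMessage(w), call. = FALSE)
        invokeRestart("muffleWarning")
      })
    idx <- which(msk)
    if (!length(idx)) next
    ijk <- arrayInd(idx, geom$dim)
    rec <- data.frame(matrix(0, length(idx), 5))
    names(rec) <- contrastColumns()
    for (a in seq_along(cn)) rec[[a]] <- pvs@contrasts[[cn[a]]]@data[idx]
    rec$patient_id <- pvs@patientId
    for (j in seq_along(outcomeColumns()))
      rec[[outcomeColumns()[j]]] <- smp@outcomes[[outcomeNames()[j]]]
    for (j in seq_along(outcomeColumns()))
      rec[[paste0("prov_", outcomeColumns()[j])]] <- smp@provenance[[outcomeNames()[j]]]
    rec$core <- s
    rec$voxel_i <- ijk[, 1]; rec$voxel_j <- ijk[, 2]; rec$voxel_k <- ijk[, 3]
    out[[s]] <- rec
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    empty <- data.frame(matrix(numeric(0), 0, length(featureMatrixColumns()) + 4))
    names(empty) <- c(featureMatrixColumns(), "core", "voxel_i", "voxel_j", "voxel_k")
    return(empty)
  }
  do.call(rbind, out)
}

#' Pool per-patient voxel records into the cohort feature matrix
#'
#' @param patientFrames List of data.frames from [extractBiopsyVoxels()].
#' @return A single data.frame (rows = voxels across all cores and patients).
#' @export
buildFeatureMatrix <- function(patientFrames) {
  fm <- do.call(rbind, patientFrames)
  rownames(fm) <- NULL
  stopifnot(!anyNA(fm[contrastColumns()]))
  fm
}

#' Leave-one-patient-out split of a feature matrix
#'
#' Test rows are exactly the held-out patient's rows; training rows are all
#' others. Train and test partition the matrix: no patient contributes to
#' both sides.
#'
#' @param fm Feature matrix (data.frame with a `patient_id` column).
#' @param holdout Patient id to hold out.
#' @return List with `train` and `test` data.frames.
#' @export
looSplit <- function(fm, holdout) {
  if (!holdout %in% fm$patient_id)
    stop("unknown patient id: ", holdout)
  test <- fm$patient_id == holdout
  list(train = fm[!test, , drop = FALSE], test = fm[test, , drop = FALSE])
}

#' Cohort background distribution of one outcome
#'
#' The voxel-wise expected class distribution: the fraction of all
#' biopsy-labeled voxels (tested and triaged alike) carrying a positive flag.
#' Computed once on the full cohort; it is the expected distribution of the
#' Pearson chi-square transform.
#'
#' @param fm Feature matrix.
#' @param outcome One of [outcomeNames()].
#' @return A [BackgroundDistribution-class].
#' @export
backgroundDistribution <- function(fm, outcome) {
  col <- outcomeColumns()[match(outcome, outcomeNames())]
  if (is.na(col)) stop("unknown outcome: ", outcome)
  if (!nrow(fm)) stop("feature matrix has no rows")
  nPos <- sum(fm[[col]] == 1L)
  BackgroundDistribution(outcome, nPos, nrow(fm) - nPos)
}

#' Write / read a feature matrix as TSV
#'
#' @param fm Feature matrix.
#' @param path TSV file path.
#' @return `path` (write) or the data.frame (read).
#' @export
writeFeatureMatrix <- function(fm, path) {
  utils::write.table(fm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
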