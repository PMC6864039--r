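#' Pearson chi-square transform of a class probability
#'
#' Compares the predicted two-class probability vector with the cohort
#' background distribution. Observed pseudo-counts are the k neighbors split
#' by predicted probability, expected counts are k split by the background:
#' `chi2 = k * ((p_pos - q_pos)^2 / q_pos + (p_neg - q_neg)^2 / q_neg)`,
#' on 1 degree of freedom (two cells, one constraint).
#'
#' @param pPos Predicted positive-class probability (vectorized).
#' @param background A [BackgroundDistribution-class]; its `pPos` must lie
#'   strictly inside (0, 1).
#' @param k Neighbor count scaling the pseudo-counts.
#' @return Nonnegative chi-square values; zero iff prediction equals the
#'   background.
#' @examples
#' pearsonChi2(1, BackgroundDistribution("CNEC", 1, 1), 10)   # 10
#' @export
pearsonChi2 <- function(pPos, background, k) {
  q <- background@pPos
  if (q <= 0 || q >= 1)
    stop("degenerate background distribution (pPos = ", q, ")")
  k * ((pPos - q)^2 / q + ((1 - pPos) - (1 - q))^2 / (1 - q))
}

#' Upper-tail p-value of a chi-square statistic
#'
#' @param chi2 Nonnegative statistic (vectorized).
#' @param df Degrees of freedom.
#' @return Upper-tail probability.
#' @export
chi2ToP <- function(chi2, df = 1) {
  if (any(chi2 < 0, na.rm = TRUE)) stop("chi-square values must be nonnegative")
  pchisq(chi2, df, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up rejection
#'
#' Sorts the p-values ascending, finds the largest i with
#' `p_(i) <= i * alpha / m`, and rejects every p-value at or below that
#' order statistic; no such i means no rejections. Applied within one
#' patient's voxel family.
#'
#' @param pValues p-values in `[0, 1]`.
#' @param alpha Target false-discovery rate (default 0.05).
#' @return A [SignificanceResult-class]; `threshold` is the realized cutoff
#'   (0 when nothing is rejected). An empty input yields an empty result.
#' @examples
#' bhReject(c(0.01, 0.02, 0.04, 0.5), 0.05)  # rejects 0.01 and 0.02
#' @export
bhReject <- function(pValues, alpha = 0.05) {
  m <- length(pValues)
  if (m == 0L)
    return(new("SignificanceResult", pValues = numeric(0), reject = logical(0),
               threshold = 0, correction = "BH", alpha = alpha))
  if (any(pValues < 0 | pValues > 1)) stop("p-values must lie in [0, 1]")
  ps <- sort(pValues)
  ok <- which(ps <= seq_len(m) * alpha / m)
  thr <- if (length(ok)) ps[max(ok)] else 0
  new("SignificanceResult", pValues = pValues,
      reject = pValues <= thr & thr > 0,
      threshold = thr, correction = "BH", alpha = alpha)
}

#' Per-patient confusion matrices and mean accuracy
#'
#' Predictions are the class of greatest probability, taken only over voxels
#' that passed the FWER correction. Accuracy per patient is the fraction of
#' its rejected voxels classified correctly; the cohort accuracy is the mean
#' over patients contributing at least one rejected voxel (patients with none
#' are excluded rather than counted as undefined zeros).
#'
#' @param predicted 0/1 predicted class per voxel.
#' @param truth 0/1 recorded label per voxel.
#' @param patientId Patient id per voxel.
#' @param rejected Logical: did the voxel pass the correction?
#' @return List with `confusion` (per-patient 2x2 tables), `perPatient`
#'   (named accuracy vector), and `acc` (mean accuracy, `NA` when no patient
#'   contributes).
#' @export
confusionAccuracy <- function(predicted, truth, patientId, rejected) {
  keep <- rejected
  ids <- unique(patientId[keep])
  conf <- list(); accs <- numeric(0)
  for (id in ids) {
    sel <- keep & patientId == id
    tab <- table(factor(predicted[sel], levels = 0:1),
                 factor(truth[sel], levels = 0:1),
                 dnn = c("predicted", "truth"))
    conf[[as.character(id)]] <- tab
    accs[as.character(id)] <- mean(predicted[sel] == truth[sel])
  }
  list(confusion = conf, perPatient = accs,
       acc = if (length(accs)) mean(accs) else NA_real_)
}

#' Classification sensitivity: share of biopsy voxels passing the threshold
#'
#' Primary definition: mean over patients of the per-patient percentage of
#' biopsy voxels rejected. A pooled variant (total rejected over total biopsy
#' voxels) is co-reported.
#'
#' @param nRejected Per-patient rejected voxel counts.
#' @param nBiopsy Per-patient biopsy voxel counts (positive).
#' @return List with `perPatient` and `pooled` sensitivities, in percent.
#' @export
sensitivity <- function(nRejected, nBiopsy) {
  stopifnot(length(nRejected) == length(nBiopsy), all(nBiopsy > 0))
  list(perPatient = 100 * mean(nRejected / nBiopsy),
       pooled = 100 * sum(nRejected) / sum(nBiopsy))
}

#' Select the optimal neighbor count
#'
#' `k_opt` maximizes SENS(k) among k with `ACC(k) >= accFloor`; ties break
#' toward the smaller k. When no k qualifies, `k_opt` is `NA` (the
#' no-significant-voxels pattern).
#'
#' @param trace data.frame with columns `k`, `acc`, `sens`.
#' @param accFloor Minimum acceptable accuracy (default 0.95).
#' @return List with `kOpt` (integer or `NA`) and the input `trace`.
#' @export
optimizeK <- function(trace, accFloor = 0.95) {
  stopifnot(nrow(trace) >= 1)
  trace <- trace[order(trace$k), , drop = FALSE]
  ok <- !is.na(trace$acc) & trace$acc >= accFloor
  kOpt <- NA_integer_
  if (any(ok)) {
    cand <- trace[ok, , drop = FALSE]
    kOpt <- as.integer(cand$k[which.max(cand$sens)])  # which.max: first max = smallest k
  }
  list(kOpt = kOpt, trace = trace)
}

#' Default neighbor-count grid
#'
#' @return Integer grid 100, 200, ..., 3000, bracketing the optima reported
#'   for the clinical cohort (700-3000).
#' @export
defaultKGrid <- function() as.integer(seq(100, 3000, by = 100))

#' Leave-one-patient-out classification with BH correction (sub-analysis 2)
#'
#' Runs every leave-one-patient-out experiment over the k grid and all
#' requested outcomes: inverse-distance-weighted kNN probabilities, Pearson
#' chi-square against the cohort background, per-patient Benjamini-Hochberg
#' at `alpha`, per-k accuracy/sensitivity, and the k optimization.
#'
#' @param fm Pooled feature matrix.
#' @param kGrid Increasing neighbor counts; entries exceeding the smallest
#'   training fold are dropped with a warning.
#' @param alpha FDR level for the per-patient BH correction.
#' @param accFloor Accuracy floor for [optimizeK()].
#' @param outcomes Outcomes to run.
#' @param chi2Scale Pseudo-count scale of the Pearson transform. The default
#'   1 is the probability-vector statistic the study's result tables imply
#'   (see the methods vignette); pass the neighbor count to use k-scaled
#'   pseudo-counts instead.
#' @param keepPerVoxel Keep per-voxel probabilities/rejections at each k
#'   (memory-heavy; for diagnostics).
#' @return List with `trace` (outcome, k, acc, sens_perpatient, sens_pooled,
#'   n_significant), `summary` (outcome, k_opt, acc, n_sig, sens),
#'   `backgrounds`, and `perVoxel` (NULL unless `keepPerVoxel`).
#' @export
runSubhyp2 <- function(fm, kGrid = defaultKGrid(), alpha = 0.05,
                       accFloor = 0.95, outcomes = outcomeNames(),
                       chi2Scale = 1, keepPerVoxel = FALSE) {
  ids <- sort(unique(fm$patient_id))
  minTrain <- nrow(fm) - max(table(fm$patient_id))
  if (any(kGrid > minTrain)) {
    warning("dropping k values exceeding the smallest training fold (",
            minTrain, ")")
    kGrid <- kGrid[kGrid <= minTrain]
  }
  kGrid <- sort(as.integer(kGrid))
  stopifnot(length(kGrid) >= 1)
  backgrounds <- lapply(outcomes, function(oc) backgroundDistribution(fm, oc))
  names(backgrounds) <- outcomes
  ocCols <- outcomeColumns()[match(outcomes, outcomeNames())]

  nK <- length(kGrid)
  accList <- vector("list", length(outcomes) * nK)
  dim(accList) <- c(length(outcomes), nK)
  nRej <- array(0, dim = c(length(outcomes), nK, length(ids)))
  nBio <- numeric(length(ids))
  perVoxel <- if (keepPerVoxel) list() else NULL

  for (pi in seq_along(ids)) {
    sp <- looSplit(fm, ids[pi])
    nBio[pi] <- nrow(sp$test)
    probs <- wknnProbabilities(as.matrix(sp$train[contrastColumns()]),
                               as.matrix(sp$train[ocCols]),
                               as.matrix(sp$test[contrastColumns()]), kGrid)
    for (oi in seq_along(outcomes)) {
      q <- backgrounds[[oi]]
      truth <- sp$test[[ocCols[oi]]]
      for (ki in seq_len(nK)) {
        pp <- probs[, ki, oi]
        chi2 <- pearsonChi2(pp, q, if (is.null(chi2Scale)) kGrid[ki] else chi2Scale)
        res <- bhReject(chi2ToP(chi2, df = 1), alpha)
        rej <- res@reject
        nRej[oi, ki, pi] <- sum(rej)
        if (any(rej)) {
          pred <- as.integer(pp[rej] > 0.5)
          accList[[oi, ki]] <- c(accList[[oi, ki]],
                                 mean(pred == truth[rej]))
        }
        if (keepPerVoxel)
          perVoxel[[paste(ids[pi], outcomes[oi], kGrid[ki], sep = ".")]] <-
            data.frame(p_pos = pp, chi2 = chi2, reject = rej, truth = truth)
      }
    }
  }

  trace <- do.call(rbind, lapply(seq_along(outcomes), function(oi) {
    do.call(rbind, lapply(seq_len(nK), function(ki) {
      accs <- accList[[oi, ki]]
      sens <- sensitivity(nRej[oi, ki, ], nBio)
      data.frame(outcome = outcomes[oi], k = kGrid[ki],
                 acc = if (length(accs)) mean(accs) else NA_real_,
                 sens_perpatient = sens$perPatient,
                 sens_pooled = sens$pooled,
                 n_significant = sum(nRej[oi, ki, ]))
    }))
  }))
  rownames(trace) <- NULL

  summary <- do.call(rbind, lapply(outcomes, function(oc) {
    tr <- trace[trace$outcome == oc, c("k", "acc", "sens_perpatient")]
    names(tr) <- c("k", "acc", "sens")
    opt <- optimizeK(tr, accFloor)
    row <- trace[trace$outcome == oc & trace$k %in% opt$kOpt, , drop = FALSE]
    data.frame(outcome = oc, k_opt = opt$kOpt,
               acc = if (nrow(row)) row$acc else NA_real_,
               n_sig = if (nrow(row)) row$n_significant else 0L,
               sens = if (nrow(row)) row$sens_perpatient else 0)
  }))
  rownames(summary) <- NULL
  list(trace = trace, summary = summary, backgrounds = backgrounds,
       perVoxel = perVoxel, kGrid = kGrid, alpha = alpha, accFloor = accFloor,
       chi2Scale = chi2Scale)
}

#' Whole-brain chi-square parametric map for one held-out patient
#'
#' Scores every brain-mask voxel of the held-out patient with the model
#' trained on all other patients' biopsy voxels, then applies the Pearson
#' transform against the cohort background. Voxels whose predicted
#' probability equals the background exactly map to zero; voxels outside the
#' brain mask are `NA`.
#'
#' @param fm Pooled feature matrix (all patients; the held-out patient's rows
#'   are removed internally).
#' @param pvs The held-out patient's normalized [PatientVolumeSet-class].
#' @param outcome One of [outcomeNames()].
#' @param k Neighbor count (typically the `k_opt` from [runSubhyp2()]).
#' @param background Optional [BackgroundDistribution-class]; default is
#'   computed from the full `fm`.
#' @param chi2Scale Pseudo-count scale of the Pearson transform (see
#'   [runSubhyp2()]).
#' @return A [ChiSquareMap-class] with `space = "brain"`.
#' @export
wholeBrainMap <- function(fm, pvs, outcome, k, background = NULL,
                          chi2Scale = 1) {
  if (is.na(k)) stop("k_opt is missing for outcome ", outcome)
  if (!pvs@normalized) stop("volumes must be normalized")
  if (is.null(background)) background <- backgroundDistribution(fm, outcome)
  train <- fm[fm$patient_id != pvs@patientId, , drop = FALSE]
  col <- outcomeColumns()[match(outcome, outcomeNames())]
  idx <- which(pvs@brainMask)
  q <- matrix(0, length(idx), 5)
  for (a in seq_along(contrastNames()))
    q[, a] <- pvs@contrasts[[contrastNames()[a]]]@data[idx]
  p <- wknnProbabilities(as.matrix(train[contrastColumns()]), train[[col]],
                         q, as.integer(k))
  chi2 <- pearsonChi2(p[, 1, 1], background,
                      if (is.null(chi2Scale)) k else chi2Scale)
  vals <- array(NA_real_, dim = dim(pvs@brainMask))
  vals[idx] <- chi2
  pArr <- array(NA_real_, dim = dim(pvs@brainMask))
  pArr[idx] <- p[, 1, 1]
  attr(vals, "pPos") <- pArr   # predicted probabilities ride along for scoring
  new("ChiSquareMap", outcome = outcome, values = vals, df = 1,
      background = background, k = as.integer(k), space = "brain")
}
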