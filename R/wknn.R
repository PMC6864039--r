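#' Inverse-distance-weighted kNN class probabilities
#'
#' For each query point the k nearest training points by Euclidean distance in
#' the 5-D normalized-contrast space are weighted by the reciprocal of their
#' distance; the positive-class probability is the positive weight share among
#' the k neighbors. Ties at the k-th distance expand the neighbor set (the
#' result is independent of training-row order); when a query coincides with
#' training points, the whole probability mass is split uniformly over the
#' zero-distance points' labels.
#'
#' @param model A [TrainedWKNN-class].
#' @param query Numeric vector (one point) or matrix (rows = points) in the
#'   training feature space.
#' @return data.frame with columns `p_pos`, `p_neg` (rows = query points,
#'   each pair summing to one).
#' @examples
#' m <- TrainedWKNN(cbind(c(0, 1)), c(0L, 1L), k = 2)
#' predictProba(m, 0.25)  # p_neg 0.75, p_pos 0.25
#' @export
predictProba <- function(model, query) {
  if (is.null(dim(query))) query <- matrix(query, nrow = 1)
  query <- as.matrix(query)
  if (ncol(query) != ncol(model@trainPoints))
    stop("query dimension mismatch")
  if (any(!is.finite(query))) stop("query must be finite")
  p <- .wknnCumProb(model@trainPoints,
                    matrix(model@trainLabels, ncol = 1),
                    query, as.integer(model@k))
  data.frame(p_pos = p[, 1], p_neg = 1 - p[, 1])
}

#' Probabilities over several outcomes and neighbor counts at once
#'
#' Neighbor sets depend only on the contrast values, so one search serves all
#' outcomes and every k in an increasing grid.
#'
#' @param train n x d numeric matrix of training points.
#' @param labels n x m 0/1 matrix (column per outcome) or a vector.
#' @param query q x d matrix.
#' @param kGrid Strictly increasing neighbor counts, `max(kGrid) <= n`.
#' @return Numeric array `q x length(kGrid) x m` of positive-class
#'   probabilities, with dimnames on the k and outcome axes.
#' @export
wknnProbabilities <- function(train, labels, query, kGrid) {
  train <- as.matrix(train)
  if (is.null(dim(labels))) labels <- matrix(labels, ncol = 1)
  labels <- matrix(as.integer(as.matrix(labels)), nrow = nrow(train),
                   dimnames = dimnames(labels))
  query <- as.matrix(query)
  kGrid <- as.integer(kGrid)
  if (any(kGrid > nrow(train)))
    stop("k exceeds the number of training points (", nrow(train), ")")
  p <- .wknnCumProb(train, labels, query, kGrid)
  out <- array(p, dim = c(nrow(query), length(kGrid), ncol(labels)))
  dimnames(out) <- list(NULL, as.character(kGrid), colnames(labels))
  out
}

#' Predict one held-out patient's voxels (one LOO experiment)
#'
#' Trains on every other patient's biopsy voxels and scores the held-out
#' patient's voxels for one outcome. A hard guard rejects any train/test
#' patient overlap, preserving the leave-one-patient-out contract.
#'
#' @param fmTrain,fmTest Feature matrices (train must not contain the test
#'   patient).
#' @param outcome One of [outcomeNames()].
#' @param k Neighbor count.
#' @return data.frame with `p_pos`, `p_neg`, one row per test voxel;
#'   deterministic given the inputs.
#' @export
predictPatient <- function(fmTrain, fmTest, outcome, k) {
  shared <- intersect(unique(fmTrain$patient_id), unique(fmTest$patient_id))
  if (length(shared))
    stop("train/test patient overlap: ", paste(shared, collapse = ", "))
  col <- outcomeColumns()[match(outcome, outcomeNames())]
  if (is.na(col)) stop("unknown outcome: ", outcome)
  p <- wknnProbabilities(as.matrix(fmTrain[contrastColumns()]),
                         fmTrain[[col]],
                         as.matrix(fmTest[contrastColumns()]),
                         k)
  data.frame(p_pos = p[, 1, 1], p_neg = 1 - p[, 1, 1])
}
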