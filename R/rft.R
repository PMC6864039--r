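#' Gaussianize a chi-square map
#'
#' Converts each voxel's chi-square value to the standard-normal quantile of
#' its upper-tail probability, `z = qnorm(1 - p)`, so Gaussian-field Euler
#' characteristic theory applies. Values are clipped to `[-8.2, 8.2]` (the
#' finite range of the double-precision quantile).
#'
#' @param map A [ChiSquareMap-class] (or a numeric array plus `df`).
#' @param df Degrees of freedom when `map` is a plain array.
#' @return z-field of the same shape; `NA` passes through.
#' @export
chi2FieldToZ <- function(map, df = 1) {
  vals <- if (is(map, "ChiSquareMap")) map@values else map
  if (is(map, "ChiSquareMap")) df <- map@df
  p <- pchisq(vals, df, lower.tail = FALSE)
  z <- qnorm(p, lower.tail = FALSE)
  z[!is.na(z)] <- pmin(pmax(z[!is.na(z)], -8.2), 8.2)
  z
}

#' Estimate the spatial smoothness of a statistical field
#'
#' Per-axis FWHM of the effective Gaussian autocorrelation kernel, from the
#' variance of first spatial differences of the standardized in-mask field:
#' `FWHM_a = spacing_a * sqrt(4 ln 2 * var(f) / var_a(diff f))`. The RESEL
#' count is the mask volume divided by the FWHM product. Estimated from the
#' statistical image itself (single-image regime; this design has no
#' residual maps).
#'
#' @param field Numeric 3-D array (z-field).
#' @param mask Logical 3-D array; differences use only voxel pairs fully
#'   inside the mask.
#' @param spacing Voxel size triple (mm).
#' @return A [SmoothnessEstimate-class]. Errors when fewer than 100 in-mask
#'   voxels have valid forward-difference neighbors or when the field has no
#'   variance.
#' @export
estimateSmoothness <- function(field, mask, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(field)) == 3L, identical(dim(field), dim(mask)))
  f <- field
  inm <- mask & is.finite(f)
  v0 <- stats::var(f[inm])
  if (!is.finite(v0) || v0 <= 0) stop("field has zero variance inside the mask")
  f <- (f - mean(f[inm])) / sqrt(v0)
  dm <- dim(f)
  fwhm <- numeric(3)
  nPairs <- integer(3)
  take <- function(arr, a, head) {
    # head: drop the last slice along axis a; otherwise drop the first
    i <- if (head) seq_len(dm[a] - 1L) else 1L + seq_len(dm[a] - 1L)
    if (a == 1) arr[i, , , drop = FALSE]
    else if (a == 2) arr[, i, , drop = FALSE]
    else arr[, , i, drop = FALSE]
  }
  for (a in 1:3) {
    # forward differences over voxel pairs fully inside the mask
    okPair <- take(inm, a, TRUE) & take(inm, a, FALSE)
    d <- (take(f, a, FALSE) - take(f, a, TRUE))[okPair]
    nPairs[a] <- length(d)
    if (nPairs[a] < 100L)
      stop("too few in-mask voxels with forward-difference neighbors on axis ", a)
    vd <- mean(d^2)   # field standardized to unit variance
    if (vd <= 0) stop("zero difference variance on axis ", a)
    fwhm[a] <- spacing[a] * sqrt(4 * log(2) / vd)
  }
  nMask <- sum(inm)
  resels <- nMask * prod(spacing) / prod(fwhm)
  new("SmoothnessEstimate", fwhm = fwhm, resels = resels,
      dlh = (4 * log(2))^1.5 / prod(fwhm), nMaskVoxels = nMask,
      spacing = spacing)
}

#' Expected Euler characteristic of a thresholded Gaussian field
#'
#' The 3-D Gaussian-field EC density times the RESEL count:
#' `E[EC] = R * (4 ln 2)^{3/2} * (2 pi)^{-2} * (z^2 - 1) * exp(-z^2 / 2)`.
#' At high thresholds this approximates the expected number of
#' supra-threshold clusters.
#'
#' @param z Threshold on the standard-normal scale.
#' @param resels RESEL count (positive).
#' @return Expected EC (clamped below at 0; the density has a root at z = 1).
#' @export
expectedEC <- function(z, resels) {
  stopifnot(resels > 0)
  pmax(0, resels * (4 * log(2))^1.5 * (2 * pi)^-2 * (z^2 - 1) * exp(-z^2 / 2))
}

#' Label connected components of a binary 3-D field
#'
#' @param mask Logical 3-D array.
#' @param connectivity 26 (faces+edges+corners, default) or 6 (faces).
#' @return Integer array of labels (0 = background).
#' @export
labelComponents <- function(mask, connectivity = 26) {
  .labelComponents3D(mask, as.integer(connectivity))
}

#' Random-field-theory cluster inference
#'
#' Thresholds the z-field at the cluster-forming level, labels the
#' supra-threshold components, and assigns each cluster a corrected p-value
#' from the Gaussian-RFT cluster-size distribution: with `E[m]` clusters
#' expected ([expectedEC()]) and expected supra-threshold volume
#' `E[N] = n_mask * pnorm(-u)`, cluster sizes follow
#' `P(n >= s) = exp(-beta * s^{2/3})`, `beta = (gamma(5/2) * E[m] / E[N])^{2/3}`,
#' and the corrected p is `1 - exp(-E[m] * P(n >= s))`. Survivors are
#' clusters with `p <= alpha`.
#'
#' @param zField Numeric 3-D array (z scale).
#' @param mask Logical 3-D array.
#' @param smoothness A [SmoothnessEstimate-class] for the field.
#' @param zThreshold Cluster-forming threshold (default
#'   [defaultClusterForming()]).
#' @param alpha FWER level (default 0.05).
#' @param connectivity 26 or 6.
#' @param chi2Field Optional chi-square array aligned with `zField`, used to
#'   report peak chi-square values.
#' @return A [ClusterTable-class]; an empty table when nothing is
#'   supra-threshold.
#' @export
clusterInference <- function(zField, mask, smoothness,
                             zThreshold = defaultClusterForming(),
                             alpha = 0.05, connectivity = 26,
                             chi2Field = NULL) {
  stopifnot(is(smoothness, "SmoothnessEstimate"))
  supra <- !is.na(zField) & mask & zField > zThreshold
  lab <- labelComponents(supra, connectivity)
  nClusters <- max(lab)
  emptyTab <- data.frame(label = integer(0), size = integer(0),
                         peakZ = numeric(0), peakChi2 = numeric(0),
                         peakI = integer(0), peakJ = integer(0),
                         peakK = integer(0), p = numeric(0))
  if (nClusters == 0L)
    return(new("ClusterTable", clusters = emptyTab, fwerThreshold = alpha,
               survivors = integer(0), labelArray = lab,
               zThreshold = zThreshold))

  Em <- expectedEC(zThreshold, smoothness@resels)
  EN <- sum(mask) * pnorm(zThreshold, lower.tail = FALSE)
  # degenerate geometry guard: with no expected clusters nothing can be called
  beta <- if (Em > 0 && EN > 0) (gamma(5 / 2) * Em / EN)^(2 / 3) else Inf

  idxAll <- which(lab > 0)
  labs <- lab[idxAll]
  zs <- zField[idxAll]
  rows <- lapply(seq_len(nClusters), function(li) {
    sel <- labs == li
    sz <- sum(sel)
    pk <- which.max(zs[sel])
    vox <- idxAll[sel][pk]
    ijk <- arrayInd(vox, dim(zField))
    pSize <- if (is.finite(beta)) exp(-beta * sz^(2 / 3)) else 0
    p <- 1 - exp(-Em * pSize)
    data.frame(label = li, size = sz, peakZ = zs[sel][pk],
               peakChi2 = if (is.null(chi2Field)) NA_real_ else chi2Field[vox],
               peakI = ijk[1], peakJ = ijk[2],
               peakK = ijk[3], p = max(min(p, 1), .Machine$double.xmin))
  })
  tab <- do.call(rbind, rows)
  new("ClusterTable", clusters = tab, fwerThreshold = alpha,
      survivors = as.integer(tab$label[tab$p <= alpha]), labelArray = lab,
      zThreshold = zThreshold)
}

#' Default cluster-forming threshold
#'
#' @return z = 3.3 on the standard-normal scale, chosen by null-field
#'   calibration so the realized cluster-level family-wise error sits at the
#'   nominal 5% level for fields of moderate smoothness. The z = 2.3
#'   convention of older fMRI tooling belongs to a regime (massive smoothness,
#'   low thresholds) where the cluster-size approximation behaves differently;
#'   see the methods vignette.
#' @export
defaultClusterForming <- function() 3.3

#' Binary mask of voxels inside surviving clusters
#'
#' @param ct A [ClusterTable-class].
#' @return Logical 3-D array.
#' @export
survivingClusterMask <- function(ct) {
  array(ct@labelArray %in% ct@survivors, dim = dim(ct@labelArray))
}

#' Generate a smooth Gaussian null field
#'
#' White Gaussian noise convolved with a Gaussian kernel of the given FWHM
#' and restandardized to zero mean / unit variance; used for the FWER
#' calibration checks and by the phantom generator's noise model. The noise
#' is generated on a grid padded by the kernel support and cropped back, so
#' the returned field is stationary to the edge (in-place boundary handling
#' would re-use edge noise values and inflate the boundary variance, which
#' shows up as excess supra-threshold peaks).
#'
#' @param dim Grid dimensions.
#' @param fwhm Smoothing kernel FWHM in mm (scalar or per-axis).
#' @param spacing Voxel size (mm).
#' @return Numeric 3-D array.
#' @export
smoothGaussianField <- function(dim, fwhm, spacing = c(1, 1, 1)) {
  if (all(fwhm <= 0)) {
    x <- array(rnorm(prod(dim)), dim = dim)
    return((x - mean(x)) / sd(x))
  }
  sigma <- rep(fwhm, length.out = 3) / spacing / (2 * sqrt(2 * log(2)))
  pad <- pmax(1L, ceiling(4 * sigma))
  pdim <- dim + 2L * pad
  x <- array(rnorm(prod(pdim)), dim = pdim)
  x <- .gaussianSmooth3D(x, sigma)
  x <- x[pad[1] + seq_len(dim[1]), pad[2] + seq_len(dim[2]),
         pad[3] + seq_len(dim[3]), drop = FALSE]
  (x - mean(x)) / sd(x)
}
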