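# Small cohorts used across test files. Generation costs a few seconds at
# 32^3; results are cached per session via local environments.

tinyPhantomSpec <- function(seed = 7L, nPatients = 6L, null = FALSE) {
  spec <- if (null) nullPhantomSpec(seed, nPatients) else
    defaultPhantomSpec(seed, nPatients)
  spec@dim <- c(32L, 32L, 32L)
  spec@brainRadius <- 14
  spec@wmCenter <- c(8, 0, 0); spec@wmRadius <- 3
  spec@tumorCenterBase <- c(-5, 0, 0); spec@tumorCenterJitter <- 2
  spec@tumorRadiusRange <- c(4, 6)
  spec@coreVolumeMeanLog <- log(150); spec@coreVolumeSDLog <- 0.2
  spec
}

.cache <- new.env(parent = emptyenv())

cachedTinyCohort <- function() {
  if (is.null(.cache$tiny)) {
    coh <- generateCohort(tinyPhantomSpec())
    cfm <- cohortFeatureMatrix(coh)
    .cache$tiny <- list(cohort = coh, fm = cfm$fm, normalized = cfm$normalized)
  }
  .cache$tiny
}

# independent brute-force reference for the weighted kNN probability
bruteForceWKNN <- function(train, labels, query, k) {
  d <- sqrt(colSums((t(train) - query)^2))
  ord <- order(d)
  kth <- d[ord[k]]
  nb <- which(d <= kth + kth * 1e-12)       # tie expansion at the k-th distance
  if (any(d[nb] == 0)) {
    z <- nb[d[nb] == 0]
    return(mean(labels[z]))
  }
  w <- 1 / d[nb]
  sum(w[labels[nb] == 1]) / sum(w)
}

# independent flood-fill labeling (6 or 26 connectivity) for small grids
floodFillLabels <- function(mask, connectivity = 26) {
  dm <- dim(mask)
  lab <- array(0L, dim = dm)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  nextLab <- 0L
  for (v in which(mask)) {
    if (lab[v] != 0L) next
    nextLab <- nextLab + 1L
    queue <- matrix(arrayInd(v, dm), ncol = 3)
    lab[v] <- nextLab
    while (nrow(queue)) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (o in seq_len(nrow(offs))) {
        nb <- cur + offs[o, ]
        if (any(nb < 1) || any(nb > dm)) next
        if (mask[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- nextLab
          queue <- rbind(queue, nb)
        }
      }
    }
  }
  lab
}

# map component labels to a canonical form (sorted voxel-set signature) so two
# labelings can be compared irrespective of label order
canonicalComponents <- function(lab) {
  sets <- split(which(lab > 0), lab[lab > 0])
  unname(sets[order(vapply(sets, min, numeric(1)))])
}
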