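#' Inverse inclusion-probability weights for a binary outcome
#'
#' Each row is weighted by the reciprocal of its class's sample fraction, so
#' the weighted mass of the two classes is equal — the design-based correction
#' for the severe voxel class imbalance.
#'
#' @param flags 0/1 vector.
#' @return Numeric weight vector; errors when only one class is present.
#' @examples
#' inclusionWeights(c(1, 1, rep(0, 8)))  # positives 5, negatives 1.25
#' @export
inclusionWeights <- function(flags) {
  p1 <- mean(flags == 1)
  if (p1 <= 0 || p1 >= 1)
    stop("both classes must be present to form inclusion weights")
  ifelse(flags == 1, 1 / p1, 1 / (1 - p1))
}

weightedBernoulliLogLik <- function(y, mu, w) {
  eps <- 1e-12
  sum(w * (y * log(pmax(mu, eps)) + (1 - y) * log(pmax(1 - mu, eps))))
}

# IRLS for the weighted logit; convergence when max|score| < scoreTol
# or after maxIter iterations (flagged, not silently truncated).
irlsWeightedLogit <- function(X, y, w, scoreTol = 1e-8, maxIter = 100L) {
  beta <- numeric(ncol(X))
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    score <- drop(crossprod(X, w * (y - mu)))
    if (max(abs(score)) < scoreTol) { converged <- TRUE; break }
    wirls <- w * mu * (1 - mu)
    info <- crossprod(X, X * wirls)
    step <- tryCatch(solve(info, score), error = function(e)
      stop("information matrix is singular (perfect separation?)"))
    # step-halving to keep the likelihood ascending
    ll0 <- weightedBernoulliLogLik(y, mu, w)
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      llc <- weightedBernoulliLogLik(y, plogis(drop(X %*% cand)), w)
      if (llc >= ll0 - 1e-10 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    beta <- beta + lambda * step
  }
  if (!converged)
    warning("IRLS reached the iteration cap without score convergence ",
            "(possible separation)")
  mu <- plogis(drop(X %*% beta))
  list(beta = beta, mu = mu, converged = converged,
       info = crossprod(X, X * (w * mu * (1 - mu))))
}

#' Huber-White robust covariance of a weighted logit fit
#'
#' Sandwich estimator: bread = inverse weighted information, meat = outer
#' product of the per-row weighted scores.
#'
#' @param X Design matrix (with intercept column).
#' @param y 0/1 response.
#' @param w Row weights.
#' @param beta Coefficient vector at the converged fit.
#' @return Covariance matrix of `beta`.
#' @export
robustVcov <- function(X, y, w, beta) {
  mu <- plogis(drop(X %*% beta))
  info <- crossprod(X, X * (w * mu * (1 - mu)))
  bread <- tryCatch(solve(info), error = function(e)
    stop("singular information matrix in sandwich bread"))
  u <- X * (w * (y - mu))       # per-row weighted score contributions
  meat <- crossprod(u)
  bread %*% meat %*% bread
}

#' Fit the inclusion-weighted maximum-likelihood logit
#'
#' Regresses one binary outcome on the five normalized contrasts by
#' iteratively reweighted least squares on the weighted Bernoulli
#' log-likelihood (score tolerance 1e-8, at most 100 iterations). The null
#' model is the intercept-only weighted fit; McFadden's pseudo R-squared is
#' `1 - loglik_full / loglik_null`. The joint Wald chi-square tests the five
#' contrast coefficients against zero using the robust covariance.
#'
#' @param X Numeric n x 5 matrix of contrast values (no intercept column).
#' @param y 0/1 response vector.
#' @param w Row weights; defaults to [inclusionWeights()] of `y`.
#' @param outcome Outcome name carried into the result.
#' @return A [LogitFit-class].
#' @export
fitWeightedLogit <- function(X, y, w = inclusionWeights(y), outcome = "outcome") {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("constant predictor column besides the intercept")
  Xd <- cbind(`(Intercept)` = 1, X)
  fit <- irlsWeightedLogit(Xd, y, w)
  llFull <- weightedBernoulliLogLik(y, fit$mu, w)

  # intercept-only null: closed form, mu0 = weighted mean of y
  mu0 <- sum(w * y) / sum(w)
  llNull <- weightedBernoulliLogLik(y, rep(mu0, length(y)), w)

  V <- robustVcov(Xd, y, w, fit$beta)
  rse <- sqrt(pmax(diag(V), 0))
  bC <- fit$beta[-1L]
  VC <- V[-1L, -1L, drop = FALSE]
  wstat <- tryCatch(drop(t(bC) %*% solve(VC, bC)), error = function(e)
    stop("singular coefficient covariance in Wald test"))
  df <- length(bC)
  new("LogitFit", outcome = outcome,
      coefficients = fit$beta, robustSE = rse, vcovRobust = V,
      vcovModel = solve(fit$info),
      loglikFull = llFull, loglikNull = llNull,
      waldChi2 = wstat, waldP = pchisq(wstat, df, lower.tail = FALSE),
      pseudoR2 = max(0, 1 - llFull / llNull),
      nObs = length(y), converged = fit$converged)
}

#' Joint and single-coefficient Wald tests
#'
#' The joint test is `b' V^-1 b` over the five contrast coefficients (5 df)
#' with the robust covariance; single-coefficient tests reduce to
#' `(beta/SE)^2` on 1 df.
#'
#' @param fit A [LogitFit-class].
#' @param coef Optional single coefficient name/index (excluding intercept)
#'   for a 1-df test; default is the joint test.
#' @return List with `statistic`, `df`, `p`.
#' @export
waldChi2 <- function(fit, coef = NULL) {
  if (is.null(coef)) {
    return(list(statistic = fit@waldChi2, df = length(fit@coefficients) - 1L,
                p = fit@waldP))
  }
  i <- if (is.character(coef)) match(coef, names(fit@coefficients)) else coef + 1L
  stat <- unname((fit@coefficients[i] / fit@robustSE[i])^2)
  list(statistic = stat, df = 1L, p = pchisq(stat, 1, lower.tail = FALSE))
}

#' Logistic screening of all four outcomes (sub-analysis 1)
#'
#' Fits the inclusion-weighted logit of each outcome on the five contrasts of
#' the pooled feature matrix and tabulates the joint Wald test and McFadden
#' pseudo R-squared.
#'
#' @param fm Pooled feature matrix.
#' @param outcomes Outcomes to screen (default all four).
#' @return List with `table` (data.frame: outcome, n, wald_chi2, p, pseudo_r2)
#'   and `fits` (named list of [LogitFit-class]).
#' @export
runSubhyp1 <- function(fm, outcomes = outcomeNames()) {
  X <- as.matrix(fm[contrastColumns()])
  fits <- list()
  rows <- list()
  for (oc in outcomes) {
    y <- fm[[outcomeColumns()[match(oc, outcomeNames())]]]
    fit <- fitWeightedLogit(X, y, outcome = oc)
    fits[[oc]] <- fit
    rows[[oc]] <- data.frame(outcome = oc, n = fit@nObs,
                             wald_chi2 = fit@waldChi2, p = fit@waldP,
                             pseudo_r2 = fit@pseudoR2)
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))), fits = fits)
}

#' Coefficient table with robust standard errors
#'
#' @param fits Named list of [LogitFit-class] objects (as from [runSubhyp1()]).
#' @return data.frame: outcome, contrast, estimate, robust_se.
#' @export
coefficientTable <- function(fits) {
  do.call(rbind, lapply(names(fits), function(oc) {
    f <- fits[[oc]]
    data.frame(outcome = oc, contrast = contrastNames(),
               estimate = f@coefficients[-1L], robust_se = f@robustSE[-1L],
               row.names = NULL)
  }))
}
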