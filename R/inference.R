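# Posterior summarization (PPI, median-model and Bayesian-FDR selection,
# point and interval estimates) and Monte-Carlo predictive reconstruction of
# cell-level relative expression and spot-level counts.

#' Marginal posterior probability of inclusion
#'
#' `ppi[l] = (1/U) sum_u gamma_l^(u)`: the fraction of retained draws in
#' which covariate l is in the model.
#'
#' @param samples a [PosteriorSamples] object.
#' @return numeric vector in `[0, 1]`, named by covariate.
#' @export
computePPI <- function(samples) {
  if (nDraws(samples) == 0L) stop("no retained draws (U = 0)")
  colMeans(drawMatrix(samples, "gamma"))
}

#' Median-model selection
#'
#' Selects exactly the covariates whose PPI strictly exceeds the threshold
#' (default 0.5, the median model; a PPI of exactly 0.5 is not selected).
#'
#' @param ppi numeric vector of inclusion probabilities.
#' @param threshold selection threshold, default 0.5.
#' @return integer 0/1 vector, named like `ppi`.
#' @export
selectMedianModel <- function(ppi, threshold = 0.5) {
  stopifnot(all(ppi >= 0 & ppi <= 1))
  stats::setNames(as.integer(ppi > threshold), names(ppi))
}

#' Bayesian false discovery rate selection
#'
#' Selects the largest set `{l : ppi[l] >= t*}` where `t*` is the smallest
#' threshold such that the mean posterior exclusion probability
#' `mean(1 - ppi)` over the selected covariates stays at or below `alpha`;
#' the selection is empty when no threshold qualifies.
#'
#' @param ppi numeric vector of inclusion probabilities.
#' @param alpha target expected Bayesian FDR, in (0, 1).
#' @return integer 0/1 vector, named like `ppi`.
#' @export
selectBFDR <- function(ppi, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, all(ppi >= 0 & ppi <= 1))
  sel <- integer(length(ppi))
  names(sel) <- names(ppi)
  ord <- order(ppi, decreasing = TRUE)
  fdr <- cumsum(1 - ppi[ord]) / seq_along(ord)
  k <- which(fdr <= alpha & ppi[ord] > 0)
  if (length(k)) {
    tstar <- ppi[ord][max(k)]
    sel[ppi >= tstar] <- 1L
  }
  sel
}

#' Posterior point estimates and credible intervals
#'
#' Coefficient and dispersion estimates are plain averages over all retained
#' draws; the coefficient draws include the exact zeros of spike states, so
#' the averages are model-averaged (already shrunk) estimates. Intervals are
#' empirical quantiles at the requested level.
#'
#' @param samples a [PosteriorSamples] object.
#' @param level credible level (default 0.95).
#' @return list with `beta0Hat`, `betaHat` (named), `phiHat`, and `ci`, a
#'   data.frame with columns `parameter`, `lower`, `upper`.
#' @export
posteriorEstimates <- function(samples, level = 0.95) {
  if (nDraws(samples) == 0L) stop("no retained draws (U = 0)")
  stopifnot(level > 0, level < 1)
  beta <- drawMatrix(samples, "beta")
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- apply(cbind(`(Intercept)` = samples@beta0, beta,
                    phi = samples@phi), 2L, stats::quantile, probs = probs)
  list(beta0Hat = mean(samples@beta0),
       betaHat = colMeans(beta),
       phiHat = mean(samples@phi),
       ci = data.frame(parameter = colnames(qs),
                       lower = qs[1L, ], upper = qs[2L, ],
                       row.names = NULL))
}

.thetaDrawBlock <- function(X, beta0Block, betaBlock) {
  eta <- X %*% t(betaBlock)
  eta <- sweep(eta, 2L, beta0Block, "+")
  eta[eta > 30] <- 30
  eta[eta < -30] <- -30
  exp(eta)  # M x u block of theta draws
}

#' Posterior-mean cell-level relative expression for one gene
#'
#' `theta_m^(u) = exp(beta0^(u) + sum_l beta_l^(u) x_ml)` per retained draw;
#' the estimate is the draw average, computed for all M cells whether or not
#' a spot covers them. The covariate columns must match the fit (same names
#' and the same standardization).
#'
#' @param X an [ImageProfile] or M-by-L covariate matrix.
#' @param samples a [PosteriorSamples] object.
#' @param chunkSize draws per block (memory control).
#' @return positive numeric vector of length M, named by cell id.
#' @export
predictCellExpression <- function(X, samples, chunkSize = 500L) {
  if (is(X, "ImageProfile")) X <- cellCovariates(X)
  X <- as.matrix(X)
  beta <- drawMatrix(samples, "beta")
  if (ncol(X) != ncol(beta) ||
      (!is.null(colnames(X)) && !is.null(colnames(beta)) &&
       !identical(colnames(X), colnames(beta)))) {
    stop("covariate columns do not match the fitted model")
  }
  U <- nDraws(samples)
  if (U == 0L) stop("no retained draws (U = 0)")
  acc <- numeric(nrow(X))
  for (start in seq(1L, U, by = chunkSize)) {
    idx <- start:min(start + chunkSize - 1L, U)
    acc <- acc + Matrix::rowSums(
      .thetaDrawBlock(X, samples@beta0[idx], beta[idx, , drop = FALSE]))
  }
  stats::setNames(acc / U, rownames(X))
}

#' Monte-Carlo predictive spot counts for one gene
#'
#' Per retained draw, samples `y_i^(u) ~ NB(s_i * lambda_i^(u), phi^(u))`
#' with `lambda_i^(u)` the average of the draw's cell-level theta over the
#' spot's member cells; the reported count is the ceiling of the draw
#' average.
#'
#' @param s positive size factors for the spots to predict.
#' @param G membership for those spots (a [GeospatialProfile], matrix, or
#'   member index list); every spot must cover at least one cell.
#' @param samples a [PosteriorSamples] object.
#' @param X an [ImageProfile] or covariate matrix over all cells indexed by
#'   `G`.
#' @param chunkSize draws per block.
#' @return list with `yHat` (integer, ceiling of the predictive mean),
#'   `muHat` (mean of the NB means `s_i lambda_i^(u)`), and `yMean` (the
#'   predictive mean before the ceiling).
#' @export
predictSpotCounts <- function(s, G, samples, X, chunkSize = 500L) {
  if (is(X, "ImageProfile")) X <- cellCovariates(X)
  X <- as.matrix(X)
  members <- .asMembers(G)
  nPer <- lengths(members)
  if (any(nPer == 0L)) stop("empty spot(s); filter them upstream")
  stopifnot(length(s) == length(members))
  U <- nDraws(samples)
  if (U == 0L) stop("no retained draws (U = 0)")
  beta <- drawMatrix(samples, "beta")
  memIdx <- unlist(members)
  memSpot <- rep.int(seq_along(members), nPer)
  N <- length(members)
  ySum <- numeric(N)
  muSum <- numeric(N)
  for (start in seq(1L, U, by = chunkSize)) {
    idx <- start:min(start + chunkSize - 1L, U)
    th <- .thetaDrawBlock(X[memIdx, , drop = FALSE],
                          samples@beta0[idx], beta[idx, , drop = FALSE])
    lam <- rowsum(th, group = memSpot) / nPer  # N x u spot averages
    mu <- lam * s
    phiDraw <- samples@phi[idx]
    yDraw <- matrix(
      stats::rnbinom(length(mu), size = rep(phiDraw, each = N), mu = mu),
      nrow = N)
    ySum <- ySum + Matrix::rowSums(yDraw)
    muSum <- muSum + Matrix::rowSums(mu)
  }
  list(yHat = as.integer(ceiling(ySum / U)),
       muHat = as.numeric(muSum / U),
       yMean = as.numeric(ySum / U))
}

#' Reconstruct expression for many genes
#'
#' Runs [predictCellExpression()] and [predictSpotCounts()] for every fitted
#' gene. The predictive RNG seed is independent of the fitting seeds and
#' recorded in the result.
#'
#' @param profile the [MolecularProfile] the fits came from (provides spot
#'   ids and, with `sizeFactors = NULL`, the size factors).
#' @param image an [ImageProfile] over all M cells.
#' @param G a [GeospatialProfile] matching `profile`.
#' @param fits named list of [PosteriorSamples] (from [runAllGenes()]).
#' @param sizeFactors optional fixed size factors.
#' @param seed integer seed for the predictive NB sampling.
#' @param spotCountsToo logical; also simulate predictive spot counts.
#' @return a [PredictedExpression] object (genes = the non-failed fits).
#' @export
reconstructExpression <- function(profile, image, G, fits,
                                  sizeFactors = NULL, seed = 1L,
                                  spotCountsToo = TRUE) {
  ok <- !vapply(fits, is.null, logical(1))
  fits <- fits[ok]
  if (!length(fits)) stop("no successful fits supplied")
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(profile)
  members <- spotMembers(G)
  M <- nCells(image)
  theta <- matrix(NA_real_, M, length(fits),
                  dimnames = list(cellIds(image), names(fits)))
  yh <- matrix(NA_integer_, length(members), length(fits),
               dimnames = list(names(members), names(fits)))
  set.seed(seed)
  for (g in names(fits)) {
    theta[, g] <- predictCellExpression(image, fits[[g]])
    if (spotCountsToo) {
      yh[, g] <- predictSpotCounts(sizeFactors, members, fits[[g]], image)$yHat
    }
  }
  if (!spotCountsToo) yh <- matrix(integer(0), 0L, length(fits),
                                   dimnames = list(NULL, names(fits)))
  new("PredictedExpression", thetaHat = theta, yHat = yh,
      drawCount = nDraws(fits[[1L]]))
}

#' Per-gene coefficient summary table
#'
#' One row per gene and covariate with the model-averaged estimate, the PPI,
#' the median-model indicator and the credible interval, in the layout the
#' CLI writes to disk.
#'
#' @param fits named list of [PosteriorSamples].
#' @param level credible level.
#' @param ppiThreshold median-model threshold.
#' @return data.frame with columns `gene`, `covariate`, `beta_hat`, `ppi`,
#'   `gamma_hat`, `ci_lo`, `ci_hi`; the intercept appears as covariate
#'   `(Intercept)` with `ppi = NA` (it is never subject to selection).
#' @export
coefficientTable <- function(fits, level = 0.95, ppiThreshold = 0.5) {
  ok <- !vapply(fits, is.null, logical(1))
  rows <- lapply(names(fits)[ok], function(g) {
    est <- posteriorEstimates(fits[[g]], level = level)
    ppi <- computePPI(fits[[g]])
    ghat <- selectMedianModel(ppi, ppiThreshold)
    ci <- est$ci
    data.frame(gene = g,
               covariate = ci$parameter[ci$parameter != "phi"],
               beta_hat = c(est$beta0Hat, est$betaHat),
               ppi = c(NA_real_, ppi),
               gamma_hat = c(NA_integer_, ghat),
               ci_lo = ci$lower[ci$parameter != "phi"],
               ci_hi = ci$upper[ci$parameter != "phi"],
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Per-gene dispersion summary table
#'
#' @param fits named list of [PosteriorSamples].
#' @param level credible level.
#' @return data.frame with columns `gene`, `phi_hat`, `ci_lo`, `ci_hi`.
#' @export
dispersionTable <- function(fits, level = 0.95) {
  ok <- !vapply(fits, is.null, logical(1))
  rows <- lapply(names(fits)[ok], function(g) {
    est <- posteriorEstimates(fits[[g]], level = level)
    ci <- est$ci[est$ci$parameter == "phi", ]
    data.frame(gene = g, phi_hat = est$phiHat,
               ci_lo = ci$lower, ci_hi = ci$upper, row.names = NULL)
  })
  do.call(rbind, rows)
}
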