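# The probabilistic model for one gene: NB likelihood with a size-factor /
# relative-expression mean decomposition, a log-linear cell-level expression
# model, and the spike-and-slab / gamma priors.

.ETA_CLIP <- 30

#' Construct a per-gene model state
#'
#' The state couples the selection indicators and the coefficients: a
#' coefficient is exactly zero whenever its indicator is zero (the point-mass
#' spike); active coefficients carry the slab.
#'
#' @param beta0 numeric intercept (always in the model).
#' @param beta numeric length-L coefficient vector.
#' @param gamma binary length-L indicator vector; defaults to
#'   `as.integer(beta != 0)`.
#' @param phi positive NB dispersion.
#' @return a validated list with elements `beta0`, `beta`, `gamma`, `phi`.
#' @export
GeneModelState <- function(beta0 = 0, beta = numeric(0),
                           gamma = as.integer(beta != 0), phi = 1) {
  state <- list(beta0 = as.numeric(beta0), beta = as.numeric(beta),
                gamma = as.integer(gamma), phi = as.numeric(phi))
  .checkState(state)
  state
}

.checkState <- function(state) {
  stopifnot(length(state$beta) == length(state$gamma),
            all(state$gamma %in% c(0L, 1L)),
            state$phi > 0)
  if (any(state$beta[state$gamma == 0L] != 0)) {
    stop("state invariant violated: gamma = 0 requires beta = 0")
  }
  invisible(state)
}

#' Negative binomial log pmf (mean/dispersion parameterization)
#'
#' `log f(y | v, phi)` for the NB distribution with mean `v` and dispersion
#' `1/phi`, i.e. variance `v + v^2/phi`. Large `phi` recovers the Poisson.
#'
#' @param y non-negative integer count(s).
#' @param v positive mean(s).
#' @param phi positive dispersion parameter(s).
#' @return numeric log probability mass, finite for all valid inputs.
#' @export
#' @examples
#' nbLogPmf(2, 1, 1)  # log(1/8)
nbLogPmf <- function(y, v, phi) {
  if (any(v <= 0)) stop("v must be positive")
  if (any(phi <= 0)) stop("phi must be positive")
  if (any(y < 0) || any(y != round(y))) stop("y must be non-negative integers")
  stats::dnbinom(y, size = phi, mu = v, log = TRUE)
}

#' Cell-level relative expression under the log-link model
#'
#' `theta = exp(beta0 + sum_l beta_l x_l)`. Linear predictors beyond +/-30
#' are clipped (with a warning) as a pure overflow guard; the region is
#' unreachable for standardized covariates under a unit slab variance.
#'
#' @param x a covariate row (length L), an M-by-L matrix, or an
#'   [ImageProfile].
#' @param state a [GeneModelState()] list.
#' @return positive numeric vector of relative expression values.
#' @export
cellRelativeExpression <- function(x, state) {
  if (is(x, "ImageProfile")) x <- cellCovariates(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  stopifnot(ncol(x) == length(state$beta))
  eta <- as.numeric(state$beta0 + x %*% state$beta)
  if (any(abs(eta) > .ETA_CLIP)) {
    warning("linear predictor clipped at +/-", .ETA_CLIP)
    eta <- pmin(pmax(eta, -.ETA_CLIP), .ETA_CLIP)
  }
  exp(eta)
}

#' Spot-level relative expression as a cell average
#'
#' `lambda_i = sum_m g_im theta_m / sum_m g_im`: the spot's relative
#' expression is the plain average of the relative expression of the cells it
#' covers.
#'
#' @param thetaCells positive numeric vector over all M cells.
#' @param membershipRow binary vector of length M (one spot's row of G).
#' @return positive scalar.
#' @export
spotRelativeExpression <- function(thetaCells, membershipRow) {
  membershipRow <- as.numeric(membershipRow)
  n <- sum(membershipRow)
  if (n < 1) stop("spot covers no cells; filter empty spots upstream")
  sum(membershipRow * thetaCells) / n
}

.asMembers <- function(G, M = NULL) {
  if (is(G, "GeospatialProfile")) return(spotMembers(G))
  if (is.list(G)) return(lapply(G, as.integer))
  # plain binary matrix, spots x cells
  apply(as.matrix(G) != 0, 1L, which, simplify = FALSE)
}

#' Per-gene log likelihood
#'
#' Sum over spots of the NB log pmf at mean `s_i * lambda_i`, with
#' `lambda_i` from [spotRelativeExpression()] and theta from
#' [cellRelativeExpression()].
#'
#' @param yGene non-negative integer counts, length N.
#' @param s positive size factors, length N.
#' @param G a [GeospatialProfile], binary matrix, or list of member index
#'   vectors per spot.
#' @param X cell covariate matrix (M by L) or [ImageProfile].
#' @param state a [GeneModelState()] list.
#' @return finite numeric scalar.
#' @export
geneLogLikelihood <- function(yGene, s, G, X, state) {
  if (is(X, "ImageProfile")) X <- cellCovariates(X)
  members <- .asMembers(G)
  stopifnot(length(yGene) == length(members), length(s) == length(yGene))
  nPer <- lengths(members)
  if (any(nPer == 0L)) {
    stop("empty spot(s) at index ", paste(which(nPer == 0L), collapse = ", "),
         "; filter them upstream")
  }
  theta <- cellRelativeExpression(X, state)
  lam <- vapply(members, function(m) mean(theta[m]), numeric(1))
  sum(nbLogPmf(yGene, s * lam, state$phi))
}

#' Log prior density of a per-gene model state
#'
#' Sum of the gamma kernel on the dispersion (`(aPhi - 1) log phi - bPhi phi`,
#' up to a constant), the normal slab log density of the intercept and of
#' every active coefficient (spike states contribute zero), and the Bernoulli
#' log mass of the selection indicators.
#'
#' @param state a [GeneModelState()] list.
#' @param hp a [Hyperparameters()] object.
#' @return numeric scalar (up to the constant of the gamma kernel).
#' @export
logPrior <- function(state, hp) {
  .checkState(state)
  sb <- sqrt(hp@sigmaBetaSq)
  phiTerm <- (hp@aPhi - 1) * log(state$phi) - hp@bPhi * state$phi
  active <- state$gamma == 1L
  slabTerm <- stats::dnorm(state$beta0, 0, sb, log = TRUE) +
    sum(stats::dnorm(state$beta[active], 0, sb, log = TRUE))
  bernTerm <- sum(state$gamma) * log(hp@piGamma) +
    sum(1L - state$gamma) * log(1 - hp@piGamma)
  phiTerm + slabTerm + bernTerm
}
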