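# Model-matched synthetic SRT data: Visium-like lattice geometry, a paired
# cell cloud with cell-type and standardized shape covariates (including an
# `orientation` pure-noise negative control), sparse true coefficients, and
# NB counts with product-one size factors. Ground truth is returned for
# validation.

.SHAPE_FEATURES <- c("filled_area", "net_area", "convex_area", "extent",
                     "perimeter", "solidity", "eccentricity",
                     "major_axis_length", "minor_axis_length", "orientation")

#' Column name of the built-in pure-noise covariate
#'
#' The continuous covariate named `orientation` mimics a nuclear-orientation
#' measurement: it depends only on how the tissue lies on the slide, so its
#' true coefficient is zero for every gene and it serves as a negative
#' control for the selection machinery.
#'
#' @return character scalar `"orientation"`.
#' @export
noiseControlCovariate <- function() "orientation"

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate spot lattice and paired cell cloud
#'
#' Spots sit on a regular lattice with spacing exceeding the diameter (so
#' spots never overlap). Each spot receives a Poisson number of cells
#' (resampled to at least one) placed uniformly in its disc; an additional
#' `uncoveredCellFrac` fraction of all cells is placed in the gaps between
#' spots.
#'
#' @param config a [SimulationConfig()].
#' @return list with `spotCoords`, `cellCoords`, `geospatial` (a
#'   [GeospatialProfile]), `spotIds`, `cellIds`, and `coveredSpotOfCell`
#'   (integer, NA for uncovered cells). Uses the current RNG state; seed
#'   under the caller's control (see [simulateDataset()]).
#' @export
simulateGeometry <- function(config) {
  validObject(config)
  N <- config@nSpots
  rows <- config@gridShape[1L]
  cols <- config@gridShape[2L]
  idx <- seq_len(N) - 1L
  spotCoords <- cbind(x = (idx %% cols) * config@spotSpacing,
                      y = (idx %/% cols) * config@spotSpacing)
  spotIds <- sprintf("spot_%04d", seq_len(N))
  rownames(spotCoords) <- spotIds

  k <- stats::rpois(N, config@cellsPerSpotMean)
  while (any(k < 1)) k[k < 1] <- stats::rpois(sum(k < 1),
                                              config@cellsPerSpotMean)
  nCov <- sum(k)
  spotOf <- rep.int(seq_len(N), k)
  r <- (config@spotDiameter / 2) * sqrt(stats::runif(nCov))
  ang <- stats::runif(nCov, 0, 2 * pi)
  covCoords <- cbind(spotCoords[spotOf, 1L] + r * cos(ang),
                     spotCoords[spotOf, 2L] + r * sin(ang))

  f <- config@uncoveredCellFrac
  nUnc <- round(f / (1 - f) * nCov)
  uncCoords <- matrix(numeric(0), 0L, 2L)
  if (nUnc > 0) {
    lo <- c(min(spotCoords[, 1L]), min(spotCoords[, 2L])) -
      config@spotSpacing / 2
    hi <- c(max(spotCoords[, 1L]), max(spotCoords[, 2L])) +
      config@spotSpacing / 2
    pts <- matrix(numeric(0), 0L, 2L)
    r2 <- (config@spotDiameter / 2)^2
    while (nrow(pts) < nUnc) {
      cand <- cbind(stats::runif(2L * nUnc, lo[1L], hi[1L]),
                    stats::runif(2L * nUnc, lo[2L], hi[2L]))
      # distance to the nearest lattice center (lattice is regular)
      cx <- pmin(pmax(round(cand[, 1L] / config@spotSpacing), 0), cols - 1L)
      cy <- pmin(pmax(round(cand[, 2L] / config@spotSpacing), 0), rows - 1L)
      nearest <- cy * cols + cx + 1L
      inGrid <- nearest <= N
      d2 <- rep(Inf, nrow(cand))
      d2[inGrid] <- (cand[inGrid, 1L] - spotCoords[nearest[inGrid], 1L])^2 +
        (cand[inGrid, 2L] - spotCoords[nearest[inGrid], 2L])^2
      pts <- rbind(pts, cand[d2 > r2 + 1e-9, , drop = FALSE])
    }
    uncCoords <- pts[seq_len(nUnc), , drop = FALSE]
  }

  cellCoords <- rbind(covCoords, uncCoords)
  M <- nrow(cellCoords)
  cellIds <- sprintf("cell_%05d", seq_len(M))
  rownames(cellCoords) <- cellIds
  G <- Matrix::sparseMatrix(i = spotOf, j = seq_len(nCov), x = 1,
                            dims = c(N, M),
                            dimnames = list(spotIds, cellIds))
  list(spotCoords = spotCoords, cellCoords = cellCoords,
       geospatial = GeospatialProfile(G), spotIds = spotIds,
       cellIds = cellIds,
       coveredSpotOfCell = c(spotOf, rep(NA_integer_, nUnc)))
}

#' Simulate per-cell covariates
#'
#' Cell types are drawn from per-spot Dirichlet-perturbed categorical
#' distributions (each spot gets its own type weights, giving the spatial
#' clumping of real tissue; uncovered cells inherit the weights of the
#' nearest spot). Shape features are standard normal (i.e. already
#' standardized), one of which is the `orientation` pure-noise negative
#' control.
#'
#' @param config a [SimulationConfig()].
#' @param geometry output of [simulateGeometry()].
#' @return an [ImageProfile].
#' @export
simulateCovariates <- function(config, geometry) {
  Q <- config@nCelltypes
  M <- nrow(geometry$cellCoords)
  N <- nrow(geometry$spotCoords)
  spotProbs <- do.call(rbind, lapply(seq_len(N), function(i) {
    .rdirichlet1(rep(1, Q))
  }))
  spotOf <- geometry$coveredSpotOfCell
  if (anyNA(spotOf)) {
    unc <- which(is.na(spotOf))
    d2 <- function(p) {
      (geometry$spotCoords[, 1L] - p[1L])^2 +
        (geometry$spotCoords[, 2L] - p[2L])^2
    }
    spotOf[unc] <- vapply(unc, function(m) {
      which.min(d2(geometry$cellCoords[m, ]))
    }, integer(1))
  }
  type <- vapply(seq_len(M), function(m) {
    sample.int(Q, 1L, prob = spotProbs[spotOf[m], ])
  }, integer(1))
  labels <- sprintf("type_%02d", seq_len(Q))
  dummies <- matrix(0, M, Q, dimnames = list(NULL, paste0("celltype_",
                                                          labels)))
  dummies[cbind(seq_len(M), type)] <- 1
  nShape <- config@nShapeFeatures
  shapeNames <- if (nShape <= length(.SHAPE_FEATURES)) {
    .SHAPE_FEATURES[seq_len(nShape)]
  } else {
    c(.SHAPE_FEATURES,
      paste0("shape_", seq_len(nShape - length(.SHAPE_FEATURES))))
  }
  shapes <- matrix(stats::rnorm(M * nShape), M, nShape,
                   dimnames = list(NULL, shapeNames))
  X <- cbind(dummies, shapes)
  rownames(X) <- geometry$cellIds
  ImageProfile(X, geometry$cellCoords,
               celltypeColumns = seq_len(Q),
               continuousColumns = Q + seq_len(nShape),
               standardization = list(applied = FALSE))
}

#' Simulate sparse true coefficients and dispersions
#'
#' Per gene, each selectable coefficient is zero with probability
#' `zeroFrac`, otherwise `Norm(0, betaSd^2)`; the non-zero cell-type block is
#' re-centered to sum to zero; the noise-control (`orientation`) coefficient
#' is forced to zero for every gene; intercepts are standard normal and
#' dispersions uniform on `phiRange`. The returned `gammaTrue` is exactly
#' the indicator of a non-zero coefficient (re-centering a single active
#' cell-type coefficient drives it to zero, in which case its indicator is
#' zero too).
#'
#' @param config a [SimulationConfig()].
#' @param image an [ImageProfile] providing covariate names and the
#'   cell-type block.
#' @return list with `beta0True` (length P), `betaTrue` (L-by-P),
#'   `gammaTrue` (L-by-P binary), `phiTrue` (length P).
#' @export
simulateCoefficients <- function(config, image) {
  L <- length(covariateNames(image))
  P <- config@nGenes
  ct <- celltypeColumns(image)
  noise <- which(covariateNames(image) == noiseControlCovariate())
  beta <- matrix(0, L, P, dimnames = list(covariateNames(image),
                                          sprintf("gene_%03d", seq_len(P))))
  for (j in seq_len(P)) {
    nz <- stats::runif(L) >= config@zeroFrac
    b <- ifelse(nz, stats::rnorm(L, 0, config@betaSd), 0)
    act <- intersect(which(b != 0), ct)
    if (length(act)) b[act] <- b[act] - mean(b[act])
    if (length(noise)) b[noise] <- 0
    beta[, j] <- b
  }
  gamma <- (beta != 0) * 1L
  storage.mode(gamma) <- "integer"
  list(beta0True = stats::rnorm(P),
       betaTrue = beta, gammaTrue = gamma,
       phiTrue = stats::runif(P, config@phiRange[1L], config@phiRange[2L]))
}

#' Simulate expression and counts under the model
#'
#' Cell-level relative expression through the log link, spot-level relative
#' expression by averaging over each spot's member cells, lognormal size
#' factors renormalized to product one, and NB counts
#' `y_ij ~ NB(s_i lambda_ij, phi_j)`.
#'
#' @param geometry output of [simulateGeometry()].
#' @param image an [ImageProfile].
#' @param truth output of [simulateCoefficients()].
#' @param config a [SimulationConfig()].
#' @return list with `molecular` (a [MolecularProfile]), `sizeFactors`, and
#'   `truth` extended with `thetaTrue` (M-by-P) and `constantGenes`
#'   (logical: genes whose true theta is constant across cells, excluded
#'   from correlation metrics).
#' @export
simulateExpressionAndCounts <- function(geometry, image, truth, config) {
  X <- cellCovariates(image)
  eta <- sweep(X %*% truth$betaTrue, 2L, truth$beta0True, "+")
  eta[eta > 30] <- 30
  eta[eta < -30] <- -30
  theta <- exp(eta)
  members <- spotMembers(geometry$geospatial)
  N <- length(members)
  lam <- do.call(rbind, lapply(members, function(m) {
    colMeans(theta[m, , drop = FALSE])
  }))
  sRaw <- exp(stats::rnorm(N, 0, config@sizeFactorSdLog))
  s <- sRaw / exp(mean(log(sRaw)))
  mu <- lam * s
  P <- config@nGenes
  y <- matrix(stats::rnbinom(N * P, size = rep(truth$phiTrue, each = N),
                             mu = mu), N, P,
              dimnames = list(geometry$spotIds, colnames(truth$betaTrue)))
  molecular <- MolecularProfile(y, geometry$spotCoords, config@spotDiameter)
  truth$thetaTrue <- theta
  truth$constantGenes <- apply(theta, 2L, function(v) diff(range(v)) == 0)
  list(molecular = molecular, sizeFactors = stats::setNames(s,
                                                            geometry$spotIds),
       truth = truth)
}

#' Generate a complete model-matched synthetic dataset
#'
#' Runs the geometry, covariate, coefficient and count generators under a
#' single seed.
#'
#' @param config a [SimulationConfig()].
#' @return list with `molecular`, `image`, `geospatial`, `sizeFactors`,
#'   `truth`, `config`.
#' @export
#' @examples
#' sim <- simulateDataset(SimulationConfig(nSpots = 20L, nGenes = 3L,
#'                                         seed = 7L))
#' sim$molecular
simulateDataset <- function(config = SimulationConfig()) {
  validObject(config)
  set.seed(config@seed)
  geometry <- simulateGeometry(config)
  image <- simulateCovariates(config, geometry)
  coefs <- simulateCoefficients(config, image)
  out <- simulateExpressionAndCounts(geometry, image, coefs, config)
  list(molecular = out$molecular, image = image,
       geospatial = geometry$geospatial, sizeFactors = out$sizeFactors,
       truth = out$truth, config = config)
}

.configAsList <- function(config) {
  nm <- slotNames(class(config))
  stats::setNames(lapply(nm, function(x) slot(config, x)), nm)
}

#' Write a synthetic dataset as a fixture directory
#'
#' Emits the counts (MTX + barcode/feature lists), positions CSV, scale
#' factors JSON, cell table CSV, plain-CSV ground truth
#' (`truth_beta.csv`, `truth_gamma.csv`, `truth_phi.csv`,
#' `truth_theta.csv`) and a config echo JSON. A single seed controls the
#' whole directory, so identical configs give identical files.
#'
#' @param sim output of [simulateDataset()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writeSimulatedDataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeProfiles(sim$molecular, sim$image, dir)
  tr <- sim$truth
  utils::write.csv(
    data.frame(covariate = c("(Intercept)", rownames(tr$betaTrue)),
               rbind(tr$beta0True, tr$betaTrue), check.names = FALSE),
    file.path(dir, "truth_beta.csv"), row.names = FALSE)
  utils::write.csv(data.frame(covariate = rownames(tr$gammaTrue),
                              tr$gammaTrue, check.names = FALSE),
                   file.path(dir, "truth_gamma.csv"), row.names = FALSE)
  utils::write.csv(data.frame(gene = colnames(tr$betaTrue),
                              phi = tr$phiTrue),
                   file.path(dir, "truth_phi.csv"), row.names = FALSE)
  utils::write.csv(data.frame(cell_id = rownames(tr$thetaTrue),
                              tr$thetaTrue, check.names = FALSE),
                   file.path(dir, "truth_theta.csv"), row.names = FALSE)
  cfg <- .configAsList(sim$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
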