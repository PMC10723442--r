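# ---------------------------------------------------------------------------
# MolecularProfile
# ---------------------------------------------------------------------------

#' MolecularProfile: spot-resolution counts with spot geometry
#'
#' Container for the spot-resolution molecular profile of an NGS-based SRT
#' experiment: an integer count matrix over N spots and P genes, the pixel
#' coordinates of the spot centers, and the spot diameter (pixels). Internally
#' a [SummarizedExperiment::SummarizedExperiment] with genes as rows and spots
#' as columns; [spotCounts()] returns the spots-by-genes orientation used in
#' the model formulas.
#'
#' @param counts spots-by-genes matrix (base or sparse) of non-negative
#'   integer read counts.
#' @param spotCoords N-by-2 numeric matrix of spot-center pixel coordinates
#'   (x, y).
#' @param spotDiameter positive scalar, spot diameter in pixels.
#' @param spotIds,geneIds optional character vectors; default to the dimnames
#'   of `counts`.
#' @return a `MolecularProfile` object.
#' @export
#' @examples
#' mp <- MolecularProfile(matrix(1:4, 2, 2), cbind(c(0, 100), c(0, 0)), 55)
#' spotCounts(mp)
setClass("MolecularProfile", contains = "SummarizedExperiment")

setValidity("MolecularProfile", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object)) {
    return("assay 'counts' is required")
  }
  cnt <- assay(object, "counts")
  vals <- if (inherits(cnt, "sparseMatrix")) cnt@x else as.numeric(cnt)
  if (length(vals)) {
    if (anyNA(vals) || min(vals) < 0 || any(abs(vals - round(vals)) > 1e-8)) {
      msg <- c(msg, "counts must be non-negative integers")
    }
  }
  if (is.null(colnames(object)) || is.null(rownames(object))) {
    msg <- c(msg, "spot and gene ids are required")
  } else {
    if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicated spot ids")
    if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicated gene ids")
  }
  cd <- colData(object)
  if (!all(c("pxl_x", "pxl_y") %in% colnames(cd))) {
    msg <- c(msg, "colData must contain spot coordinates pxl_x, pxl_y")
  }
  d <- metadata(object)$spot_diameter
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0) {
    msg <- c(msg, "spot_diameter must be a positive scalar")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname MolecularProfile-class
#' @aliases MolecularProfile
#' @export
MolecularProfile <- function(counts, spotCoords, spotDiameter,
                             spotIds = rownames(counts),
                             geneIds = colnames(counts)) {
  if (is.null(spotIds)) spotIds <- paste0("spot_", seq_len(nrow(counts)))
  if (is.null(geneIds)) geneIds <- paste0("gene_", seq_len(ncol(counts)))
  spotCoords <- as.matrix(spotCoords)
  if (nrow(spotCoords) != nrow(counts) || ncol(spotCoords) != 2L) {
    stop("spotCoords must be an N-by-2 matrix matching nrow(counts)")
  }
  cnt <- Matrix::t(if (inherits(counts, "sparseMatrix")) counts else
    as.matrix(counts))
  dimnames(cnt) <- list(geneIds, spotIds)
  se <- SummarizedExperiment(
    assays = list(counts = cnt),
    colData = DataFrame(pxl_x = spotCoords[, 1L], pxl_y = spotCoords[, 2L],
                        row.names = spotIds),
    metadata = list(spot_diameter = as.numeric(spotDiameter))
  )
  new("MolecularProfile", se)
}

#' @rdname SpotRecon-generics
#' @export
setMethod("spotCounts", "MolecularProfile", function(x) {
  Matrix::t(assay(x, "counts"))
})

#' @rdname SpotRecon-generics
#' @export
setMethod("spotCoords", "MolecularProfile", function(x) {
  cd <- colData(x)
  m <- cbind(x = cd$pxl_x, y = cd$pxl_y)
  rownames(m) <- colnames(x)
  m
})

#' @rdname SpotRecon-generics
#' @export
setMethod("spotDiameter", "MolecularProfile", function(x) {
  metadata(x)$spot_diameter
})

#' @rdname SpotRecon-generics
#' @export
setMethod("spotIds", "MolecularProfile", function(x) colnames(x))

#' @rdname SpotRecon-generics
#' @export
setMethod("geneIds", "MolecularProfile", function(x) rownames(x))

#' @rdname SpotRecon-generics
#' @export
setMethod("nSpots", "MolecularProfile", function(x) ncol(x))

#' @rdname SpotRecon-generics
#' @export
setMethod("nGenes", "MolecularProfile", function(x) nrow(x))

setMethod("show", "MolecularProfile", function(object) {
  cat("MolecularProfile:", ncol(object), "spots x", nrow(object), "genes\n")
  cat("  spot diameter:", metadata(object)$spot_diameter, "px\n")
  cat("  total counts:", sum(assay(object, "counts")), "\n")
})

#' Subset a MolecularProfile by spots and/or genes
#'
#' @param x a `MolecularProfile`
#' @param spots,genes index vectors (integer, logical or character ids)
#' @return the subsetted `MolecularProfile`
#' @export
subsetProfile <- function(x, spots = NULL, genes = NULL) {
  stopifnot(is(x, "MolecularProfile"))
  if (!is.null(genes)) x <- x[genes, ]
  if (!is.null(spots)) x <- x[, spots]
  x
}

# ---------------------------------------------------------------------------
# ImageProfile
# ---------------------------------------------------------------------------

#' ImageProfile: per-cell design matrix from the paired histology image
#'
#' Holds the M-by-L design matrix of per-cell covariates (Q one-hot cell-type
#' dummies plus continuous nuclei-shape features), the pixel coordinates of
#' each cell, and the standardization applied to the continuous columns (so
#' that the identical transform is reused at prediction time).
#'
#' @slot covariates M-by-L numeric matrix; rownames are cell ids, colnames
#'   covariate names.
#' @slot cellCoords M-by-2 numeric matrix of cell pixel coordinates.
#' @slot celltypeColumns integer indices of the one-hot cell-type columns.
#' @slot continuousColumns integer indices of the continuous columns.
#' @slot standardization list with elements `applied` (logical), `center`,
#'   `scale` (named numeric over continuous columns).
#' @export
setClass("ImageProfile", representation(
  covariates = "matrix",
  cellCoords = "matrix",
  celltypeColumns = "integer",
  continuousColumns = "integer",
  standardization = "list"
))

setValidity("ImageProfile", function(object) {
  msg <- character()
  X <- object@covariates
  if (is.null(rownames(X)) || is.null(colnames(X))) {
    msg <- c(msg, "covariates must have cell ids (rownames) and covariate names (colnames)")
  } else if (anyDuplicated(rownames(X))) {
    msg <- c(msg, "duplicated cell ids")
  }
  ct <- object@celltypeColumns
  cc <- object@continuousColumns
  if (length(intersect(ct, cc))) {
    msg <- c(msg, "celltypeColumns and continuousColumns must be disjoint")
  }
  if (!setequal(c(ct, cc), seq_len(ncol(X)))) {
    msg <- c(msg, "celltypeColumns and continuousColumns must cover all columns")
  }
  if (length(ct)) {
    dummies <- X[, ct, drop = FALSE]
    onehot <- all(dummies %in% c(0, 1)) &&
      all(abs(Matrix::rowSums(dummies) - 1) < 1e-12)
    if (!onehot) msg <- c(msg, "cell-type columns must be one-hot per row")
  }
  if (nrow(object@cellCoords) != nrow(X) || ncol(object@cellCoords) != 2L) {
    msg <- c(msg, "cellCoords must be M-by-2")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname ImageProfile-class
#' @aliases ImageProfile
#' @param covariates,cellCoords,celltypeColumns,continuousColumns,standardization
#'   see slot descriptions.
#' @return an `ImageProfile` object.
#' @export
ImageProfile <- function(covariates, cellCoords,
                         celltypeColumns = integer(0),
                         continuousColumns = setdiff(seq_len(ncol(covariates)),
                                                     celltypeColumns),
                         standardization = list(applied = FALSE)) {
  covariates <- as.matrix(covariates)
  if (is.null(rownames(covariates))) {
    rownames(covariates) <- paste0("cell_", seq_len(nrow(covariates)))
  }
  if (is.null(colnames(covariates))) {
    colnames(covariates) <- paste0("cov_", seq_len(ncol(covariates)))
  }
  cellCoords <- as.matrix(cellCoords)
  rownames(cellCoords) <- rownames(covariates)
  new("ImageProfile", covariates = covariates, cellCoords = cellCoords,
      celltypeColumns = as.integer(celltypeColumns),
      continuousColumns = as.integer(continuousColumns),
      standardization = standardization)
}

#' @rdname SpotRecon-generics
#' @export
setMethod("cellCovariates", "ImageProfile", function(x) x@covariates)

#' @rdname SpotRecon-generics
#' @export
setMethod("cellCoords", "ImageProfile", function(x) x@cellCoords)

#' @rdname SpotRecon-generics
#' @export
setMethod("cellIds", "ImageProfile", function(x) rownames(x@covariates))

#' @rdname SpotRecon-generics
#' @export
setMethod("covariateNames", "ImageProfile", function(x) colnames(x@covariates))

#' @rdname SpotRecon-generics
#' @export
setMethod("celltypeColumns", "ImageProfile", function(x) x@celltypeColumns)

#' @rdname SpotRecon-generics
#' @export
setMethod("continuousColumns", "ImageProfile", function(x) x@continuousColumns)

#' @rdname SpotRecon-generics
#' @export
setMethod("nCells", "ImageProfile", function(x) nrow(x@covariates))

setMethod("show", "ImageProfile", function(object) {
  cat("ImageProfile:", nrow(object@covariates), "cells x",
      ncol(object@covariates), "covariates\n")
  cat("  cell-type dummies:", length(object@celltypeColumns),
      "| continuous:", length(object@continuousColumns), "\n")
  cat("  continuous columns standardized:",
      isTRUE(object@standardization$applied), "\n")
})

# ---------------------------------------------------------------------------
# GeospatialProfile
# ---------------------------------------------------------------------------

#' GeospatialProfile: sparse spot-by-cell membership
#'
#' Binary N-by-M matrix G with `g[i, m] = 1` when cell m lies within the
#' barcoded disc of spot i (distance to the spot center at most half the spot
#' diameter, boundary inclusive).
#'
#' @slot membership sparse binary `dgCMatrix`, spots in rows, cells in
#'   columns, with dimnames.
#' @export
setClass("GeospatialProfile", representation(membership = "dgCMatrix"))

setValidity("GeospatialProfile", function(object) {
  msg <- character()
  G <- object@membership
  if (length(G@x) && !all(G@x %in% c(0, 1))) {
    msg <- c(msg, "membership entries must be 0 or 1")
  }
  if (is.null(rownames(G)) || is.null(colnames(G))) {
    msg <- c(msg, "membership must carry spot ids (rows) and cell ids (columns)")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname GeospatialProfile-class
#' @aliases GeospatialProfile
#' @param membership binary matrix (sparse or dense), spots by cells, with
#'   dimnames.
#' @return a `GeospatialProfile` object.
#' @export
GeospatialProfile <- function(membership) {
  G <- as(as(as(membership, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  G <- drop0(G)
  new("GeospatialProfile", membership = G)
}

#' @rdname SpotRecon-generics
#' @export
setMethod("membership", "GeospatialProfile", function(x) x@membership)

#' @rdname SpotRecon-generics
#' @export
setMethod("cellsPerSpot", "GeospatialProfile", function(x) {
  stats::setNames(as.integer(Matrix::rowSums(x@membership)),
                  rownames(x@membership))
})

#' @rdname SpotRecon-generics
#' @export
setMethod("uncoveredCells", "GeospatialProfile", function(x) {
  which(Matrix::colSums(x@membership) == 0)
})

#' @rdname SpotRecon-generics
#' @export
setMethod("spotMembers", "GeospatialProfile", function(x) {
  Gt <- Matrix::t(x@membership)  # cells x spots, column-compressed by spot
  n <- ncol(Gt)
  out <- vector("list", n)
  p <- Gt@p
  for (i in seq_len(n)) {
    out[[i]] <- Gt@i[seq.int(p[i] + 1L, length.out = p[i + 1L] - p[i])] + 1L
  }
  names(out) <- colnames(Gt)
  out
})

#' @rdname SpotRecon-generics
#' @export
setMethod("nSpots", "GeospatialProfile", function(x) nrow(x@membership))

#' @rdname SpotRecon-generics
#' @export
setMethod("nCells", "GeospatialProfile", function(x) ncol(x@membership))

setMethod("show", "GeospatialProfile", function(object) {
  G <- object@membership
  cps <- Matrix::rowSums(G)
  cat("GeospatialProfile:", nrow(G), "spots x", ncol(G), "cells\n")
  cat("  uncovered cells:", sum(Matrix::colSums(G) == 0),
      "| mean cells/spot:", round(mean(cps), 2), "\n")
})

#' Subset a GeospatialProfile
#'
#' @param x a `GeospatialProfile`
#' @param spots,cells index vectors (integer, logical or character)
#' @return the subsetted `GeospatialProfile`
#' @export
subsetGeospatial <- function(x, spots = NULL, cells = NULL) {
  G <- membership(x)
  if (!is.null(spots)) G <- G[spots, , drop = FALSE]
  if (!is.null(cells)) G <- G[, cells, drop = FALSE]
  GeospatialProfile(G)
}

# ---------------------------------------------------------------------------
# Hyperparameters / SamplerConfig
# ---------------------------------------------------------------------------

#' Model hyperparameters
#'
#' Fixed hyperparameters of the hierarchical model: the gamma prior
#' `Ga(aPhi, bPhi)` on the NB dispersion, the slab variance `sigmaBetaSq` of
#' the normal component of the spike-and-slab prior, and the prior inclusion
#' probability `piGamma` of the Bernoulli prior on the selection indicators.
#' Defaults are the weakly informative setting `aPhi = bPhi = 0.1`,
#' `sigmaBetaSq = 1`, `piGamma = 0.5`.
#'
#' @param aPhi,bPhi,sigmaBetaSq,piGamma numeric scalars.
#' @return a `Hyperparameters` object.
#' @export
setClass("Hyperparameters", representation(
  aPhi = "numeric", bPhi = "numeric",
  sigmaBetaSq = "numeric", piGamma = "numeric"
), prototype(aPhi = 0.1, bPhi = 0.1, sigmaBetaSq = 1, piGamma = 0.5))

setValidity("Hyperparameters", function(object) {
  ok1 <- all(vapply(list(object@aPhi, object@bPhi, object@sigmaBetaSq),
                    function(v) is.numeric(v) && length(v) == 1L &&
                      is.finite(v) && v > 0, logical(1)))
  ok2 <- is.numeric(object@piGamma) && length(object@piGamma) == 1L &&
    object@piGamma > 0 && object@piGamma < 1
  if (!ok1) return("aPhi, bPhi and sigmaBetaSq must be positive scalars")
  if (!ok2) return("piGamma must lie strictly inside (0, 1)")
  TRUE
})

#' @rdname Hyperparameters-class
#' @aliases Hyperparameters
#' @export
Hyperparameters <- function(aPhi = 0.1, bPhi = 0.1, sigmaBetaSq = 1,
                            piGamma = 0.5) {
  new("Hyperparameters", aPhi = aPhi, bPhi = bPhi,
      sigmaBetaSq = sigmaBetaSq, piGamma = piGamma)
}

#' MCMC sampler configuration
#'
#' Chain length and proposal scales for the per-gene Metropolis-Hastings /
#' SSVS sampler. `regularize = FALSE` fixes all selection indicators to one
#' (slab-only fit, i.e. a plain normal prior on every coefficient).
#' `updatePhi = FALSE` holds the dispersion fixed at `phiInit`, and
#' `priorOnly = TRUE` disables the likelihood term (both are diagnostic
#' switches used by the correctness oracles).
#'
#' @param nIter,nBurn,thin integers: total iterations, burn-in, thinning.
#' @param seed integer seed for the chain.
#' @param phiProposalSd random-walk sd on log(phi).
#' @param betaProposalSd within-model random-walk sd on active coefficients.
#' @param regularize,updatePhi,priorOnly logical switches (see above).
#' @param phiInit initial (or fixed) dispersion value.
#' @return a `SamplerConfig` object.
#' @export
setClass("SamplerConfig", representation(
  nIter = "integer", nBurn = "integer", thin = "integer", seed = "integer",
  phiProposalSd = "numeric", betaProposalSd = "numeric",
  regularize = "logical", updatePhi = "logical", priorOnly = "logical",
  phiInit = "numeric"
), prototype(nIter = 10000L, nBurn = 5000L, thin = 1L, seed = 1L,
             phiProposalSd = 0.2, betaProposalSd = 0.1,
             regularize = TRUE, updatePhi = TRUE, priorOnly = FALSE,
             phiInit = 1))

setValidity("SamplerConfig", function(object) {
  msg <- character()
  if (object@nIter < 1L) msg <- c(msg, "nIter must be positive")
  if (object@nBurn < 0L || object@nBurn > object@nIter) {
    msg <- c(msg, "nBurn must satisfy 0 <= nBurn <= nIter")
  }
  if (object@thin < 1L) msg <- c(msg, "thin must be a positive integer")
  if (object@phiProposalSd <= 0 || object@betaProposalSd <= 0) {
    msg <- c(msg, "proposal sds must be positive")
  }
  if (object@phiInit <= 0) msg <- c(msg, "phiInit must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname SamplerConfig-class
#' @aliases SamplerConfig
#' @export
SamplerConfig <- function(nIter = 10000L, nBurn = 5000L, thin = 1L, seed = 1L,
                          phiProposalSd = 0.2, betaProposalSd = 0.1,
                          regularize = TRUE, updatePhi = TRUE,
                          priorOnly = FALSE, phiInit = 1) {
  new("SamplerConfig", nIter = as.integer(nIter), nBurn = as.integer(nBurn),
      thin = as.integer(thin), seed = as.integer(seed),
      phiProposalSd = phiProposalSd, betaProposalSd = betaProposalSd,
      regularize = regularize, updatePhi = updatePhi, priorOnly = priorOnly,
      phiInit = phiInit)
}

# ---------------------------------------------------------------------------
# PosteriorSamples
# ---------------------------------------------------------------------------

#' PosteriorSamples: retained MCMC draws for one gene
#'
#' Post-burn-in, thinned draws of the intercept, the L covariate coefficients,
#' the selection indicators and the dispersion for a single gene, together
#' with the seed and a config echo sufficient to reproduce the chain.
#'
#' @slot beta0 numeric vector, length U.
#' @slot beta U-by-L numeric matrix (colnames are covariate names).
#' @slot gamma U-by-L binary integer matrix.
#' @slot phi positive numeric vector, length U.
#' @slot geneId character scalar.
#' @slot seed integer seed the chain was run with.
#' @slot config list echo of the sampler configuration.
#' @slot diagnostics list of acceptance rates.
#' @export
setClass("PosteriorSamples", representation(
  beta0 = "numeric", beta = "matrix", gamma = "matrix", phi = "numeric",
  geneId = "character", seed = "integer", config = "list",
  diagnostics = "list"
))

setValidity("PosteriorSamples", function(object) {
  msg <- character()
  U <- length(object@beta0)
  if (nrow(object@beta) != U || nrow(object@gamma) != U ||
      length(object@phi) != U) {
    msg <- c(msg, "draw counts of beta0, beta, gamma, phi must agree")
  }
  if (!all(object@gamma %in% c(0L, 1L))) {
    msg <- c(msg, "gamma draws must be binary")
  }
  if (any(object@beta[object@gamma == 0L] != 0)) {
    msg <- c(msg, "spike states must have exactly zero coefficients")
  }
  if (U && any(object@phi <= 0)) msg <- c(msg, "phi draws must be positive")
  if (length(msg)) msg else TRUE
})

#' Number of retained draws
#' @param samples a `PosteriorSamples` object
#' @return integer draw count U
#' @export
nDraws <- function(samples) length(samples@beta0)

#' Extract draws from a PosteriorSamples object
#' @param samples a `PosteriorSamples` object
#' @param what one of `"beta0"`, `"beta"`, `"gamma"`, `"phi"`
#' @return the requested draws (vector or U-by-L matrix)
#' @export
drawMatrix <- function(samples,
                       what = c("beta", "gamma", "beta0", "phi")) {
  what <- match.arg(what)
  slot(samples, what)
}

setMethod("show", "PosteriorSamples", function(object) {
  cat("PosteriorSamples for gene", object@geneId, "\n")
  cat("  retained draws:", length(object@beta0),
      "| covariates:", ncol(object@beta), "\n")
  if (length(object@beta0)) {
    cat("  mean phi:", round(mean(object@phi), 3),
        "| mean model size:", round(mean(Matrix::rowSums(object@gamma)), 2),
        "\n")
  }
})

# ---------------------------------------------------------------------------
# SimulationConfig
# ---------------------------------------------------------------------------

#' Configuration of the synthetic SRT data generator
#'
#' Defines a model-matched synthetic dataset: a Visium-like lattice of spots,
#' a paired cell cloud with per-cell covariates (cell-type dummies plus
#' standardized continuous nuclei-shape features, one of which — named
#' `orientation` — is a pure-noise negative control whose true coefficient is
#' always zero), sparse true coefficients with roughly `zeroFrac` of the
#' selectable entries at zero, and NB counts with product-one size factors.
#'
#' @param nSpots number of lattice spots (default 500).
#' @param gridShape integer c(rows, cols); computed from `nSpots` if empty.
#' @param spotDiameter spot diameter, pixels (default 55, Visium-like).
#' @param spotSpacing lattice center-to-center spacing, pixels (default 100;
#'   must exceed `spotDiameter` so spots do not overlap).
#' @param cellsPerSpotMean Poisson mean of covered cells per spot (default 12).
#' @param nCelltypes Q, number of cell types (default 7).
#' @param nShapeFeatures number of continuous shape features incl. the noise
#'   control (default 10).
#' @param nGenes number of genes P (default 100).
#' @param zeroFrac probability a selectable true coefficient is zero
#'   (default 0.5).
#' @param betaSd sd of non-zero true coefficients (default 1).
#' @param phiRange range of the uniform draw for true dispersions
#'   (default c(2, 20)).
#' @param uncoveredCellFrac fraction of all cells lying outside every spot
#'   (default 0.3).
#' @param sizeFactorSdLog lognormal sdlog of raw size factors before the
#'   product-one renormalization (default 0.3).
#' @param seed integer seed.
#' @return a `SimulationConfig` object.
#' @export
setClass("SimulationConfig", representation(
  nSpots = "integer", gridShape = "integer", spotDiameter = "numeric",
  spotSpacing = "numeric", cellsPerSpotMean = "numeric",
  nCelltypes = "integer", nShapeFeatures = "integer", nGenes = "integer",
  zeroFrac = "numeric", betaSd = "numeric", phiRange = "numeric",
  uncoveredCellFrac = "numeric", sizeFactorSdLog = "numeric", seed = "integer"
), prototype(nSpots = 500L, gridShape = integer(0), spotDiameter = 55,
             spotSpacing = 100, cellsPerSpotMean = 12, nCelltypes = 7L,
             nShapeFeatures = 10L, nGenes = 100L, zeroFrac = 0.5, betaSd = 1,
             phiRange = c(2, 20), uncoveredCellFrac = 0.3,
             sizeFactorSdLog = 0.3, seed = 1L))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSpots < 1L) msg <- c(msg, "nSpots must be positive")
  if (length(object@gridShape) == 2L &&
      prod(object@gridShape) < object@nSpots) {
    msg <- c(msg, "gridShape rows*cols must be at least nSpots")
  }
  if (object@spotSpacing <= object@spotDiameter) {
    msg <- c(msg, "spotSpacing must exceed spotDiameter (non-overlap)")
  }
  if (object@zeroFrac < 0 || object@zeroFrac > 1) {
    msg <- c(msg, "zeroFrac must lie in [0, 1]")
  }
  if (object@uncoveredCellFrac < 0 || object@uncoveredCellFrac >= 1) {
    msg <- c(msg, "uncoveredCellFrac must lie in [0, 1)")
  }
  if (length(object@phiRange) != 2L || any(object@phiRange <= 0) ||
      diff(object@phiRange) < 0) {
    msg <- c(msg, "phiRange must be an increasing positive pair")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @aliases SimulationConfig
#' @export
SimulationConfig <- function(nSpots = 500L, gridShape = integer(0),
                             spotDiameter = 55, spotSpacing = 100,
                             cellsPerSpotMean = 12, nCelltypes = 7L,
                             nShapeFeatures = 10L, nGenes = 100L,
                             zeroFrac = 0.5, betaSd = 1, phiRange = c(2, 20),
                             uncoveredCellFrac = 0.3, sizeFactorSdLog = 0.3,
                             seed = 1L) {
  if (!length(gridShape)) {
    rows <- ceiling(sqrt(nSpots))
    gridShape <- c(rows, ceiling(nSpots / rows))
  }
  new("SimulationConfig", nSpots = as.integer(nSpots),
      gridShape = as.integer(gridShape), spotDiameter = spotDiameter,
      spotSpacing = spotSpacing, cellsPerSpotMean = cellsPerSpotMean,
      nCelltypes = as.integer(nCelltypes),
      nShapeFeatures = as.integer(nShapeFeatures), nGenes = as.integer(nGenes),
      zeroFrac = zeroFrac, betaSd = betaSd, phiRange = phiRange,
      uncoveredCellFrac = uncoveredCellFrac,
      sizeFactorSdLog = sizeFactorSdLog, seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# MaskingScheme
# ---------------------------------------------------------------------------

#' MaskingScheme: a train/test split of spots for imputation validation
#'
#' Scenario `"random_fraction"` masks `floor(maskFrac * N)` spots uniformly at
#' random; scenario `"half_domain"` masks every spot whose coordinate on the
#' chosen axis exceeds the split point (default: the median coordinate).
#'
#' @slot scenario `"random_fraction"` or `"half_domain"`.
#' @slot maskFrac numeric in (0, 1), used by scenario 1.
#' @slot axis `"x"` or `"y"`, used by scenario 2.
#' @slot split numeric split coordinate, used by scenario 2.
#' @slot seed integer.
#' @slot maskedIds,unmaskedIds disjoint character vectors covering all spots.
#' @export
setClass("MaskingScheme", representation(
  scenario = "character", maskFrac = "numeric", axis = "character",
  split = "numeric", seed = "integer",
  maskedIds = "character", unmaskedIds = "character"
))

setValidity("MaskingScheme", function(object) {
  if (length(intersect(object@maskedIds, object@unmaskedIds))) {
    return("masked and unmasked spot sets must be disjoint")
  }
  TRUE
})

setMethod("show", "MaskingScheme", function(object) {
  cat("MaskingScheme:", object@scenario, "\n")
  cat("  masked:", length(object@maskedIds),
      "| unmasked:", length(object@unmaskedIds), "\n")
})

# ---------------------------------------------------------------------------
# PredictedExpression
# ---------------------------------------------------------------------------

#' PredictedExpression: reconstructed cell-level expression and spot counts
#'
#' @slot thetaHat M-by-P positive matrix of posterior-mean cell-level relative
#'   expression (all cells, covered or not).
#' @slot yHat N-by-P non-negative integer matrix of predictive spot counts
#'   (ceiling of the Monte-Carlo predictive mean).
#' @slot drawCount integer, the number of MCMC draws averaged.
#' @export
setClass("PredictedExpression", representation(
  thetaHat = "matrix", yHat = "matrix", drawCount = "integer"
))

setValidity("PredictedExpression", function(object) {
  msg <- character()
  if (any(object@thetaHat <= 0)) {
    msg <- c(msg, "thetaHat must be strictly positive")
  }
  if (length(object@yHat) &&
      (any(object@yHat < 0) || any(object@yHat != round(object@yHat)))) {
    msg <- c(msg, "yHat must contain non-negative integers")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PredictedExpression", function(object) {
  cat("PredictedExpression:", nrow(object@thetaHat), "cells x",
      ncol(object@thetaHat), "genes |", nrow(object@yHat),
      "spots | U =", object@drawCount, "\n")
})

#' @describeIn PredictedExpression-class cell-level relative expression
#' @param object a `PredictedExpression`
#' @export
thetaHat <- function(object) object@thetaHat

#' @describeIn PredictedExpression-class predictive spot counts
#' @export
yHat <- function(object) object@yHat
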