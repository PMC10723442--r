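# Evaluation protocols: logged-expression correlation, coefficient RMSE
# split by the true support, and the two spot-masking imputation scenarios.

#' Pearson correlation of logged expression
#'
#' Correlation between `log(thetaHat)` and `log(thetaTrue)` over cells.
#' Returns `NA` (a skip flag) when either logged vector has zero variance —
#' e.g. a gene whose true expression is constant across cells — since the
#' correlation is undefined there.
#'
#' @param thetaHat,thetaTrue strictly positive vectors of equal length >= 3.
#' @return numeric in `[-1, 1]`, or `NA` when skipped.
#' @export
loggedExpressionCorrelation <- function(thetaHat, thetaTrue) {
  stopifnot(length(thetaHat) == length(thetaTrue), length(thetaHat) >= 3L)
  if (any(thetaHat <= 0) || any(thetaTrue <= 0)) {
    stop("relative expression must be strictly positive")
  }
  lh <- log(thetaHat)
  lt <- log(thetaTrue)
  if (stats::sd(lh) == 0 || stats::sd(lt) == 0) return(NA_real_)
  stats::cor(lh, lt)
}

#' Coefficient RMSE split by the true support
#'
#' Root mean square error between estimated and true coefficients, reported
#' separately over entries whose true coefficient is non-zero
#' (`gammaTrue = 1`) and over truly-zero entries (`gammaTrue = 0`). An empty
#' partition is reported as `NA`.
#'
#' @param betaHat,betaTrue numeric vectors/matrices of matching shape.
#' @param gammaTrue binary, same shape.
#' @return named numeric `c(rmse_nonzero, rmse_zero)`.
#' @export
coefficientRmse <- function(betaHat, betaTrue, gammaTrue) {
  stopifnot(length(betaHat) == length(betaTrue),
            length(gammaTrue) == length(betaTrue))
  err2 <- (as.numeric(betaHat) - as.numeric(betaTrue))^2
  g <- as.integer(gammaTrue)
  rmse <- function(e) if (length(e)) sqrt(mean(e)) else NA_real_
  c(rmse_nonzero = rmse(err2[g == 1L]), rmse_zero = rmse(err2[g == 0L]))
}

#' Construct a spot-masking scheme
#'
#' Scenario `"random_fraction"` masks exactly `floor(maskFrac * N)` spots
#' chosen uniformly without replacement. Scenario `"half_domain"` masks
#' every spot whose coordinate on the chosen axis exceeds the split point
#' (default: the median coordinate), producing two spatially disjoint
#' halves.
#'
#' @param profile a [MolecularProfile].
#' @param scenario `"random_fraction"` or `"half_domain"`.
#' @param maskFrac fraction to mask in scenario 1, strictly inside (0, 1).
#' @param axis `"x"` or `"y"` (scenario 2).
#' @param split numeric split coordinate (scenario 2; default the median).
#' @param seed integer; the same seed always returns the same masked set.
#' @return a [MaskingScheme].
#' @export
maskSpots <- function(profile, scenario = c("random_fraction", "half_domain"),
                      maskFrac = 0.4, axis = c("x", "y"), split = NULL,
                      seed = 1L) {
  scenario <- match.arg(scenario)
  axis <- match.arg(axis)
  ids <- spotIds(profile)
  N <- length(ids)
  if (scenario == "random_fraction") {
    stopifnot(maskFrac > 0, maskFrac < 1)
    set.seed(seed)
    masked <- sort(sample.int(N, floor(maskFrac * N)))
    split <- NA_real_
  } else {
    coords <- spotCoords(profile)[, if (axis == "x") 1L else 2L]
    if (is.null(split)) split <- stats::median(coords)
    masked <- which(coords > split)
  }
  if (N - length(masked) < 10L) {
    stop("masking would leave fewer than 10 unmasked spots")
  }
  if (length(masked) == 0L) stop("masking selected no spots")
  new("MaskingScheme", scenario = scenario, maskFrac = maskFrac,
      axis = axis, split = as.numeric(split), seed = as.integer(seed),
      maskedIds = ids[masked], unmaskedIds = ids[-masked])
}

#' Masked-spot imputation experiment
#'
#' Fits per-gene chains on the unmasked spots only, imputes the masked
#' spots' counts by Monte-Carlo posterior prediction using the masked
#' spots' own cells, and reports the per-gene Pearson correlation between
#' observed and imputed masked-spot counts. Size factors are computed from
#' the full (pre-masking) profile and held fixed: masked counts exist but
#' are hidden from the fit, and totals are used for scaling only.
#'
#' @param profile the full [MolecularProfile].
#' @param image an [ImageProfile] over all cells.
#' @param G a [GeospatialProfile] matching `profile`.
#' @param scheme a [MaskingScheme] from [maskSpots()].
#' @param hp a [Hyperparameters()].
#' @param config a [SamplerConfig()].
#' @param geneSubset genes to evaluate (default: all).
#' @param logScale logical; correlate `log1p` counts instead of raw counts
#'   (default FALSE, raw scale).
#' @param predictSeed seed of the predictive sampling.
#' @return list with `perGeneRho` (named numeric, NA where skipped),
#'   `medianRho` (over non-skipped genes), `nMasked`, `nUnmasked`, and a
#'   `scheme` echo.
#' @export
runMaskingExperiment <- function(profile, image, G, scheme,
                                 hp = Hyperparameters(),
                                 config = SamplerConfig(),
                                 geneSubset = NULL, logScale = FALSE,
                                 predictSeed = 1L) {
  ids <- spotIds(profile)
  stopifnot(setequal(c(scheme@maskedIds, scheme@unmaskedIds), ids))
  sFull <- computeSizeFactors(profile)
  unm <- match(scheme@unmaskedIds, ids)
  msk <- match(scheme@maskedIds, ids)
  trainProfile <- subsetProfile(profile, spots = unm)
  trainG <- subsetGeospatial(G, spots = unm)
  if (any(cellsPerSpot(trainG) == 0L)) {
    stop("unmasked spot(s) with no covered cells; filter them first")
  }
  fits <- runAllGenes(trainProfile, image, trainG, hp = hp, config = config,
                      geneSubset = geneSubset,
                      sizeFactors = sFull[scheme@unmaskedIds])
  ok <- !vapply(fits, is.null, logical(1))
  maskG <- subsetGeospatial(G, spots = msk)
  if (any(cellsPerSpot(maskG) == 0L)) {
    stop("masked spot(s) with no covered cells; filter them first")
  }
  maskMembers <- spotMembers(maskG)
  obs <- as.matrix(spotCounts(subsetProfile(profile, spots = msk)))
  set.seed(predictSeed)
  rho <- rep(NA_real_, sum(ok))
  names(rho) <- names(fits)[ok]
  for (g in names(rho)) {
    pred <- predictSpotCounts(sFull[scheme@maskedIds], maskMembers,
                              fits[[g]], image)
    o <- obs[, g]
    p <- pred$yHat
    if (logScale) {
      o <- log1p(o)
      p <- log1p(p)
    }
    if (stats::sd(o) > 0 && stats::sd(p) > 0) rho[g] <- stats::cor(o, p)
  }
  list(perGeneRho = rho,
       medianRho = stats::median(rho, na.rm = TRUE),
       nMasked = length(msk), nUnmasked = length(unm),
       scheme = list(scenario = scheme@scenario, maskFrac = scheme@maskFrac,
                     axis = scheme@axis, split = scheme@split,
                     seed = scheme@seed))
}

#' Write masking metrics to disk
#'
#' Emits a per-gene metrics CSV (`gene, rho, skipped`) and a JSON summary.
#'
#' @param report output of [runMaskingExperiment()].
#' @param csvPath,jsonPath output paths.
#' @return invisibly, the CSV path.
#' @export
writeMaskingReport <- function(report, csvPath, jsonPath) {
  utils::write.csv(data.frame(gene = names(report$perGeneRho),
                              rho = as.numeric(report$perGeneRho),
                              skipped = is.na(report$perGeneRho)),
                   csvPath, row.names = FALSE)
  jsonlite::write_json(list(median_rho = report$medianRho,
                            n_masked = report$nMasked,
                            n_unmasked = report$nUnmasked,
                            scheme = report$scheme),
                       jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(csvPath)
}
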