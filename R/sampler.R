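# Per-gene Metropolis-Hastings / SSVS sampler. The single-move operations
# below are plain R and are checked against brute-force log-posterior
# oracles in the tests; the full chain (runGeneChain) runs in compiled code
# with the identical proposal mechanics.

.chainData <- function(y, s, G, X, celltypeColumns = integer(0)) {
  if (is(X, "ImageProfile")) {
    celltypeColumns <- celltypeColumns(X)
    X <- cellCovariates(X)
  }
  members <- .asMembers(G)
  stopifnot(length(y) == length(members), length(s) == length(y))
  list(y = as.integer(y), s = as.numeric(s), members = members,
       X = as.matrix(X), celltypeColumns = as.integer(celltypeColumns))
}

.logLikState <- function(state, data) {
  geneLogLikelihood(data$y, data$s, data$members, data$X, state)
}

.mhAccept <- function(logAlpha) {
  is.finite(logAlpha) && log(stats::runif(1)) < min(0, logAlpha)
}

#' Metropolis-Hastings update of the dispersion
#'
#' Random walk on `log(phi)`: proposes `phi' = exp(log phi + eps)` with
#' `eps ~ Norm(0, proposalSd^2)` and accepts with probability
#' `min(1, exp(dloglik + dlogprior + log(phi'/phi)))`, the last term being
#' the log-scale Jacobian. A non-finite proposed posterior is rejected.
#'
#' @param state a [GeneModelState()] list.
#' @param data a list as built by the chain: `y`, `s`, `members`, `X`.
#' @param hp a [Hyperparameters()] object.
#' @param proposalSd random-walk sd on the log scale.
#' @param proposal optional fixed proposal value (for deterministic checks);
#'   when supplied, no random draw is made.
#' @return list with elements `state` (updated), `accepted` (logical) and
#'   `logAlpha` (the log acceptance ratio).
#' @export
mhUpdatePhi <- function(state, data, hp, proposalSd = 0.2, proposal = NULL) {
  phiNew <- if (is.null(proposal)) {
    exp(log(state$phi) + stats::rnorm(1, 0, proposalSd))
  } else {
    proposal
  }
  stateNew <- state
  stateNew$phi <- phiNew
  dLik <- .logLikState(stateNew, data) - .logLikState(state, data)
  dPrior <- ((hp@aPhi - 1) * log(phiNew) - hp@bPhi * phiNew) -
    ((hp@aPhi - 1) * log(state$phi) - hp@bPhi * state$phi)
  logAlpha <- dLik + dPrior + log(phiNew / state$phi)
  accepted <- .mhAccept(logAlpha)
  list(state = if (accepted) stateNew else state, accepted = accepted,
       logAlpha = logAlpha)
}

#' Within-model Metropolis-Hastings update of an active coefficient
#'
#' Symmetric random-walk proposal on an active coefficient (`gamma_l = 1`) or
#' on the intercept (`l = 0`); the acceptance ratio is the likelihood ratio
#' times the slab prior ratio (no Jacobian).
#'
#' @inheritParams mhUpdatePhi
#' @param l coefficient index in `1..L`, or `0` for the intercept.
#' @param proposalSd random-walk sd.
#' @return list(`state`, `accepted`, `logAlpha`).
#' @export
mhUpdateBetaWithin <- function(state, data, hp, l, proposalSd = 0.1,
                               proposal = NULL) {
  stopifnot(l >= 0, l <= length(state$beta))
  if (l > 0 && state$gamma[l] != 1L) {
    stop("within-model update requires gamma[l] = 1")
  }
  cur <- if (l == 0) state$beta0 else state$beta[l]
  new <- if (is.null(proposal)) cur + stats::rnorm(1, 0, proposalSd) else
    proposal
  stateNew <- state
  if (l == 0) stateNew$beta0 <- new else stateNew$beta[l] <- new
  sb <- sqrt(hp@sigmaBetaSq)
  logAlpha <- (.logLikState(stateNew, data) - .logLikState(state, data)) +
    (stats::dnorm(new, 0, sb, log = TRUE) -
       stats::dnorm(cur, 0, sb, log = TRUE))
  accepted <- .mhAccept(logAlpha)
  list(state = if (accepted) stateNew else state, accepted = accepted,
       logAlpha = logAlpha)
}

#' Between-model (add/delete) update of a coefficient and its indicator
#'
#' Proposes flipping `gamma_l`. An add move (0 to 1) draws the new
#' coefficient from the slab `Norm(0, sigmaBetaSq)`; a delete move (1 to 0)
#' sets it to zero. With this proposal the slab density cancels, so the log
#' acceptance ratio is `dloglik + log(piGamma/(1 - piGamma)) * (gamma' -
#' gamma)`. The joint invariant (`gamma = 0` implies `beta = 0`) is preserved
#' by construction.
#'
#' @inheritParams mhUpdatePhi
#' @param l selectable coefficient index in `1..L` (never the intercept).
#' @param proposedBeta optional fixed slab draw for an add move.
#' @return list(`state`, `accepted`, `logAlpha`).
#' @export
mhUpdateGammaBetaBetween <- function(state, data, hp, l, proposedBeta = NULL) {
  stopifnot(l >= 1, l <= length(state$beta))
  stateNew <- state
  if (state$gamma[l] == 0L) {
    stateNew$gamma[l] <- 1L
    stateNew$beta[l] <- if (is.null(proposedBeta)) {
      stats::rnorm(1, 0, sqrt(hp@sigmaBetaSq))
    } else {
      proposedBeta
    }
    priorOdds <- log(hp@piGamma / (1 - hp@piGamma))
  } else {
    stateNew$gamma[l] <- 0L
    stateNew$beta[l] <- 0
    priorOdds <- -log(hp@piGamma / (1 - hp@piGamma))
  }
  logAlpha <- (.logLikState(stateNew, data) - .logLikState(state, data)) +
    priorOdds
  accepted <- .mhAccept(logAlpha)
  list(state = if (accepted) stateNew else state, accepted = accepted,
       logAlpha = logAlpha)
}

#' Enforce the sum-to-zero constraint on active cell-type coefficients
#'
#' Subtracts the mean of the currently active cell-type coefficients from
#' each of them and adds it to the intercept. Because every cell carries
#' exactly one cell-type dummy, the fitted relative expression of a cell
#' whose type is active is unchanged; the move is a no-op when no cell-type
#' coefficient is active. After the move, the active cell-type coefficients
#' sum to zero.
#'
#' @param state a [GeneModelState()] list.
#' @param celltypeColumns integer indices of the cell-type dummy columns.
#' @return the re-centered state.
#' @export
enforceSumToZero <- function(state, celltypeColumns) {
  active <- intersect(which(state$gamma == 1L), celltypeColumns)
  if (!length(active)) return(state)
  ctr <- mean(state$beta[active])
  state$beta[active] <- state$beta[active] - ctr
  state$beta0 <- state$beta0 + ctr
  state
}

#' Run the per-gene MCMC chain
#'
#' One full sweep per iteration: dispersion update, a between-model update
#' for every selectable covariate in random order, a within-model update for
#' the intercept and every active covariate in random order, then the
#' sum-to-zero re-centering of active cell-type coefficients. Initialization
#' is `beta0 = log(sum(y)/sum(s))` (moment-matched intercept), `beta = 0`,
#' `gamma = 0` (or all one when `regularize = FALSE`), `phi = phiInit`.
#' Post-burn-in draws are retained every `thin` iterations. The chain is
#' fully reproducible given `config@seed`.
#'
#' @param y non-negative integer counts, length N.
#' @param s positive size factors, length N (product one).
#' @param G a [GeospatialProfile], binary membership matrix, or list of
#'   member cell indices per spot; every spot must cover at least one cell.
#' @param X cell covariate matrix or [ImageProfile] (cell-type columns are
#'   taken from the profile).
#' @param hp a [Hyperparameters()] object.
#' @param config a [SamplerConfig()] object.
#' @param geneId optional gene id recorded in the output.
#' @param celltypeColumns integer indices (only needed when `X` is a bare
#'   matrix).
#' @return a [PosteriorSamples] object.
#' @export
runGeneChain <- function(y, s, G, X, hp = Hyperparameters(),
                         config = SamplerConfig(), geneId = NA_character_,
                         celltypeColumns = integer(0)) {
  validObject(hp)
  validObject(config)
  data <- .chainData(y, s, G, X, celltypeColumns)
  nPer <- lengths(data$members)
  if (any(nPer == 0L)) {
    stop("spot(s) with no covered cells: index ",
         paste(utils::head(which(nPer == 0L), 10L), collapse = ", "),
         "; filter them upstream")
  }
  if (sum(data$y) == 0 && !config@priorOnly) {
    stop("non-finite log-posterior at initialization: all counts are zero ",
         "for gene ", geneId)
  }
  # restrict to covered cells; remap member indices
  covered <- sort(unique(unlist(data$members)))
  remap <- match(covered, covered)
  lookup <- integer(nrow(data$X))
  lookup[covered] <- seq_along(covered)
  members0 <- lapply(data$members, function(m) lookup[m] - 1L)  # 0-based
  Xc <- data$X[covered, , drop = FALSE]
  beta0Init <- if (config@priorOnly) 0 else log(sum(data$y) / sum(data$s))
  set.seed(config@seed)
  res <- chain_nb_ssvs(
    y = data$y, s = data$s, members = members0, X = Xc,
    celltype_cols = data$celltypeColumns - 1L,
    a_phi = hp@aPhi, b_phi = hp@bPhi, sigma_beta_sq = hp@sigmaBetaSq,
    pi_gamma = hp@piGamma,
    n_iter = config@nIter, n_burn = config@nBurn, thin = config@thin,
    phi_prop_sd = config@phiProposalSd, beta_prop_sd = config@betaProposalSd,
    regularize = config@regularize, update_phi = config@updatePhi,
    prior_only = config@priorOnly, phi_init = config@phiInit,
    beta0_init = beta0Init
  )
  covNames <- colnames(data$X)
  if (is.null(covNames)) covNames <- paste0("cov_", seq_len(ncol(data$X)))
  beta <- res$beta
  gamma <- res$gamma
  colnames(beta) <- covNames
  colnames(gamma) <- covNames
  storage.mode(gamma) <- "integer"
  new("PosteriorSamples",
      beta0 = as.numeric(res$beta0), beta = beta, gamma = gamma,
      phi = as.numeric(res$phi), geneId = as.character(geneId),
      seed = config@seed,
      config = list(nIter = config@nIter, nBurn = config@nBurn,
                    thin = config@thin, seed = config@seed,
                    phiProposalSd = config@phiProposalSd,
                    betaProposalSd = config@betaProposalSd,
                    regularize = config@regularize,
                    updatePhi = config@updatePhi,
                    priorOnly = config@priorOnly, phiInit = config@phiInit,
                    aPhi = hp@aPhi, bPhi = hp@bPhi,
                    sigmaBetaSq = hp@sigmaBetaSq, piGamma = hp@piGamma),
      diagnostics = res$diagnostics)
}

#' Fit independent per-gene chains
#'
#' Runs [runGeneChain()] for every requested gene with a per-gene seed
#' derived from the gene's position in the profile's full gene list
#' (`config@seed + index`), so results are attached to gene identity, not to
#' the order of `geneSubset`. One gene's failure is reported without
#' aborting the others; an error is raised only when every gene fails.
#'
#' @param profile a [MolecularProfile].
#' @param image an [ImageProfile].
#' @param G a [GeospatialProfile] whose spots match `profile`.
#' @param hp a [Hyperparameters()] object.
#' @param config a [SamplerConfig()] object; `config@seed` is the base seed.
#' @param geneSubset character vector of gene ids (default: all genes).
#' @param sizeFactors optional fixed size factors (default: computed from
#'   `profile`); used by the masking protocol, where size factors from the
#'   full data are held fixed.
#' @param verbose logical, report per-gene progress.
#' @return named list of [PosteriorSamples], in `geneSubset` order; failed
#'   genes carry the condition message in an attribute `failures`.
#' @export
runAllGenes <- function(profile, image, G, hp = Hyperparameters(),
                        config = SamplerConfig(), geneSubset = NULL,
                        sizeFactors = NULL, verbose = FALSE) {
  genes <- geneIds(profile)
  if (is.null(geneSubset)) geneSubset <- genes
  if (!all(geneSubset %in% genes)) {
    stop("unknown gene id(s): ",
         paste(utils::head(setdiff(geneSubset, genes), 5L), collapse = ", "))
  }
  counts <- spotCounts(profile)
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(profile)
  members <- spotMembers(G)
  out <- vector("list", length(geneSubset))
  names(out) <- geneSubset
  failures <- character(0)
  for (g in geneSubset) {
    idx <- match(g, genes)
    cfg <- initialize(config, seed = config@seed + idx)
    res <- tryCatch(
      runGeneChain(counts[, idx], sizeFactors, members, image,
                   hp = hp, config = cfg, geneId = g),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[g] <- conditionMessage(res)
      out[g] <- list(NULL)
    } else {
      out[[g]] <- res
    }
    if (verbose) message("gene ", g, if (g %in% names(failures))
      " FAILED" else " done")
  }
  if (length(failures) == length(geneSubset)) {
    stop("all genes failed; first error: ", failures[[1L]])
  }
  if (length(failures)) {
    warning(length(failures), " gene(s) failed: ",
            paste(names(failures), collapse = ", "))
    attr(out, "failures") <- failures
  }
  out
}

#' Persist per-gene posterior samples
#'
#' Writes one serialized draws file per gene plus a JSON manifest with the
#' config echo (runtime artifacts; see [loadSamples()]).
#'
#' @param fits named list of [PosteriorSamples] (as from [runAllGenes()]).
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
saveSamples <- function(fits, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ok <- !vapply(fits, is.null, logical(1))
  for (g in names(fits)[ok]) {
    saveRDS(fits[[g]], file.path(dir, paste0(make.names(g), ".rds")))
  }
  manifest <- list(genes = names(fits)[ok],
                   files = paste0(make.names(names(fits)[ok]), ".rds"),
                   config = if (any(ok)) fits[[which(ok)[1L]]]@config else
                     list())
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname saveSamples
#' @param dir directory written by [saveSamples()].
#' @export
loadSamples <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  fits <- lapply(file.path(dir, manifest$files), readRDS)
  names(fits) <- manifest$genes
  fits
}
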