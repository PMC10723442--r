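# helper: build a PosteriorSamples object with hand-chosen draws
mkSamples <- function(beta0, beta, gamma = (beta != 0) * 1L, phi = NULL,
                      geneId = "g") {
  beta <- as.matrix(beta)
  gamma <- matrix(as.integer(gamma), nrow(beta), ncol(beta))
  if (is.null(phi)) phi <- rep(1, nrow(beta))
  if (is.null(colnames(beta))) {
    colnames(beta) <- paste0("cov_", seq_len(ncol(beta)))
  }
  colnames(gamma) <- colnames(beta)
  new("PosteriorSamples", beta0 = as.numeric(beta0), beta = beta,
      gamma = gamma, phi = as.numeric(phi), geneId = geneId, seed = 1L,
      config = list(), diagnostics = list())
}

test_that("PPI is the draw average of the inclusion indicators", {
  s <- mkSamples(rep(0, 4), cbind(a = c(1, 1, 1, 1) * c(0.2, 0.3, 0.1, 0.5),
                                  b = c(0.4, 0, 0.9, 0), c = c(0, 0, 0, 0)))
  expect_equal(unname(computePPI(s)), c(1, 0.5, 0))
  empty <- mkSamples(numeric(0), matrix(0, 0, 2))
  expect_error(computePPI(empty), "U = 0")
})

test_that("median-model selection is strict at the threshold", {
  expect_equal(unname(selectMedianModel(c(0.9, 0.4))), c(1L, 0L))
  expect_equal(unname(selectMedianModel(c(0.5, 0.500001, 1))), c(0L, 1L, 1L))
  expect_equal(unname(selectMedianModel(rep(1, 3))), rep(1L, 3))
})

test_that("Bayesian FDR selection scans thresholds and nests in alpha", {
  sel <- selectBFDR(c(0.99, 0.98, 0.60), alpha = 0.05)
  expect_equal(unname(sel), c(1L, 1L, 0L))
  # vacuous control keeps everything with positive PPI
  expect_equal(unname(selectBFDR(c(0.99, 0.98, 0.60, 0), alpha = 0.999)),
               c(1L, 1L, 1L, 0L))
  expect_equal(unname(selectBFDR(rep(0, 4), alpha = 0.2)), rep(0L, 4))
  # selections are nested and decreasing as alpha shrinks
  set.seed(6)
  ppi <- runif(12)
  alphas <- c(0.5, 0.2, 0.1, 0.02, 0.005)
  sels <- lapply(alphas, function(a) which(selectBFDR(ppi, a) == 1L))
  for (k in seq_len(length(alphas) - 1L)) {
    expect_true(all(sels[[k + 1L]] %in% sels[[k]]))
  }
})

test_that("point estimates average all draws including spike zeros", {
  s <- mkSamples(c(1, 1, 1, 1), cbind(a = c(0, 0, 2, 2)),
                 gamma = cbind(c(0L, 0L, 1L, 1L)), phi = c(2, 2, 2, 2))
  est <- posteriorEstimates(s)
  expect_equal(unname(est$betaHat), 1)
  expect_equal(est$phiHat, 2)
  expect_equal(est$beta0Hat, 1)
  # constant draws give zero-width intervals
  expect_equal(est$ci$lower[est$ci$parameter == "phi"],
               est$ci$upper[est$ci$parameter == "phi"])
  # interval level 0.95 on sorted draws = empirical 2.5% / 97.5% quantiles
  draws <- seq_len(1000) / 10
  s2 <- mkSamples(draws, cbind(a = draws), phi = rep(1, 1000))
  est2 <- posteriorEstimates(s2, level = 0.95)
  ci <- est2$ci[est2$ci$parameter == "a", ]
  expect_equal(ci$lower, unname(quantile(draws, 0.025)))
  expect_equal(ci$upper, unname(quantile(draws, 0.975)))
})

test_that("cell expression prediction averages exp-link draws over all cells", {
  X <- matrix(c(0.5, 0.5, -1), 3, 1, dimnames = list(NULL, "a"))
  # null chain: every draw has beta = 0, beta0 = 0
  s0 <- mkSamples(c(0, 0), cbind(a = c(0, 0)))
  expect_equal(unname(predictCellExpression(X, s0)), rep(1, 3))
  # single draw with beta0 = log 3
  s1 <- mkSamples(log(3), cbind(a = 0))
  expect_equal(unname(predictCellExpression(X, s1)), rep(3, 3))
  # identical covariate rows give identical predictions
  s2 <- mkSamples(c(0.1, -0.2), cbind(a = c(0.5, 0)))
  th <- predictCellExpression(X, s2)
  expect_equal(th[[1]], th[[2]])
  # the average is over draws of exp(eta), not exp of the average
  expect_equal(unname(th[3]),
               mean(exp(c(0.1 - 0.5, -0.2))))
  # mismatched covariates are refused
  Xbad <- matrix(0, 3, 1, dimnames = list(NULL, "zz"))
  expect_error(predictCellExpression(Xbad, s2), "match")
})

test_that("spot count prediction ceilings the Monte-Carlo mean and stays consistent", {
  X <- matrix(c(0, log(2), log(4)), 3, 1, dimnames = list(NULL, "a"))
  members <- list(1:2, 3L)
  s <- c(1, 2)
  # phi huge: the NB collapses to its mean
  samp <- mkSamples(c(0, 0), cbind(a = c(1, 1)), phi = c(1e9, 1e9))
  set.seed(8)
  out <- predictSpotCounts(s, members, samp, X)
  # spot 1: mean(exp(0), exp(log 2)) = 1.5; spot 2: 2 * 4 = 8
  expect_equal(out$muHat, c(1.5, 8))
  expect_equal(out$yHat, as.integer(ceiling(out$yMean)))
  expect_true(all(out$yHat >= 0))
  # fixed-draw identity: mean NB mean equals s_i times the draw-average of
  # the member-cell theta average, to 1e-10
  samp2 <- mkSamples(c(0.2, -0.1), cbind(a = c(0.7, 0)), phi = c(2, 3))
  out2 <- predictSpotCounts(s, members, samp2, X)
  thDraws <- sapply(1:2, function(u) {
    exp(samp2@beta0[u] + X[, 1] * samp2@beta[u, 1])
  })
  lamDraws <- rbind(colMeans(thDraws[1:2, ]), thDraws[3, ])
  expect_equal(out2$muHat, rowMeans(lamDraws * s), tolerance = 1e-10)
  expect_error(predictSpotCounts(s, list(integer(0), 3L), samp, X), "empty")
})

test_that("multi-gene reconstruction returns cell-by-gene and spot-by-gene blocks", {
  sim <- tinySim()
  cfg <- SamplerConfig(nIter = 400L, nBurn = 200L, seed = 5L)
  fits <- runAllGenes(sim$molecular, sim$image, sim$geospatial, config = cfg)
  pred <- reconstructExpression(sim$molecular, sim$image, sim$geospatial,
                                fits, seed = 77L)
  expect_equal(dim(thetaHat(pred)), c(nCells(sim$image), length(fits)))
  expect_equal(dim(yHat(pred)), c(nSpots(sim$molecular), length(fits)))
  expect_true(all(thetaHat(pred) > 0))
  expect_true(all(yHat(pred) >= 0))
  tab <- coefficientTable(fits)
  expect_equal(nrow(tab),
               length(fits) * (ncol(cellCovariates(sim$image)) + 1L))
  expect_true(all(c("gene", "covariate", "beta_hat", "ppi", "gamma_hat",
                    "ci_lo", "ci_hi") %in% colnames(tab)))
})
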