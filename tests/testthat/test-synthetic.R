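test_that("simulated geometry is self-consistent with the membership rule", {
  cfg <- SimulationConfig(nSpots = 40L, nGenes = 2L, seed = 13L)
  set.seed(cfg@seed)
  geo <- simulateGeometry(cfg)
  # re-deriving G from coordinates and diameter reproduces the emitted G
  re <- assignCellsToSpots(geo$spotCoords, cfg@spotDiameter, geo$cellCoords)
  expect_equal(as.matrix(membership(re)), as.matrix(membership(geo$geospatial)))
  expect_true(all(cellsPerSpot(geo$geospatial) >= 1L))
  # uncovered fraction close to its target
  fr <- length(uncoveredCells(geo$geospatial)) / nrow(geo$cellCoords)
  expect_lt(abs(fr - cfg@uncoveredCellFrac), 0.05)
  # zero uncovered fraction puts every cell in a spot
  cfg0 <- SimulationConfig(nSpots = 20L, nGenes = 2L, seed = 13L,
                           uncoveredCellFrac = 0)
  set.seed(cfg0@seed)
  geo0 <- simulateGeometry(cfg0)
  expect_equal(length(uncoveredCells(geo0$geospatial)), 0L)
})

test_that("simulated covariates are one-hot typed with standardized shapes", {
  cfg <- SimulationConfig(nSpots = 350L, nGenes = 2L, seed = 17L)
  set.seed(cfg@seed)
  geo <- simulateGeometry(cfg)
  ip <- simulateCovariates(cfg, geo)
  X <- cellCovariates(ip)
  M <- nrow(X)
  expect_gt(M, 3000)
  dummies <- X[, celltypeColumns(ip), drop = FALSE]
  expect_true(all(rowSums(dummies) == 1))
  expect_true(all(dummies %in% c(0, 1)))
  # shape-feature columns are standard normal within CLT bounds
  shapes <- X[, continuousColumns(ip), drop = FALSE]
  expect_true(all(abs(colMeans(shapes)) < 3 / sqrt(M)))
  expect_true(all(abs(apply(shapes, 2, sd) - 1) < 3 / sqrt(M)))
  expect_true(noiseControlCovariate() %in% covariateNames(ip))
  # a single cell type degenerates to one all-ones dummy column
  cfg1 <- SimulationConfig(nSpots = 20L, nGenes = 2L, seed = 17L,
                           nCelltypes = 1L)
  set.seed(cfg1@seed)
  geo1 <- simulateGeometry(cfg1)
  ip1 <- simulateCovariates(cfg1, geo1)
  expect_equal(length(celltypeColumns(ip1)), 1L)
  expect_true(all(cellCovariates(ip1)[, 1] == 1))
})

test_that("simulated coefficients honor sparsity, centering and the noise control", {
  cfg <- SimulationConfig(nSpots = 60L, nGenes = 100L, seed = 19L)
  set.seed(cfg@seed)
  geo <- simulateGeometry(cfg)
  ip <- simulateCovariates(cfg, geo)
  tr <- simulateCoefficients(cfg, ip)
  expect_true(all((tr$betaTrue == 0) == (tr$gammaTrue == 0L)))
  # the noise control never carries signal
  expect_true(all(tr$betaTrue[noiseControlCovariate(), ] == 0))
  # zero fraction near its binomial expectation on the other 16 columns
  other <- setdiff(rownames(tr$betaTrue), noiseControlCovariate())
  nz <- sum(tr$betaTrue[other, ] == 0)
  n <- length(other) * cfg@nGenes
  expect_lt(abs(nz - 0.5 * n), 3 * sqrt(n * 0.25) + 0.06 * n)
  # active cell-type block of every gene sums to zero
  ct <- celltypeColumns(ip)
  for (j in seq_len(cfg@nGenes)) {
    act <- tr$betaTrue[ct, j][tr$betaTrue[ct, j] != 0]
    if (length(act)) expect_lt(abs(sum(act)), 1e-10)
  }
  expect_true(all(tr$phiTrue >= cfg@phiRange[1] &
                    tr$phiTrue <= cfg@phiRange[2]))
  # boundary: zeroFrac = 1 wipes every selectable coefficient
  cfgZ <- SimulationConfig(nSpots = 20L, nGenes = 5L, seed = 19L,
                           zeroFrac = 1)
  trZ <- simulateCoefficients(cfgZ, ip)
  expect_true(all(trZ$betaTrue == 0))
})

test_that("simulated counts follow the declared NB law and truth identities", {
  sim <- tinySim()
  tr <- sim$truth
  # theta_true equals the log-link recomputed independently
  eta <- sweep(cellCovariates(sim$image) %*% tr$betaTrue, 2, tr$beta0True,
               "+")
  expect_equal(tr$thetaTrue, exp(pmin(pmax(eta, -30), 30)),
               tolerance = 1e-12)
  expect_equal(prod(sim$sizeFactors), 1, tolerance = 1e-8)
  # standardized residuals of the counts against the NB moments
  members <- spotMembers(sim$geospatial)
  lam <- do.call(rbind, lapply(members, function(m) {
    colMeans(tr$thetaTrue[m, , drop = FALSE])
  }))
  mu <- lam * sim$sizeFactors
  y <- as.matrix(spotCounts(sim$molecular))
  z <- (y - mu) / sqrt(sweep(mu + sweep(mu^2, 2, tr$phiTrue, "/"), 1, 1, "*"))
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)) * 1.5)
  # empirical NB variance matches v + v^2/phi at fixed parameters
  set.seed(99)
  draws <- rnbinom(20000, size = 1, mu = 2)
  vTheory <- 2 + 4 / 1
  seVar <- sd((draws - mean(draws))^2) / sqrt(length(draws))
  expect_lt(abs(var(draws) - vTheory), 3 * seVar)
  # null model: all beta zero and unit size factors give mean ~ 1
  cfgN <- SimulationConfig(nSpots = 40L, nGenes = 20L, seed = 23L,
                           zeroFrac = 1, sizeFactorSdLog = 1e-8)
  simN <- simulateDataset(cfgN)
  muN <- exp(simN$truth$beta0True)
  yN <- as.matrix(spotCounts(simN$molecular))
  expect_equal(mean(yN), mean(sweep(matrix(1, 40, 20), 2, muN, "*")),
               tolerance = 0.1)
})

test_that("fixture directories are written completely and reproducibly", {
  sim <- tinySim()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeSimulatedDataset(sim, d1)
  writeSimulatedDataset(sim, d2)
  files <- c("matrix.mtx", "barcodes.tsv", "features.tsv", "positions.csv",
             "scalefactors.json", "cells.csv", "truth_beta.csv",
             "truth_gamma.csv", "truth_phi.csv", "truth_theta.csv",
             "config.json")
  expect_true(all(file.exists(file.path(d1, files))))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
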