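test_that("size factors follow the geometric-mean normalization with product one", {
  expect_equal(unname(computeSizeFactors(rbind(a = c(1, 1), b = c(1, 1)))),
               c(1, 1))
  s <- computeSizeFactors(rbind(a = c(2, 2), b = c(8, 8)))
  expect_equal(unname(s), c(0.5, 2.0))
  expect_equal(prod(s), 1)
  # product-one constraint on arbitrary valid profiles
  set.seed(1)
  for (r in 1:5) {
    counts <- matrix(rpois(60, 5) + 1L, 10, 6)
    expect_equal(prod(computeSizeFactors(counts)), 1, tolerance = 1e-10)
  }
})

test_that("size factors are scale-equivariant and reject empty spots", {
  set.seed(2)
  counts <- matrix(rpois(50, 3) + 1L, 10, 5,
                   dimnames = list(paste0("s", 1:10), NULL))
  s <- computeSizeFactors(counts)
  for (k in c(2L, 7L)) {
    expect_equal(computeSizeFactors(counts * k), s)
  }
  counts[3, ] <- 0L
  expect_error(computeSizeFactors(counts), "s3")
})

test_that("spot-prevalence gene filter counts non-zero spots and is monotone", {
  counts <- rbind(c(1, 0), c(1, 0), c(1, 1))
  expect_equal(unname(filterGenesSpotPrevalence(counts, 0.5)), 1L)
  # an all-zero gene never passes
  counts0 <- cbind(counts, 0)
  expect_false(3L %in% filterGenesSpotPrevalence(counts0, 0.01))
  expect_error(filterGenesSpotPrevalence(counts, 0), "minFrac")
  set.seed(3)
  big <- matrix(rbinom(400, 1, 0.4) * rpois(400, 3), 20, 20)
  fr <- c(0.1, 0.3, 0.5, 0.8)
  keeps <- lapply(fr, function(f) filterGenesSpotPrevalence(big, f))
  for (k in seq_len(length(fr) - 1L)) {
    expect_true(all(keeps[[k + 1L]] %in% keeps[[k]]))
  }
})

test_that("cell-level gene filter applies both clauses", {
  m <- cbind(g1 = c(5L, 12L, rep(0L, 8)),   # expressed in 20% of cells
             g2 = c(rep(3L, 4L), 11L, rep(0L, 5)),  # 50%, max 11
             g3 = rep(0L, 10),
             g4 = c(rep(2L, 6L), rep(0L, 4)))  # 60% but max 2
  keep <- filterGenesCellwise(m, minCellFrac = 0.3, minMaxCount = 10L)
  expect_equal(unname(keep), 2L)
  expect_error(filterGenesCellwise(matrix(0L, 0, 0)), "empty")
})

test_that("cell tables expand to sorted one-hot dummies and round-trip", {
  cells <- data.frame(cell_id = c("c1", "c2", "c3"), x = 1:3, y = 4:6,
                      cell_type = c("a", "b", "a"),
                      area = c(10, 20, 30))
  ip <- imageProfileFromTable(cells, standardize = FALSE)
  X <- cellCovariates(ip)
  expect_equal(colnames(X)[celltypeColumns(ip)],
               c("celltype_a", "celltype_b"))
  expect_equal(unname(X[, "celltype_a"]), c(1, 0, 1))
  expect_equal(unname(X[, "celltype_b"]), c(0, 1, 0))
  back <- imageProfileToTable(ip)
  expect_equal(back$cell_type, cells$cell_type)
  expect_equal(back$area, cells$area)
  # standardization is stored and inverted on the way out
  ip2 <- imageProfileFromTable(cells, standardize = TRUE)
  expect_equal(mean(cellCovariates(ip2)[, "area"]), 0)
  expect_equal(sd(cellCovariates(ip2)[, "area"]), 1)
  expect_equal(imageProfileToTable(ip2)$area, cells$area)
  expect_error(imageProfileFromTable(cells[, -2]), "x")
})

test_that("profiles survive a save/load round trip without altering counts", {
  sim <- tinySim()
  dir <- withr::local_tempdir()
  writeProfiles(sim$molecular, sim$image, dir)
  got <- loadProfiles(countsPath = file.path(dir, "matrix.mtx"),
                      positionsPath = file.path(dir, "positions.csv"),
                      cellsPath = file.path(dir, "cells.csv"),
                      scalefactorsPath = file.path(dir, "scalefactors.json"),
                      barcodesPath = file.path(dir, "barcodes.tsv"),
                      featuresPath = file.path(dir, "features.tsv"),
                      standardize = FALSE)
  expect_equal(sum(spotCounts(got$molecular)), sum(spotCounts(sim$molecular)))
  expect_equal(as.matrix(spotCounts(got$molecular)),
               as.matrix(spotCounts(sim$molecular)))
  expect_equal(spotIds(got$molecular), spotIds(sim$molecular))
  expect_equal(spotDiameter(got$molecular), spotDiameter(sim$molecular))
  expect_equal(unname(spotCoords(got$molecular)),
               unname(spotCoords(sim$molecular)))
  expect_equal(cellCovariates(got$image), cellCovariates(sim$image))
})

test_that("the 10x tissue_positions dialect is accepted, in-tissue rows only", {
  sim <- tinySim()
  dir <- withr::local_tempdir()
  writeProfiles(sim$molecular, sim$image, dir)
  coords <- spotCoords(sim$molecular)
  pos10x <- data.frame(barcode = c(spotIds(sim$molecular), "ghost"),
                       in_tissue = c(rep(1L, nrow(coords)), 0L),
                       array_row = 0L, array_col = 0L,
                       pxl_row_in_fullres = c(coords[, 2L], 9e9),
                       pxl_col_in_fullres = c(coords[, 1L], 9e9))
  write.csv(pos10x, file.path(dir, "tissue_positions.csv"),
            row.names = FALSE)
  got <- loadProfiles(countsPath = file.path(dir, "matrix.mtx"),
                      positionsPath = file.path(dir, "tissue_positions.csv"),
                      cellsPath = file.path(dir, "cells.csv"),
                      spotDiameter = 55,
                      barcodesPath = file.path(dir, "barcodes.tsv"),
                      featuresPath = file.path(dir, "features.tsv"))
  expect_equal(unname(spotCoords(got$molecular)), unname(coords))
})

test_that("profile validity rejects malformed inputs", {
  expect_error(MolecularProfile(matrix(c(1, -1, 0, 2), 2, 2),
                                cbind(1:2, 1:2), 55),
               "non-negative")
  expect_error(MolecularProfile(matrix(c(0.5, 1, 0, 2), 2, 2),
                                cbind(1:2, 1:2), 55),
               "non-negative integers")
  expect_error(MolecularProfile(matrix(0:3, 2, 2), cbind(1:2, 1:2), -1),
               "positive")
  counts <- matrix(0:3, 2, 2,
                   dimnames = list(c("a", "a"), c("g1", "g2")))
  expect_error(MolecularProfile(counts, cbind(1:2, 1:2), 55), "duplicated")
  # one-hot violation in the cell-type block
  X <- cbind(t1 = c(1, 1), t2 = c(1, 0), f = c(0.2, 0.3))
  expect_error(ImageProfile(X, cbind(1:2, 1:2), celltypeColumns = 1:2),
               "one-hot")
})

test_that("dropEmptySpots removes and names zero-count spots", {
  counts <- matrix(c(0L, 5L, 0L, 3L), 2, 2,
                   dimnames = list(c("s1", "s2"), c("g1", "g2")))
  mp <- MolecularProfile(counts, cbind(1:2, 1:2), 55)
  expect_warning(out <- dropEmptySpots(mp), "s1")
  expect_equal(spotIds(out), "s2")
})
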