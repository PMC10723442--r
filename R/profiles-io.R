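# Loading, validation and persistence of the three profiles; size factors
# and the gene filters applied before model fitting.

.countsMatrix <- function(x) {
  if (is(x, "MolecularProfile")) spotCounts(x) else x
}

#' Spot size factors with a product-one constraint
#'
#' Computes per-spot size factors proportional to the spot's total read count
#' and normalized by the geometric mean of all totals, so that the product of
#' the N size factors equals one. Spots with zero total count are not allowed
#' here; remove them first (see [dropEmptySpots()]).
#'
#' @param x a [MolecularProfile] or a spots-by-genes count matrix.
#' @return named numeric vector of positive size factors, product one.
#' @export
#' @examples
#' computeSizeFactors(rbind(a = c(2, 2), b = c(8, 8)))  # 0.5, 2
computeSizeFactors <- function(x) {
  counts <- .countsMatrix(x)
  tot <- as.numeric(Matrix::rowSums(counts))
  ids <- rownames(counts)
  if (is.null(ids)) ids <- paste0("spot_", seq_along(tot))
  if (any(tot <= 0)) {
    stop("spots with zero total count: ",
         paste(ids[tot <= 0], collapse = ", "),
         "; remove them before computing size factors")
  }
  s <- tot / exp(mean(log(tot)))
  stopifnot(abs(prod(s)^(1 / length(s)) - 1) < 1e-8)
  stats::setNames(s, ids)
}

#' Drop spots whose total count is zero
#'
#' Size factors are undefined for empty spots; this removes them with a
#' warning naming the dropped spot ids.
#'
#' @param profile a [MolecularProfile].
#' @return the profile restricted to spots with positive total count.
#' @export
dropEmptySpots <- function(profile) {
  tot <- as.numeric(Matrix::rowSums(spotCounts(profile)))
  bad <- tot <= 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " spot(s) with zero total count: ",
            paste(utils::head(spotIds(profile)[bad], 10L), collapse = ", "))
    profile <- subsetProfile(profile, spots = which(!bad))
  }
  profile
}

#' Filter genes by spot prevalence
#'
#' Keeps genes with a non-zero count in at least a fraction `minFrac` of
#' spots. `minFrac = 0.5` is the setting used to pick validation genes on
#' Visium data.
#'
#' @param x a [MolecularProfile] or spots-by-genes count matrix.
#' @param minFrac required fraction of spots with a non-zero count, in (0, 1].
#' @return integer indices of the retained genes (original order), named by
#'   gene id when available.
#' @export
filterGenesSpotPrevalence <- function(x, minFrac = 0.5) {
  stopifnot(is.numeric(minFrac), length(minFrac) == 1L,
            minFrac > 0, minFrac <= 1)
  counts <- .countsMatrix(x)
  frac <- as.numeric(Matrix::colSums(counts > 0)) / nrow(counts)
  keep <- which(frac >= minFrac)
  names(keep) <- colnames(counts)[keep]
  keep
}

#' Filter genes of a cell-resolution count matrix
#'
#' Keeps genes expressed (count > 0) in at least a fraction `minCellFrac` of
#' cells and whose maximum count is at least `minMaxCount`. The defaults
#' (0.3, 10) reproduce the filter used on imaging-based SRT data.
#'
#' @param cellCounts cells-by-genes non-negative integer matrix.
#' @param minCellFrac required expressed fraction of cells, in (0, 1].
#' @param minMaxCount required maximum count, non-negative integer.
#' @return integer indices of the retained genes, named by gene id when
#'   available.
#' @export
filterGenesCellwise <- function(cellCounts, minCellFrac = 0.3,
                                minMaxCount = 10L) {
  stopifnot(minCellFrac > 0, minCellFrac <= 1, minMaxCount >= 0)
  if (!length(cellCounts) || nrow(cellCounts) == 0L || ncol(cellCounts) == 0L) {
    stop("cellCounts is empty")
  }
  frac <- as.numeric(Matrix::colSums(cellCounts > 0)) / nrow(cellCounts)
  mx <- apply(as.matrix(cellCounts), 2L, max)
  keep <- which(frac >= minCellFrac & mx >= minMaxCount)
  names(keep) <- colnames(cellCounts)[keep]
  keep
}

# --- cell-table handling ----------------------------------------------------

#' Build an ImageProfile from a cell table
#'
#' The table must contain columns `cell_id`, `x`, `y`, `cell_type`; every
#' remaining column is treated as a continuous covariate. The cell-type
#' column is expanded into one-hot dummy columns in sorted label order
#' (`celltype_<label>`), and continuous covariates are z-scored by default,
#' with the transform stored for reuse at prediction time.
#'
#' @param cells data.frame as described above.
#' @param standardize logical; z-score continuous covariates (default TRUE).
#' @return an [ImageProfile].
#' @export
imageProfileFromTable <- function(cells, standardize = TRUE) {
  required <- c("cell_id", "x", "y", "cell_type")
  missing <- setdiff(required, colnames(cells))
  if (length(missing)) {
    stop("cell table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(cells$cell_id)) stop("duplicated cell_id values")
  labels <- sort(unique(as.character(cells$cell_type)))
  dummies <- vapply(labels, function(lb) {
    as.numeric(cells$cell_type == lb)
  }, numeric(nrow(cells)))
  dummies <- matrix(dummies, nrow = nrow(cells),
                    dimnames = list(NULL, paste0("celltype_", labels)))
  contCols <- setdiff(colnames(cells), required)
  cont <- as.matrix(cells[, contCols, drop = FALSE])
  if (length(contCols) && !is.numeric(cont)) {
    stop("continuous covariate columns must be numeric: ",
         paste(contCols, collapse = ", "))
  }
  std <- list(applied = FALSE)
  if (standardize && length(contCols)) {
    ctr <- colMeans(cont)
    scl <- apply(cont, 2L, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    cont <- sweep(sweep(cont, 2L, ctr, "-"), 2L, scl, "/")
    std <- list(applied = TRUE, center = ctr, scale = scl)
  }
  X <- cbind(dummies, cont)
  rownames(X) <- as.character(cells$cell_id)
  ImageProfile(X, cbind(cells$x, cells$y),
               celltypeColumns = seq_along(labels),
               continuousColumns = length(labels) + seq_along(contCols),
               standardization = std)
}

#' Reverse an ImageProfile back into a cell table
#'
#' Inverts the one-hot expansion and any stored standardization, so that
#' `imageProfileFromTable(imageProfileToTable(x))` round-trips.
#'
#' @param image an [ImageProfile].
#' @return data.frame with columns `cell_id`, `x`, `y`, `cell_type` and one
#'   column per continuous covariate on its original scale.
#' @export
imageProfileToTable <- function(image) {
  X <- cellCovariates(image)
  ct <- celltypeColumns(image)
  labels <- sub("^celltype_", "", colnames(X)[ct])
  type <- labels[max.col(X[, ct, drop = FALSE])]
  cont <- X[, continuousColumns(image), drop = FALSE]
  std <- image@standardization
  if (isTRUE(std$applied) && ncol(cont)) {
    cont <- sweep(sweep(cont, 2L, std$scale, "*"), 2L, std$center, "+")
  }
  coords <- cellCoords(image)
  out <- data.frame(cell_id = cellIds(image), x = coords[, 1L],
                    y = coords[, 2L], cell_type = type,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(cont))
}

# --- readers ----------------------------------------------------------------

.readCounts <- function(countsPath, barcodesPath, featuresPath) {
  if (grepl("\\.mtx$", countsPath)) {
    if (is.null(barcodesPath) || is.null(featuresPath)) {
      stop("MTX counts require barcodesPath and featuresPath")
    }
    m <- Matrix::readMM(countsPath)  # features x barcodes (10x orientation)
    barcodes <- readLines(barcodesPath)
    features <- readLines(featuresPath)
    if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
      stop("MTX dimensions (", nrow(m), " x ", ncol(m),
           ") do not match features/barcodes lengths")
    }
    counts <- Matrix::t(m)
    dimnames(counts) <- list(barcodes, features)
  } else {
    df <- utils::read.csv(countsPath, row.names = 1L, check.names = FALSE)
    counts <- as.matrix(df)
  }
  counts
}

.readPositions <- function(positionsPath) {
  pos <- utils::read.csv(positionsPath, check.names = FALSE)
  tenx <- c("barcode", "in_tissue", "array_row", "array_col",
            "pxl_row_in_fullres", "pxl_col_in_fullres")
  if (all(tenx %in% colnames(pos))) {
    pos <- pos[pos$in_tissue == 1, , drop = FALSE]
    data.frame(barcode = pos$barcode, pixel_x = pos$pxl_col_in_fullres,
               pixel_y = pos$pxl_row_in_fullres, stringsAsFactors = FALSE)
  } else {
    need <- c("barcode", "pixel_x", "pixel_y")
    missing <- setdiff(need, colnames(pos))
    if (length(missing)) {
      stop("positions file is missing column(s): ",
           paste(missing, collapse = ", "))
    }
    pos[, need]
  }
}

#' Load the molecular and image profiles from disk
#'
#' Reads spot counts (MatrixMarket MTX with barcode/feature lists, or a dense
#' CSV with gene ids in the header and spot ids in the first column), spot
#' positions (plain `barcode, pixel_x, pixel_y` CSV or the 10x
#' `tissue_positions` dialect, of which only `in_tissue == 1` rows are used),
#' the spot diameter (argument, or the `spot_diameter_fullres` key of a
#' scale-factor JSON), and the per-cell covariate table.
#'
#' @param countsPath path to `.mtx` or `.csv` counts.
#' @param positionsPath path to the spot positions CSV.
#' @param cellsPath path to the cell table CSV (`cell_id, x, y, cell_type`,
#'   then one column per continuous feature).
#' @param spotDiameter numeric; overrides `scalefactorsPath`.
#' @param scalefactorsPath path to a JSON with key `spot_diameter_fullres`.
#' @param barcodesPath,featuresPath required with MTX counts.
#' @param standardize passed to [imageProfileFromTable()].
#' @return `list(molecular = MolecularProfile, image = ImageProfile)`.
#' @export
loadProfiles <- function(countsPath, positionsPath, cellsPath,
                         spotDiameter = NULL, scalefactorsPath = NULL,
                         barcodesPath = NULL, featuresPath = NULL,
                         standardize = TRUE) {
  for (p in c(countsPath, positionsPath, cellsPath)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  counts <- .readCounts(countsPath, barcodesPath, featuresPath)
  pos <- .readPositions(positionsPath)
  missingSpots <- setdiff(rownames(counts), pos$barcode)
  if (length(missingSpots)) {
    stop("no position for spot(s): ",
         paste(utils::head(missingSpots, 5L), collapse = ", "))
  }
  pos <- pos[match(rownames(counts), pos$barcode), , drop = FALSE]
  if (is.null(spotDiameter)) {
    if (is.null(scalefactorsPath)) {
      stop("provide spotDiameter or scalefactorsPath")
    }
    sf <- jsonlite::read_json(scalefactorsPath)
    if (is.null(sf$spot_diameter_fullres)) {
      stop("scale-factor JSON lacks key 'spot_diameter_fullres'")
    }
    spotDiameter <- as.numeric(sf$spot_diameter_fullres)
  }
  molecular <- MolecularProfile(counts,
                                cbind(pos$pixel_x, pos$pixel_y),
                                spotDiameter)
  cells <- utils::read.csv(cellsPath, check.names = FALSE)
  image <- imageProfileFromTable(cells, standardize = standardize)
  list(molecular = molecular, image = image)
}

#' Persist the molecular and image profiles to a directory
#'
#' Writes `matrix.mtx` (genes by spots), `barcodes.tsv`, `features.tsv`,
#' `positions.csv`, `scalefactors.json` and `cells.csv` so that
#' [loadProfiles()] on the directory round-trips.
#'
#' @param molecular a [MolecularProfile].
#' @param image an [ImageProfile].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
writeProfiles <- function(molecular, image, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cnt <- assay(molecular, "counts")  # genes x spots
  Matrix::writeMM(as(as(cnt, "dMatrix"), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(cnt), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(cnt), file.path(dir, "features.tsv"))
  coords <- spotCoords(molecular)
  utils::write.csv(data.frame(barcode = spotIds(molecular),
                              pixel_x = coords[, 1L], pixel_y = coords[, 2L]),
                   file.path(dir, "positions.csv"), row.names = FALSE)
  jsonlite::write_json(list(spot_diameter_fullres = spotDiameter(molecular)),
                       file.path(dir, "scalefactors.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(imageProfileToTable(image), file.path(dir, "cells.csv"),
                   row.names = FALSE)
  invisible(dir)
}
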