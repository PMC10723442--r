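# Spot-cell geometry: disc membership for array spots, and square binning of
# imaging-based single-cell data into pseudo-spots.

#' Assign cells to spots by the disc-membership rule
#'
#' A cell belongs to a spot when its Euclidean distance to the spot center is
#' at most half the spot diameter (boundary inclusive). Physical array spots
#' do not overlap, so a cell lying within two discs is an error by default;
#' set `tieBreak = TRUE` to assign such cells to the nearest center instead.
#'
#' @param spotCoords N-by-2 spot-center coordinates, or a [MolecularProfile].
#' @param spotDiameter positive scalar (ignored when `spotCoords` is a
#'   [MolecularProfile]).
#' @param cellCoords M-by-2 cell coordinates, or an [ImageProfile].
#' @param tieBreak logical; resolve multi-spot cells by nearest center.
#' @param spotIds,cellIds optional id vectors (defaults: rownames, else
#'   generated).
#' @return a [GeospatialProfile].
#' @export
#' @examples
#' geo <- assignCellsToSpots(rbind(c(0, 0), c(100, 0)), 55,
#'                           rbind(c(10, 0), c(60, 0)))
#' cellsPerSpot(geo)
assignCellsToSpots <- function(spotCoords, spotDiameter = NULL, cellCoords,
                               tieBreak = FALSE, spotIds = NULL,
                               cellIds = NULL) {
  if (is(spotCoords, "MolecularProfile")) {
    if (is.null(spotDiameter)) spotDiameter <- spotDiameter(spotCoords)
    if (is.null(spotIds)) spotIds <- spotIds(spotCoords)
    spotCoords <- spotCoords(spotCoords)
  }
  if (is(cellCoords, "ImageProfile")) {
    if (is.null(cellIds)) cellIds <- cellIds(cellCoords)
    cellCoords <- cellCoords(cellCoords)
  }
  spotCoords <- as.matrix(spotCoords)
  cellCoords <- as.matrix(cellCoords)
  stopifnot(is.numeric(spotDiameter), length(spotDiameter) == 1L,
            spotDiameter > 0, ncol(spotCoords) == 2L, ncol(cellCoords) == 2L)
  if (is.null(spotIds)) {
    spotIds <- rownames(spotCoords)
    if (is.null(spotIds)) spotIds <- paste0("spot_", seq_len(nrow(spotCoords)))
  }
  if (is.null(cellIds)) {
    cellIds <- rownames(cellCoords)
    if (is.null(cellIds)) cellIds <- paste0("cell_", seq_len(nrow(cellCoords)))
  }
  r2 <- (spotDiameter / 2)^2
  N <- nrow(spotCoords)
  M <- nrow(cellCoords)
  ii <- jj <- vector("list", N)
  for (i in seq_len(N)) {
    d2 <- (cellCoords[, 1L] - spotCoords[i, 1L])^2 +
      (cellCoords[, 2L] - spotCoords[i, 2L])^2
    hit <- which(d2 <= r2 + 1e-9)
    ii[[i]] <- rep.int(i, length(hit))
    jj[[i]] <- hit
  }
  ii <- unlist(ii)
  jj <- unlist(jj)
  dup <- unique(jj[duplicated(jj)])
  if (length(dup)) {
    if (!tieBreak) {
      stop("cell(s) within d/2 of more than one spot center (overlapping ",
           "spots): ", paste(utils::head(cellIds[dup], 5L), collapse = ", "),
           "; set tieBreak = TRUE to assign to the nearest center")
    }
    for (m in dup) {
      cand <- which(jj == m)
      d2 <- (spotCoords[ii[cand], 1L] - cellCoords[m, 1L])^2 +
        (spotCoords[ii[cand], 2L] - cellCoords[m, 2L])^2
      drop <- cand[-which.min(d2)]
      ii <- ii[-drop]
      jj <- jj[-drop]
    }
  }
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(N, M),
                            dimnames = list(spotIds, cellIds))
  GeospatialProfile(G)
}

#' Bin single-cell counts into square pseudo-spots
#'
#' Partitions the plane into axis-aligned squares of side `binSize` with
#' half-open intervals `[k*b, (k+1)*b)` anchored at the minimum x/y of the
#' cell cloud. Every square containing more than one cell becomes a
#' pseudo-spot whose counts are the per-gene sums over its member cells and
#' whose center is the square center; squares with at most one cell are
#' discarded. The recorded "diameter" of the pseudo-spots is the bin size, so
#' downstream code treats both spot kinds uniformly.
#'
#' @param cellCoords M-by-2 cell coordinates.
#' @param cellCounts M-by-P cells-by-genes non-negative integer matrix.
#' @param binSize positive square side, pixels (e.g. 750).
#' @return `list(molecular = MolecularProfile, geospatial = GeospatialProfile)`;
#'   the geospatial profile covers all M cells (cells in discarded squares
#'   are uncovered).
#' @export
binCellsIntoGridSpots <- function(cellCoords, cellCounts, binSize) {
  stopifnot(is.numeric(binSize), length(binSize) == 1L, binSize > 0)
  cellCoords <- as.matrix(cellCoords)
  cellCounts <- as.matrix(cellCounts)
  stopifnot(nrow(cellCoords) == nrow(cellCounts))
  cellIds <- rownames(cellCounts)
  if (is.null(cellIds)) cellIds <- paste0("cell_", seq_len(nrow(cellCounts)))
  geneIds <- colnames(cellCounts)
  if (is.null(geneIds)) geneIds <- paste0("gene_", seq_len(ncol(cellCounts)))
  origin <- c(min(cellCoords[, 1L]), min(cellCoords[, 2L]))
  bx <- floor((cellCoords[, 1L] - origin[1L]) / binSize)
  by <- floor((cellCoords[, 2L] - origin[2L]) / binSize)
  key <- paste(bx, by, sep = "_")
  tab <- table(key)
  retained <- names(tab)[tab > 1L]
  if (!length(retained)) {
    stop("no square bin retains more than one cell; increase binSize")
  }
  retained <- sort(retained)
  counts <- rowsum(cellCounts[key %in% retained, , drop = FALSE],
                   group = key[key %in% retained])
  counts <- counts[retained, , drop = FALSE]
  kk <- do.call(rbind, strsplit(retained, "_", fixed = TRUE))
  centers <- cbind(origin[1L] + (as.numeric(kk[, 1L]) + 0.5) * binSize,
                   origin[2L] + (as.numeric(kk[, 2L]) + 0.5) * binSize)
  spotIds <- paste0("bin_", retained)
  rownames(counts) <- spotIds
  colnames(counts) <- geneIds
  molecular <- MolecularProfile(counts, centers, binSize)
  inBin <- key %in% retained
  G <- Matrix::sparseMatrix(i = match(key[inBin], retained),
                            j = which(inBin), x = 1,
                            dims = c(length(retained), length(cellIds)),
                            dimnames = list(spotIds, cellIds))
  list(molecular = molecular, geospatial = GeospatialProfile(G))
}

#' Write a GeospatialProfile to disk
#'
#' Emits a coordinate-list CSV (`spot_id, cell_id`) and a JSON summary with
#' the spot count, cell count, number of uncovered cells and mean cells per
#' spot.
#'
#' @param geo a [GeospatialProfile].
#' @param csvPath,jsonPath output paths.
#' @return invisibly, the CSV path.
#' @export
writeGeospatialProfile <- function(geo, csvPath, jsonPath) {
  G <- membership(geo)
  idx <- Matrix::which(G == 1, arr.ind = TRUE)
  df <- data.frame(spot_id = rownames(G)[idx[, 1L]],
                   cell_id = colnames(G)[idx[, 2L]],
                   stringsAsFactors = FALSE)
  df <- df[order(df$spot_id, df$cell_id), , drop = FALSE]
  utils::write.csv(df, csvPath, row.names = FALSE)
  jsonlite::write_json(list(n_spots = nrow(G), n_cells = ncol(G),
                            n_uncovered_cells = length(uncoveredCells(geo)),
                            mean_cells_per_spot = mean(cellsPerSpot(geo))),
                       jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(csvPath)
}
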