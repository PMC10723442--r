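#' @name SpotRecon-generics
#' @title Accessor generics for SpotRecon data containers
#' @description Accessors for the three profile classes. Slots are never
#'   accessed directly by user code.
#' @param x a SpotRecon container object
#' @keywords internal
NULL

#' @rdname SpotRecon-generics
#' @export
setGeneric("spotCounts", function(x) standardGeneric("spotCounts"))

#' @rdname SpotRecon-generics
#' @export
setGeneric("spotCoords", function(x) standardGeneric("spotCoords"))

#' @rdname SpotRecon-generics
#' @export
setGeneric("spotDiameter", function(x) standardGeneric("spotDiameter"))

#' @rdname SpotRecon-generics
#' @export
setGeneric("spotIds", function(x) standardGeneric("spotIds"))

#' @rdname SpotRecon-generics
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname SpotRecon-generics
#' @export
setGeneric("nSpots", function(x) standardGeneric("nSpots"))

#' @rdname SpotRecon-generics
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname SpotRecon-generics
#' @export
setGeneric("cellCovariates", function(x) standardGeneric("cellCovariates"))

#' @rdname SpotRecon-generics
#' @export
setGeneric("cellCoords", function(x) standardGeneric("cellCoords"))

#' @rdname SpotRecon-generics
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname SpotRecon-generics
#' @export
setGeneric("covariateNames", function(x) standardGeneric("covariateNames"))

#' @rdname SpotRecon-generics
#' @export
setGeneric("celltypeColumns", function(x) standardGeneric("celltypeColumns"))

#' @rdname SpotRecon-generics
#' @export
setGeneric("continuousColumns", function(x) standardGeneric("continuousColumns"))

#' @rdname SpotRecon-generics
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname SpotRecon-generics
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname SpotRecon-generics
#' @export
setGeneric("cellsPerSpot", function(x) standardGeneric("cellsPerSpot"))

#' @rdname SpotRecon-generics
#' @export
setGeneric("uncoveredCells", function(x) standardGeneric("uncoveredCells"))

#' @rdname SpotRecon-generics
#' @export
setGeneric("spotMembers", function(x) standardGeneric("spotMembers"))
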