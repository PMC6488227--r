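#' @name mirSpan-accessors
#' @title Accessors for mirSpan classes
#'
#' @description Small accessor generics: \code{genes()} returns the gene
#' symbols of an object, \code{nodeCount()}/\code{edgeCount()} its graph
#' dimensions, \code{sourceCounts()} the input provenance counts of an
#' \linkS4class{Interactome}, \code{seedGenes()}/\code{isSeed()} the seed
#' annotation of a \linkS4class{SeedNetwork},
#' \code{mappedSeeds()}/\code{unmappedSeeds()} the two halves of a
#' \linkS4class{SeedSet}, \code{moduleAssignment()}/\code{nModules()}/
#' \code{modularityValue()} the contents of a
#' \linkS4class{ModulePartition}, and \code{familyIds()},
#' \code{seedSequences()}, \code{familyMembers()}, \code{familyTargets()},
#' \code{geneSetNames()}, \code{geneSetGenes()} the contents of the two
#' collection classes.
#'
#' @param x an object of the documented class.
#' @param id a family or set identifier (or index).
#' @return The corresponding slot contents (see Description).
#'
#' @aliases genes nodeCount edgeCount sourceCounts seedGenes isSeed
#'   mappedSeeds unmappedSeeds moduleAssignment nModules modularityValue
#'   familyIds seedSequences familyMembers familyTargets geneSetNames
#'   geneSetGenes
#' @examples
#' ia <- exampleInteractome()
#' genes(ia); edgeCount(ia); sourceCounts(ia)
NULL

#' @rdname mirSpan-accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname mirSpan-accessors
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))
#' @rdname mirSpan-accessors
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))
#' @rdname mirSpan-accessors
#' @export
setGeneric("sourceCounts", function(x) standardGeneric("sourceCounts"))
#' @rdname mirSpan-accessors
#' @export
setGeneric("seedGenes", function(x) standardGeneric("seedGenes"))
#' @rdname mirSpan-accessors
#' @export
setGeneric("isSeed", function(x) standardGeneric("isSeed"))
#' @rdname mirSpan-accessors
#' @export
setGeneric("mappedSeeds", function(x) standardGeneric("mappedSeeds"))
#' @rdname mirSpan-accessors
#' @export
setGeneric("unmappedSeeds", function(x) standardGeneric("unmappedSeeds"))
#' @rdname mirSpan-accessors
#' @export
setGeneric("moduleAssignment", function(x) standardGeneric("moduleAssignment"))
#' @rdname mirSpan-accessors
#' @export
setGeneric("nModules", function(x) standardGeneric("nModules"))
#' @rdname mirSpan-accessors
#' @export
setGeneric("modularityValue", function(x) standardGeneric("modularityValue"))
#' @rdname mirSpan-accessors
#' @export
setGeneric("familyIds", function(x) standardGeneric("familyIds"))
#' @rdname mirSpan-accessors
#' @export
setGeneric("seedSequences", function(x) standardGeneric("seedSequences"))
#' @rdname mirSpan-accessors
#' @export
setGeneric("familyMembers", function(x, id) standardGeneric("familyMembers"))
#' @rdname mirSpan-accessors
#' @export
setGeneric("familyTargets", function(x, id) standardGeneric("familyTargets"))
#' @rdname mirSpan-accessors
#' @export
setGeneric("geneSetNames", function(x) standardGeneric("geneSetNames"))
#' @rdname mirSpan-accessors
#' @export
setGeneric("geneSetGenes", function(x, id) standardGeneric("geneSetGenes"))
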