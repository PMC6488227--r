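# accessor and show methods

#' @rdname mirSpan-accessors
#' @export
setMethod("genes", "Interactome", function(x) x@nodes)
#' @rdname mirSpan-accessors
#' @export
setMethod("genes", "SeedNetwork", function(x) x@nodes)
#' @rdname mirSpan-accessors
#' @export
setMethod("genes", "GeneSetCollection",
          function(x) sort(unique(unlist(x@genes, use.names = FALSE))))

#' @rdname mirSpan-accessors
#' @export
setMethod("nodeCount", "Interactome", function(x) length(x@nodes))
#' @rdname mirSpan-accessors
#' @export
setMethod("nodeCount", "SeedNetwork", function(x) length(x@nodes))
#' @rdname mirSpan-accessors
#' @export
setMethod("edgeCount", "Interactome", function(x) nrow(x@edges))
#' @rdname mirSpan-accessors
#' @export
setMethod("edgeCount", "SeedNetwork", function(x) nrow(x@edges))

#' @rdname mirSpan-accessors
#' @export
setMethod("sourceCounts", "Interactome", function(x) x@sourceCounts)

#' @rdname mirSpan-accessors
#' @export
setMethod("seedGenes", "SeedNetwork", function(x) x@seeds)
#' @rdname mirSpan-accessors
#' @export
setMethod("isSeed", "SeedNetwork",
          function(x) setNames(x@nodes %in% x@seeds, x@nodes))

#' @rdname mirSpan-accessors
#' @export
setMethod("mappedSeeds", "SeedSet", function(x) x@mapped)
#' @rdname mirSpan-accessors
#' @export
setMethod("unmappedSeeds", "SeedSet", function(x) x@unmapped)

#' @rdname mirSpan-accessors
#' @export
setMethod("moduleAssignment", "ModulePartition", function(x) x@assignment)
#' @rdname mirSpan-accessors
#' @export
setMethod("nModules", "ModulePartition", function(x) x@nModules)
#' @rdname mirSpan-accessors
#' @export
setMethod("modularityValue", "ModulePartition", function(x) x@modularity)

#' @rdname mirSpan-accessors
#' @export
setMethod("familyIds", "MirnaFamilySet", function(x) x@familyId)
#' @rdname mirSpan-accessors
#' @export
setMethod("seedSequences", "MirnaFamilySet",
          function(x) setNames(x@seedSequence, x@familyId))

.familyIndex <- function(x, id) {
  i <- if (is.numeric(id)) as.integer(id) else match(id, x@familyId)
  if (is.na(i) || i < 1L || i > length(x@familyId))
    .fatal("unknown family: %s", as.character(id))
  i
}

#' @rdname mirSpan-accessors
#' @export
setMethod("familyMembers", "MirnaFamilySet",
          function(x, id) x@members[[.familyIndex(x, id)]])
#' @rdname mirSpan-accessors
#' @export
setMethod("familyTargets", "MirnaFamilySet",
          function(x, id) x@targets[[.familyIndex(x, id)]])

#' @rdname mirSpan-accessors
#' @export
setMethod("geneSetNames", "GeneSetCollection", function(x) x@setName)
#' @rdname mirSpan-accessors
#' @export
setMethod("geneSetGenes", "GeneSetCollection", function(x, id) {
  i <- if (is.numeric(id)) as.integer(id) else match(id, x@setName)
  if (is.na(i)) .fatal("unknown gene set: %s", as.character(id))
  x@genes[[i]]
})

#' @describeIn MirnaFamilySet-class number of families
#' @param x a \code{MirnaFamilySet}
#' @export
setMethod("length", "MirnaFamilySet", function(x) length(x@familyId))

#' @describeIn GeneSetCollection-class number of gene sets
#' @param x a \code{GeneSetCollection}
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@setName))

setMethod("show", "Interactome", function(object) {
  cat(sprintf("Interactome: %d genes, %d associations\n",
              length(object@nodes), nrow(object@edges)))
  sc <- object@sourceCounts
  if (length(sc))
    cat("  input lines:", paste(names(sc), sc, sep = "=", collapse = ", "),
        "\n")
})

setMethod("show", "SeedSet", function(object) {
  cat(sprintf("SeedSet: %d requested, %d mapped, %d unmapped\n",
              length(object@requested), length(object@mapped),
              length(object@unmapped)))
})

setMethod("show", "SeedNetwork", function(object) {
  cat(sprintf(
    "SeedNetwork: %d genes (%d seeds, %d interactors), %d interactions\n",
    length(object@nodes), length(object@seeds),
    length(object@nodes) - length(object@seeds), nrow(object@edges)))
})

setMethod("show", "ModulePartition", function(object) {
  cat(sprintf("ModulePartition: %d nodes in %d modules, modularity Q = %s\n",
              length(object@assignment), object@nModules,
              format(object@modularity, digits = 4)))
  sz <- table(object@assignment)
  cat("  module sizes:", paste(as.integer(sz), collapse = ", "), "\n")
})

setMethod("show", "MirnaFamilySet", function(object) {
  cat(sprintf("MirnaFamilySet: %d families, %d mature miRNAs\n",
              length(object@familyId), sum(lengths(object@members))))
  if (length(object@familyId)) {
    k <- head(seq_along(object@familyId), 3L)
    for (i in k)
      cat(sprintf("  %s: %d members, %d targets\n", object@familyId[i],
                  length(object@members[[i]]), length(object@targets[[i]])))
    if (length(object@familyId) > 3L) cat("  ...\n")
  }
})

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection: %d sets covering %d genes\n",
              length(object@setName),
              length(unique(unlist(object@genes, use.names = FALSE)))))
})

#' A tiny built-in example interactome
#'
#' Twelve genes: two 4-cliques bridged by one edge, plus a 4-cycle.
#' Used in documentation examples and unit tests.
#'
#' @return An \linkS4class{Interactome}.
#' @export
#' @examples
#' exampleInteractome()
exampleInteractome <- function() {
  cl <- function(g) t(combn(g, 2L))
  e <- rbind(cl(paste0("G", 1:4)), cl(paste0("G", 5:8)),
             c("G4", "G5"),
             cbind(paste0("G", 9:12), paste0("G", c(10:12, 9))))
  e <- .canonEdges(e[, 1], e[, 2])
  new("Interactome", nodes = sort(unique(as.vector(e))), edges = e,
      sourceCounts = c(kept = nrow(e), duplicate = 0L, self_loop = 0L,
                       malformed = 0L))
}
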