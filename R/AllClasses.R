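#' Interactome: an undirected gene-gene association graph
#'
#' The background network and enrichment universe for the whole analysis.
#' Nodes are case-normalized gene symbols; edges are unordered, deduplicated
#' pairs with no self-loops.  \code{sourceCounts} records how many input
#' lines were kept or dropped (and why) when the object was parsed from a
#' file, so provenance survives into downstream reports.
#'
#' @slot nodes character vector of gene symbols (uppercase, unique, sorted).
#' @slot edges two-column character matrix of canonical (min, max) pairs.
#' @slot sourceCounts named integer vector with elements \code{kept},
#'   \code{duplicate}, \code{self_loop}, \code{malformed}.
#'
#' @seealso \code{\link{loadInteractome}}, \code{\link{buildSeedNetwork}}
#' @exportClass Interactome
setClass("Interactome",
  representation(nodes = "character", edges = "matrix",
                 sourceCounts = "integer"))

setValidity("Interactome", function(object) {
  msg <- character()
  e <- object@edges
  if (ncol(e) != 2L) msg <- c(msg, "edges must have exactly 2 columns")
  if (any(duplicated(object@nodes))) msg <- c(msg, "duplicate nodes")
  if (!all(.validGene(object@nodes))) msg <- c(msg, "invalid gene symbols")
  if (nrow(e) > 0L) {
    if (!all(e %in% object@nodes))
      msg <- c(msg, "edge endpoint not in node set")
    if (any(e[, 1] == e[, 2])) msg <- c(msg, "self-loop present")
    if (any(e[, 1] > e[, 2])) msg <- c(msg, "edges not in canonical order")
    if (anyDuplicated(paste(e[, 1], e[, 2])))
      msg <- c(msg, "duplicate edges")
  }
  if (length(msg)) msg else TRUE
})

#' SeedSet: the outcome of mapping requested seed genes to an interactome
#'
#' @slot requested the deduplicated, case-normalized seed symbols in input
#'   order.
#' @slot mapped symbols present in the interactome.
#' @slot unmapped symbols absent from the interactome, in input order.
#'
#' @seealso \code{\link{mapSeeds}}
#' @exportClass SeedSet
setClass("SeedSet",
  representation(requested = "character", mapped = "character",
                 unmapped = "character"))

setValidity("SeedSet", function(object) {
  msg <- character()
  if (!setequal(c(object@mapped, object@unmapped), object@requested))
    msg <- c(msg, "mapped + unmapped must cover exactly the requested set")
  if (length(intersect(object@mapped, object@unmapped)))
    msg <- c(msg, "mapped and unmapped overlap")
  if (length(msg)) msg else TRUE
})

#' SeedNetwork: seeds plus their first-degree interactors
#'
#' The disease-associated subnetwork: every mapped seed together with all of
#' its direct interactome neighbours, and (by default) every interactome
#' edge between the retained nodes.
#'
#' @slot nodes character vector of network gene symbols.
#' @slot edges two-column canonical edge matrix (subset of the parent's).
#' @slot seeds character vector of the mapped seed symbols (subset of
#'   \code{nodes}).
#' @slot parent the source \linkS4class{Interactome}.
#'
#' @seealso \code{\link{buildSeedNetwork}}, \code{\link{spectralPartition}}
#' @exportClass SeedNetwork
setClass("SeedNetwork",
  representation(nodes = "character", edges = "matrix",
                 seeds = "character", parent = "Interactome"))

setValidity("SeedNetwork", function(object) {
  msg <- character()
  if (!all(object@seeds %in% object@nodes))
    msg <- c(msg, "seed not in node set")
  if (!all(object@nodes %in% object@parent@nodes))
    msg <- c(msg, "node not in parent interactome")
  if (nrow(object@edges) > 0L) {
    key <- function(e) paste(e[, 1], e[, 2])
    if (!all(key(object@edges) %in% key(object@parent@edges)))
      msg <- c(msg, "edge not present in parent interactome")
  }
  if (length(msg)) msg else TRUE
})

#' ModulePartition: a clustering of network nodes into modules
#'
#' Module indices are 0-based and contiguous; modules are labelled in
#' decreasing size order (ties broken by the lexicographically smallest
#' member symbol).  \code{modularity} is the Newman-Girvan Q of the
#' partition, or \code{NA} for an edgeless network.
#'
#' @slot assignment named integer vector, node symbol -> module index.
#' @slot nModules number of modules.
#' @slot modularity Newman-Girvan modularity of the partition.
#'
#' @seealso \code{\link{spectralPartition}}, \code{\link{networkModularity}}
#' @exportClass ModulePartition
setClass("ModulePartition",
  representation(assignment = "integer", nModules = "integer",
                 modularity = "numeric"))

setValidity("ModulePartition", function(object) {
  msg <- character()
  a <- object@assignment
  if (is.null(names(a)) || any(!nzchar(names(a))))
    msg <- c(msg, "assignment must be named by node symbol")
  if (length(a) && !identical(sort(unique(as.integer(a))),
                              seq_len(object@nModules) - 1L))
    msg <- c(msg, "module indices must be 0..nModules-1 with no gaps")
  q <- object@modularity
  if (!is.na(q) && (q < -0.5 - 1e-12 || q > 1 + 1e-12))
    msg <- c(msg, "modularity outside [-0.5, 1]")
  if (length(msg)) msg else TRUE
})

#' MirnaFamilySet: named miRNA families with target gene sets
#'
#' A parallel-slot container (one element per family).  \code{seedSequence}
#' holds the 7-nt seed (mature positions 2-8) when known and \code{NA} when
#' the families were aggregated from a target table that carries no mature
#' sequence.
#'
#' @slot familyId character vector of family labels.
#' @slot seedSequence character vector of 7-mers over A/C/G/U, or NA.
#' @slot members list of character vectors of mature miRNA names.
#' @slot targets list of character vectors of target gene symbols.
#'
#' @seealso \code{\link{loadMirnaTargets}}, \code{\link{groupFamiliesBySeed}}
#' @exportClass MirnaFamilySet
setClass("MirnaFamilySet",
  representation(familyId = "character", seedSequence = "character",
                 members = "list", targets = "list"))

setValidity("MirnaFamilySet", function(object) {
  msg <- character()
  n <- length(object@familyId)
  if (length(object@seedSequence) != n || length(object@members) != n ||
      length(object@targets) != n)
    msg <- c(msg, "slots must have one element per family")
  if (anyDuplicated(object@familyId)) msg <- c(msg, "duplicate family ids")
  ss <- object@seedSequence[!is.na(object@seedSequence)]
  if (length(ss) && !all(nchar(ss) == 7L & grepl("^[ACGU]+$", ss)))
    msg <- c(msg, "seed sequences must be 7-mers over A/C/G/U")
  if (n && any(lengths(object@members) == 0L))
    msg <- c(msg, "every family needs at least one member")
  if (length(msg)) msg else TRUE
})

#' GeneSetCollection: named gene sets with descriptions
#'
#' @slot setName unique set names.
#' @slot description one description per set.
#' @slot genes list of character vectors (uppercased, deduplicated,
#'   non-empty).
#'
#' @seealso \code{\link{loadGmt}}, \code{\link{hallmarkEnrichment}}
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
  representation(setName = "character", description = "character",
                 genes = "list"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (anyDuplicated(object@setName)) msg <- c(msg, "duplicate set names")
  if (length(object@description) != length(object@setName) ||
      length(object@genes) != length(object@setName))
    msg <- c(msg, "slots must have one element per set")
  if (length(object@genes) && any(lengths(object@genes) == 0L))
    msg <- c(msg, "empty gene set")
  if (length(msg)) msg else TRUE
})
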