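# network_build: seed mapping and the seed + first-degree-interactor network

#' Map seed genes onto an interactome
#'
#' Intersects a requested seed list with the interactome node set.  Input
#' symbols are case-normalized and deduplicated (first occurrence wins);
#' unmapped symbols are reported in input order.  Zero mapped seeds is
#' fatal — no network can be anchored.
#'
#' @param interactome an \linkS4class{Interactome}.
#' @param seeds character vector of requested seed symbols.
#' @return A \linkS4class{SeedSet}.
#' @export
mapSeeds <- function(interactome, seeds) {
  stopifnot(is(interactome, "Interactome"))
  if (!length(seeds)) .fatal("seed list is empty")
  req <- unique(.normGene(seeds))
  bad <- !.validGene(req)
  if (any(bad)) .fatal("invalid seed symbol(s): %s",
                       paste(req[bad], collapse = ", "))
  inNet <- req %in% interactome@nodes
  if (!any(inNet))
    .fatal("none of the %d seed genes map to the interactome; unmapped: %s",
           length(req), paste(head(req, 20L), collapse = ", "))
  new("SeedSet", requested = req, mapped = req[inNet],
      unmapped = req[!inNet])
}

#' Build the seed + first-degree-interactor network
#'
#' The node set is every mapped seed together with all of its direct
#' interactome neighbours.  With \code{edgeRule = "induced"} (default) the
#' edge set is the full induced subgraph on those nodes, so
#' interactor-interactor edges — the substrate of module structure among
#' non-seeds — are retained.  \code{"seed_incident"} keeps only edges with
#' at least one seed endpoint, for sensitivity analysis.  Isolated mapped
#' seeds (degree 0 in the interactome) are retained.
#'
#' @param interactome an \linkS4class{Interactome}.
#' @param seedset a \linkS4class{SeedSet} from \code{\link{mapSeeds}} (a
#'   plain character vector of mapped symbols is also accepted).
#' @param edgeRule \code{"induced"} or \code{"seed_incident"}.
#' @param minSeedLinks optional minimum number of seed neighbours an
#'   interactor must have to be retained (default 1; seeds are always
#'   kept).  Values above 1 prune weakly attached interactors.
#' @return A \linkS4class{SeedNetwork}.
#'
#' @examples
#' ia <- exampleInteractome()
#' ss <- mapSeeds(ia, c("G1", "G5", "ZZZ9"))
#' net <- buildSeedNetwork(ia, ss)
#' net
#' @export
buildSeedNetwork <- function(interactome, seedset,
                             edgeRule = c("induced", "seed_incident"),
                             minSeedLinks = 1L) {
  stopifnot(is(interactome, "Interactome"))
  edgeRule <- match.arg(edgeRule)
  mapped <- if (is(seedset, "SeedSet")) seedset@mapped
            else unique(.normGene(seedset))
  if (!length(mapped)) .fatal("no mapped seeds")
  if (!all(mapped %in% interactome@nodes))
    .fatal("seed(s) not present in interactome")
  e <- interactome@edges
  inc <- e[, 1] %in% mapped | e[, 2] %in% mapped
  nbr <- setdiff(unique(as.vector(e[inc, , drop = FALSE])), mapped)
  if (minSeedLinks > 1L && length(nbr)) {
    ei <- e[inc, , drop = FALSE]
    cnt <- table(c(ei[ei[, 2] %in% mapped, 1], ei[ei[, 1] %in% mapped, 2]))
    nbr <- nbr[nbr %in% names(cnt)[cnt >= minSeedLinks]]
  }
  V <- sort(unique(c(mapped, nbr)))
  keep <- if (edgeRule == "induced") {
    e[, 1] %in% V & e[, 2] %in% V
  } else {
    inc & e[, 1] %in% V & e[, 2] %in% V
  }
  new("SeedNetwork", nodes = V, edges = e[keep, , drop = FALSE],
      seeds = sort(mapped), parent = interactome)
}

#' Summarise a seed network
#'
#' @param net a \linkS4class{SeedNetwork}.
#' @return A one-row data.frame: node, edge, seed and non-seed counts,
#'   degree statistics (min/median/mean/max) and the number of connected
#'   components.
#' @export
networkSummary <- function(net) {
  stopifnot(is(net, "SeedNetwork"))
  deg <- setNames(numeric(length(net@nodes)), net@nodes)
  if (nrow(net@edges)) {
    t1 <- table(net@edges[, 1]); t2 <- table(net@edges[, 2])
    deg[names(t1)] <- deg[names(t1)] + as.numeric(t1)
    deg[names(t2)] <- deg[names(t2)] + as.numeric(t2)
  }
  comp <- igraph::components(.asIgraph(net@nodes, net@edges))$no
  data.frame(
    n_nodes = length(net@nodes),
    n_edges = nrow(net@edges),
    n_seeds = length(net@seeds),
    n_interactors = length(net@nodes) - length(net@seeds),
    degree_min = min(deg), degree_median = stats::median(deg),
    degree_mean = mean(deg), degree_max = max(deg),
    n_components = comp)
}
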