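# ranking: hypergeometric enrichment, the spanning score, family ranking
# and hallmark-style gene-set enrichment

#' Upper-tail hypergeometric probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(\eqn{N, K, n}): the
#' probability of observing at least \eqn{k} category members when drawing
#' \eqn{n} items without replacement from a universe of \eqn{N} containing
#' \eqn{K} category members.  Computed through \code{stats::phyper}, which
#' works on log scale internally; \eqn{P(X \ge 0) = 1} exactly.
#'
#' @param N universe size.
#' @param K category size (\eqn{K \le N}).
#' @param n draw size (\eqn{n \le N}).
#' @param k observed overlap (\eqn{0 \le k \le \min(K, n)}).
#' @return The upper-tail p-value, in \eqn{(0, 1]}.
#'
#' @examples
#' hypergeomUpperTail(10, 4, 5, 3)   # 66/252
#' @export
hypergeomUpperTail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > K || k > n)
    .fatal("invalid hypergeometric counts: N=%s K=%s n=%s k=%s", N, K, n, k)
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

.enrichResult <- function(N, K, n, k, overlap = character()) {
  list(N = N, K = K, n = n, k = k,
       p = hypergeomUpperTail(N, K, n, k), overlap = overlap)
}

#' Cross-reference one miRNA family to a clustered network
#'
#' Computes the family's hypergeometric enrichment network-wide and within
#' each module.  The universe is the full interactome gene set
#' (\code{universe = "interactome"}); \code{"targets"} restricts the
#' universe to interactome genes, for sensitivity analysis, after
#' intersecting with a supplied target-space gene vector.  A family with
#' no interactome targets is a valid input and returns \eqn{p = 1}
#' everywhere.
#'
#' @param targets character vector of target gene symbols (or a
#'   \linkS4class{MirnaFamilySet} plus \code{familyId}).
#' @param interactome the \linkS4class{Interactome} universe.
#' @param net the \linkS4class{SeedNetwork}.
#' @param clustering a \linkS4class{ModulePartition} covering \code{net}.
#' @param familyId when \code{targets} is a \code{MirnaFamilySet}, which
#'   family to profile.
#' @param universe \code{"interactome"} (default) or a character vector of
#'   gene symbols to intersect the universe with.
#' @return A list with elements \code{network} (a list \code{N, K, n, k,
#'   p, overlap}) and \code{clusters} (a data.frame with one row per
#'   module: \code{module, size, k, p}).
#' @export
mirnaEnrichmentProfile <- function(targets, interactome, net, clustering,
                                   familyId = NULL,
                                   universe = "interactome") {
  if (is(targets, "MirnaFamilySet")) {
    if (is.null(familyId)) .fatal("familyId required with a MirnaFamilySet")
    targets <- familyTargets(targets, familyId)
  }
  stopifnot(is(interactome, "Interactome"), is(net, "SeedNetwork"),
            is(clustering, "ModulePartition"))
  uni <- interactome@nodes
  if (!identical(universe, "interactome"))
    uni <- intersect(uni, .normGene(universe))
  if (!length(uni)) .fatal("empty enrichment universe")
  targets <- unique(.normGene(targets))
  a <- clustering@assignment[net@nodes]
  if (anyNA(a)) .fatal("clustering does not cover the network")
  N <- length(uni)
  tU <- intersect(targets, uni)
  K <- length(tU)
  netNodes <- intersect(net@nodes, uni)
  hitNet <- intersect(tU, netNodes)
  network <- .enrichResult(N, K, length(netNodes), length(hitNet),
                           sort(hitNet))
  rows <- lapply(0:(clustering@nModules - 1L), function(kmod) {
    mem <- intersect(net@nodes[a == kmod], uni)
    data.frame(module = kmod, size = length(mem),
               k = length(intersect(tU, mem)),
               p = hypergeomUpperTail(N, K, length(mem),
                                      length(intersect(tU, mem))))
  })
  list(network = network, clusters = do.call(rbind, rows))
}

#' Spanning score of one enrichment profile
#'
#' \eqn{S = B + (1 - p_{net})}, where \eqn{B} is the breadth term and
#' \eqn{p_{net}} the network-wide enrichment p-value.  With
#' \code{breadth = "significant"} (default) \eqn{B} counts modules whose
#' per-module hypergeometric p is below \code{alpha} (unadjusted — a
#' descriptive breadth count, not an inference); with
#' \code{breadth = "presence"} \eqn{B} counts modules containing at least
#' one target.  Both statistics are always reported.  Module breadth
#' dominates the score; whole-network enrichment acts as the tie-breaker,
#' so \eqn{S \in [0, n_{modules} + 1)}.
#'
#' @param profile result of \code{\link{mirnaEnrichmentProfile}}.
#' @param alpha per-module significance threshold (default 0.05).
#' @param breadth \code{"significant"} or \code{"presence"}.
#' @return A one-row data.frame: \code{K, network_k, p_net, B,
#'   clusters_with_targets, spanning_score}.
#'
#' @examples
#' # p_net = 0.01, module p's 0.01 / 0.2 / 0.03 -> B = 2, S = 2.99
#' prof <- list(network = list(N = 100, K = 10, n = 20, k = 5, p = 0.01),
#'              clusters = data.frame(module = 0:2, size = c(7, 7, 6),
#'                                    k = c(3, 1, 2),
#'                                    p = c(0.01, 0.2, 0.03)))
#' spanningScore(prof)
#' @export
spanningScore <- function(profile, alpha = 0.05,
                          breadth = c("significant", "presence")) {
  breadth <- match.arg(breadth)
  cl <- profile$clusters
  Bsig <- sum(cl$p < alpha)
  withT <- sum(cl$k > 0)
  B <- if (breadth == "significant") Bsig else withT
  data.frame(K = profile$network$K, network_k = profile$network$k,
             p_net = profile$network$p, B = Bsig,
             clusters_with_targets = withT,
             spanning_score = B + (1 - profile$network$p))
}

#' Spanning scores for every family in a set
#'
#' Convenience wrapper: profiles each family with
#' \code{\link{mirnaEnrichmentProfile}}, scores it with
#' \code{\link{spanningScore}} and ranks the result with
#' \code{\link{rankFamilies}}.  Families with zero interactome targets are
#' retained (they rank at the bottom with \eqn{S = 0}), so the table
#' always has one row per input family.
#'
#' @param families a \linkS4class{MirnaFamilySet}.
#' @param interactome,net,clustering see
#'   \code{\link{mirnaEnrichmentProfile}}.
#' @param alpha,breadth see \code{\link{spanningScore}}.
#' @return The ranked data.frame of \code{\link{rankFamilies}}, plus a
#'   \code{module_k} / \code{module_p} pair of per-module profile columns
#'   (comma-separated, module order).
#' @export
spanningScores <- function(families, interactome, net, clustering,
                           alpha = 0.05,
                           breadth = c("significant", "presence")) {
  stopifnot(is(families, "MirnaFamilySet"))
  breadth <- match.arg(breadth)
  rows <- lapply(seq_along(families@familyId), function(i) {
    prof <- mirnaEnrichmentProfile(families@targets[[i]], interactome,
                                   net, clustering)
    sc <- spanningScore(prof, alpha = alpha, breadth = breadth)
    cbind(data.frame(family_id = families@familyId[i],
                     seed_sequence = families@seedSequence[i]),
          sc,
          data.frame(
            module_k = paste(prof$clusters$k, collapse = ","),
            module_p = paste(signif(prof$clusters$p, 6), collapse = ",")))
  })
  rankFamilies(do.call(rbind, rows))
}

#' Rank families by spanning score
#'
#' Descending spanning score; ties broken by smaller network p-value, then
#' larger network overlap \code{network_k}, then lexicographic
#' \code{family_id}.  Rank 1 is the top family.  The sort is stable and
#' deterministic, so permuting the input rows never changes the ranking.
#'
#' @param results data.frame with columns \code{family_id},
#'   \code{spanning_score}, \code{p_net}, \code{network_k}.
#' @return The data.frame sorted by rank with a \code{rank} column (1-based)
#'   appended.
#' @export
rankFamilies <- function(results) {
  need <- c("family_id", "spanning_score", "p_net", "network_k")
  if (!all(need %in% names(results)))
    .fatal("results must have columns: %s", paste(need, collapse = ", "))
  ord <- order(-results$spanning_score, results$p_net,
               -results$network_k, results$family_id)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement (via
#' \code{stats::p.adjust}); output order matches input order and adjusted
#' values never fall below the raw ones.
#'
#' @param p numeric vector of p-values in \eqn{(0, 1]}.
#' @return Adjusted p-values, same length and order.
#' @export
bhFdr <- function(p) {
  if (!length(p)) return(numeric())
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    .fatal("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Hallmark-style gene-set enrichment of a gene list
#'
#' Hypergeometric over-representation of \code{genes} in each collection
#' set, against \code{universe}, with Benjamini-Hochberg FDR across all
#' tested sets.  Query genes outside the universe are dropped (their count
#' is attached as the \code{"dropped"} attribute); only sets intersecting
#' the universe are tested.
#'
#' @param genes character vector of query gene symbols (e.g. all network
#'   genes).
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param universe character vector of universe gene symbols (e.g. the
#'   interactome), or an \linkS4class{Interactome}.
#' @return A data.frame sorted by ascending p: \code{set_name, k, K, n, N,
#'   p_value, fdr, neg_log10_p, overlap_genes}.
#' @export
hallmarkEnrichment <- function(genes, collection, universe) {
  stopifnot(is(collection, "GeneSetCollection"))
  if (is(universe, "Interactome")) universe <- universe@nodes
  universe <- unique(.normGene(universe))
  if (!length(universe)) .fatal("empty universe")
  genes <- unique(.normGene(genes))
  dropped <- sum(!genes %in% universe)
  genes <- intersect(genes, universe)
  N <- length(universe); n <- length(genes)
  rows <- lapply(seq_along(collection@setName), function(i) {
    K <- intersect(collection@genes[[i]], universe)
    if (!length(K)) return(NULL)
    ov <- intersect(K, genes)
    data.frame(set_name = collection@setName[i],
               k = length(ov), K = length(K), n = n, N = N,
               p_value = hypergeomUpperTail(N, length(K), n, length(ov)),
               overlap_genes = paste(sort(ov), collapse = ","))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) .fatal("no gene set intersects the universe")
  out <- do.call(rbind, rows)
  out$fdr <- bhFdr(out$p_value)
  out$neg_log10_p <- -log10(out$p_value)
  out <- out[order(out$p_value, out$set_name),
             c("set_name", "k", "K", "n", "N", "p_value", "fdr",
               "neg_log10_p", "overlap_genes")]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
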