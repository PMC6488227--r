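# clustering: deterministic Newman leading-eigenvector modularity
# partitioning with Kernighan-Lin style refinement

# resolve (nodes, edges) from the graph-bearing classes
.graphParts <- function(net) {
  if (is(net, "SeedNetwork") || is(net, "Interactome"))
    return(list(nodes = net@nodes, edges = net@edges))
  .fatal("expected a SeedNetwork or Interactome")
}

#' Newman-Girvan modularity of a partition
#'
#' \deqn{Q = \sum_c \left[ e_c/m - (d_c/2m)^2 \right]} over modules
#' \eqn{c}, where \eqn{m} is the number of edges, \eqn{e_c} the number of
#' intra-module edges and \eqn{d_c} the total degree of module \eqn{c}.
#' Placing all nodes in one module gives \eqn{Q = 0} exactly.
#'
#' @param net a \linkS4class{SeedNetwork} or \linkS4class{Interactome}.
#' @param assignment named vector (node -> module label) covering every
#'   node, or a \linkS4class{ModulePartition}.
#' @return The modularity value, in \eqn{[-0.5, 1]}.
#' @export
networkModularity <- function(net, assignment) {
  g <- .graphParts(net)
  if (is(assignment, "ModulePartition")) assignment <- assignment@assignment
  if (is.null(names(assignment)) || !all(g$nodes %in% names(assignment)))
    .fatal("assignment must cover every network node by name")
  m <- nrow(g$edges)
  if (m == 0L) .fatal("modularity is undefined for an edgeless network")
  a <- assignment[g$nodes]
  ma <- a[g$edges[, 1]]; mb <- a[g$edges[, 2]]
  deg <- setNames(numeric(length(g$nodes)), g$nodes)
  t1 <- table(g$edges[, 1]); t2 <- table(g$edges[, 2])
  deg[names(t1)] <- deg[names(t1)] + as.numeric(t1)
  deg[names(t2)] <- deg[names(t2)] + as.numeric(t2)
  lev <- unique(a)
  ec <- as.numeric(table(factor(ma[ma == mb], levels = lev)))
  dc <- as.numeric(tapply(deg, factor(a, levels = lev), sum))
  dc[is.na(dc)] <- 0
  sum(ec / m - (dc / (2 * m))^2)
}

# sign vector from the leading eigenvector of the generalized modularity
# matrix; deterministic sign convention and tie handling
.eigenSplitVector <- function(Bg, symbols, tol = 1e-9) {
  es <- eigen(Bg, symmetric = TRUE)
  lambda <- es$values[1]
  if (lambda <= tol) return(NULL)
  v <- es$vectors[, 1]
  imax <- which.max(abs(v))       # ties: first index
  if (v[imax] < 0) v <- -v        # largest-magnitude entry positive
  s <- ifelse(v > tol, 1, ifelse(v < -tol, -1, 0))
  if (any(s == 0)) {
    # undecided entries join the side holding the lexicographically
    # smallest decided symbol; if nothing is decided, no split
    dec <- which(s != 0)
    if (!length(dec)) return(NULL)
    s[s == 0] <- s[dec[order(symbols[dec])[1]]]
  }
  if (all(s == s[1])) return(NULL)
  s
}

# Kernighan-Lin style refinement of a +/-1 split: repeatedly sweep all
# vertices, each moved once per sweep in best-gain order, keeping the best
# size-valid intermediate state.  Objective W = s' Bg s (proportional to
# the modularity change of the split).
.klRefine <- function(Bg, s, minSize, maxSweep = 30L) {
  n <- length(s)
  valid <- function(si) {
    k <- sum(si > 0); k >= minSize && (n - k) >= minSize
  }
  W <- function(si) as.numeric(t(si) %*% Bg %*% si)
  bestS <- s
  bestW <- if (valid(s)) W(s) else -Inf
  for (sweep in seq_len(maxSweep)) {
    cur <- s
    curW <- W(cur)
    v <- as.vector(Bg %*% cur)
    moved <- logical(n)
    trailS <- vector("list", n)
    trailW <- numeric(n)
    for (step in seq_len(n)) {
      gain <- 4 * diag(Bg) - 4 * cur * v
      gain[moved] <- -Inf
      i <- which.max(gain)        # ties: smallest index
      v <- v - 2 * cur[i] * Bg[, i]
      cur[i] <- -cur[i]
      curW <- curW + gain[i]
      moved[i] <- TRUE
      trailS[[step]] <- cur
      trailW[step] <- curW
    }
    okIdx <- which(vapply(trailS, valid, TRUE))
    improved <- FALSE
    if (length(okIdx)) {
      b <- okIdx[which.max(trailW[okIdx])]
      if (trailW[b] > bestW + 1e-12) {
        bestW <- trailW[b]; bestS <- trailS[[b]]; improved <- TRUE
      }
    }
    if (!improved) break
    s <- bestS
  }
  if (!is.finite(bestW)) return(NULL)
  bestS
}

# canonical relabeling: decreasing size, ties by smallest member symbol
.canonicalModules <- function(groups, nodes) {
  sizes <- lengths(groups)
  firsts <- vapply(groups, function(g) min(nodes[g]), "")
  ord <- order(-sizes, firsts)
  assignment <- integer(length(nodes))
  for (k in seq_along(ord)) assignment[groups[[ord[k]]]] <- k - 1L
  setNames(assignment, nodes)
}

#' Spectral modularity partitioning of a network
#'
#' Recursive leading-eigenvector bipartitioning of the modularity matrix
#' \eqn{B = A - k k^T / 2m} (Newman's spectral method, the algorithm family
#' behind ReactomeFI-style module detection).  Each candidate split is
#' refined by a Kernighan-Lin style vertex-moving pass and accepted only if
#' it increases total modularity (the indivisibility test) and both parts
#' have at least \code{minModuleSize} nodes.  Connected components are
#' partitioned independently; the result is fully deterministic for a given
#' graph — the eigenvector sign is fixed by making its largest-magnitude
#' entry positive and exact ties are broken toward the group containing the
#' lexicographically smallest symbol.
#'
#' Modules are labelled 0, 1, ... in decreasing size order (ties broken by
#' smallest member symbol).  An edgeless network yields one module per
#' node and \code{NA} modularity.
#'
#' @param net a \linkS4class{SeedNetwork} or \linkS4class{Interactome}.
#' @param minModuleSize smallest module a split may create (default 3;
#'   connected components smaller than this are kept whole as their own
#'   modules).
#' @param tol numeric tolerance for eigenvalues and modularity gains
#'   (default 1e-9).
#' @return A \linkS4class{ModulePartition}.
#'
#' @examples
#' ia <- exampleInteractome()
#' net <- buildSeedNetwork(ia, mapSeeds(ia, genes(ia)))
#' spectralPartition(net)
#' @export
spectralPartition <- function(net, minModuleSize = 3L, tol = 1e-9) {
  g <- .graphParts(net)
  nodes <- g$nodes
  n <- length(nodes)
  if (n == 0L) .fatal("empty network")
  m <- nrow(g$edges)
  if (m == 0L) {
    assignment <- .canonicalModules(as.list(seq_len(n)), nodes)
    return(new("ModulePartition", assignment = assignment,
               nModules = n, modularity = NA_real_))
  }
  A <- .adjMatrix(nodes, g$edges)
  deg <- rowSums(A)
  B <- A - outer(deg, deg) / (2 * m)
  comp <- igraph::components(.asIgraph(nodes, g$edges))$membership[nodes]
  queue <- unname(split(seq_len(n), comp))
  final <- list()
  while (length(queue)) {
    gIdx <- queue[[1]]; queue <- queue[-1]
    if (length(gIdx) < max(2L, 2L * minModuleSize)) {
      final <- c(final, list(gIdx)); next
    }
    Bg <- B[gIdx, gIdx, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)   # generalized modularity matrix
    s <- .eigenSplitVector(Bg, nodes[gIdx], tol)
    if (!is.null(s)) s <- .klRefine(Bg, s, minModuleSize)
    dQ <- if (is.null(s)) -Inf else as.numeric(t(s) %*% Bg %*% s) / (4 * m)
    if (is.null(s) || dQ <= tol ||
        min(sum(s > 0), sum(s < 0)) < minModuleSize) {
      final <- c(final, list(gIdx))
    } else {
      queue <- c(queue, list(gIdx[s > 0], gIdx[s < 0]))
    }
  }
  assignment <- .canonicalModules(final, nodes)
  q <- networkModularity(net, assignment)
  new("ModulePartition", assignment = assignment,
      nModules = length(final), modularity = q)
}

#' Per-module summary table
#'
#' @param net the clustered \linkS4class{SeedNetwork}.
#' @param clustering a \linkS4class{ModulePartition} for \code{net}.
#' @return A data.frame with one row per module: \code{module},
#'   \code{size}, \code{n_seeds} and a comma-separated sorted
#'   \code{members} column.  Sizes sum to the node count.
#' @export
clusterTable <- function(net, clustering) {
  stopifnot(is(net, "SeedNetwork"), is(clustering, "ModulePartition"))
  a <- clustering@assignment[net@nodes]
  if (anyNA(a)) .fatal("clustering does not cover the network")
  rows <- lapply(0:(clustering@nModules - 1L), function(k) {
    mem <- sort(net@nodes[a == k])
    data.frame(module = k, size = length(mem),
               n_seeds = sum(mem %in% net@seeds),
               members = paste(mem, collapse = ","))
  })
  do.call(rbind, rows)
}
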