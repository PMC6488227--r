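# independent oracles and fixture builders used across the suite

# upper-tail hypergeometric by direct enumeration of the pmf
enumHypergeomTail <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# all set partitions of 1..n as restricted-growth strings
enumPartitions <- function(n) {
  res <- list()
  rec <- function(rgs, mx) {
    if (length(rgs) == n) { res[[length(res) + 1L]] <<- rgs; return() }
    for (v in 0:(mx + 1L)) rec(c(rgs, v), max(mx, v))
  }
  rec(integer(), -1L)
  res
}

# Newman-Girvan Q from first principles: intra-edge fraction minus the
# degree-based expectation, written independently of the package code
oracleModularity <- function(nodes, edges, assign) {
  m <- nrow(edges)
  intra <- sum(assign[edges[, 1]] == assign[edges[, 2]])
  deg <- setNames(numeric(length(nodes)), nodes)
  for (col in 1:2) {
    t <- table(edges[, col])
    deg[names(t)] <- deg[names(t)] + as.numeric(t)
  }
  dc <- tapply(deg[nodes], assign[nodes], sum)
  intra / m - sum((dc / (2 * m))^2)
}

# exhaustive best modularity over every partition of the node set
bruteBestModularity <- function(nodes, edges) {
  best <- -Inf
  for (p in enumPartitions(length(nodes))) {
    a <- setNames(p, nodes)
    q <- oracleModularity(nodes, edges, a)
    if (q > best) best <- q
  }
  best
}

# exact two-sided Mann-Whitney by enumeration; U from pairwise counting
# (a different route than the package's rank-sum formula)
mwOracle <- function(x, y) {
  U <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pooled <- c(x, y)
  nx <- length(x)
  idx <- combn(length(pooled), nx)
  allU <- apply(idx, 2, function(i) {
    xi <- pooled[i]; yi <- pooled[-i]
    sum(outer(xi, yi, ">")) + 0.5 * sum(outer(xi, yi, "=="))
  })
  tol <- 1e-9
  p <- min(1, 2 * min(mean(allU <= U + tol), mean(allU >= U - tol)))
  list(U = U, p = p)
}

# Erdos-Renyi graph kept only if connected; returns canonical edge matrix
randomConnectedGraph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- LETTERS[seq_len(n)]
  repeat {
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    sel <- runif(nrow(ut)) < p
    if (sum(sel) == 0) next
    e <- cbind(nodes[ut[sel, 1]], nodes[ut[sel, 2]])
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    if (igraph::vcount(g) == n && igraph::components(g)$no == 1) {
      return(e)
    }
  }
}

# write an edge list to a temp file and load it
loadEdges <- function(pairs) {
  f <- tempfile(fileext = ".tsv")
  writeLines(paste(pairs[, 1], pairs[, 2], sep = "\t"), f)
  loadInteractome(f)
}

# full-network SeedNetwork over an edge matrix (all nodes are seeds)
fullNet <- function(pairs) {
  ia <- loadEdges(pairs)
  buildSeedNetwork(ia, mapSeeds(ia, genes(ia)))
}

cliquePairs <- function(g) t(combn(g, 2L))
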