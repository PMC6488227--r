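# internal helpers shared across modules

# case-normalize gene symbols; idempotent
.normGene <- function(x) toupper(trimws(x))

# a valid symbol is a non-empty token with no internal whitespace
.validGene <- function(x) nzchar(x) & !grepl("[[:space:]]", x)

.fatal <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# canonicalize an edge matrix: unordered pairs stored as (min, max),
# deduplicated, sorted row-wise for a stable on-disk order
.canonEdges <- function(a, b) {
  e <- cbind(pmin(a, b), pmax(a, b))
  e <- e[!duplicated(paste(e[, 1], e[, 2], sep = "\r")), , drop = FALSE]
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# dense 0/1 adjacency matrix from a node vector and canonical edge matrix
.adjMatrix <- function(nodes, edges) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0L) {
    i <- match(edges[, 1], nodes)
    j <- match(edges[, 2], nodes)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  A
}

# igraph view of (nodes, edges); undirected, keeps isolated nodes
.asIgraph <- function(nodes, edges) {
  igraph::graph_from_data_frame(
    d = data.frame(from = edges[, 1], to = edges[, 2],
                   stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
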