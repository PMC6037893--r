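#' Spanning-tree backbone of a connectivity matrix
#'
#' Builds the maximum-weight spanning tree over the PLI weights by Kruskal's
#' greedy algorithm: edges are sorted by descending weight and accepted when
#' they join two components, so the N-1 strongest non-redundant connections
#' form the backbone. (Equivalently, the minimum spanning tree over the
#' transformed weights 1 - PLI; minimizing raw PLI would keep the weakest
#' links and invert the meaning of every topology metric.) Ties are broken
#' deterministically by ascending (i, j) node-index order, so results are
#' identical across platforms. An all-equal (e.g. all-zero) matrix still
#' yields a tree - purely the tie-break order - and is flagged degenerate.
#'
#' @param x a [ConnectivityMatrix-class] or a symmetric non-negative matrix
#' @return a [TreeTopology-class] with metrics filled in
#' @export
spanningTree <- function(x) {
  if (is(x, "ConnectivityMatrix")) {
    w <- x@values
    labels <- x@channelLabels
  } else {
    w <- as.matrix(x)
    labels <- if (!is.null(rownames(w))) rownames(w)
              else sprintf("N%02d", seq_len(nrow(w)))
  }
  n <- nrow(w)
  if (n < 2L) stop("at least 2 nodes are required")
  if (max(abs(w - t(w))) > 1e-12) stop("matrix must be symmetric")
  if (min(w) < 0) stop("matrix must be non-negative")

  idx <- which(upper.tri(w), arr.ind = TRUE)
  ew <- w[upper.tri(w)]
  ord <- order(-ew, idx[, 1L], idx[, 2L])

  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  edges <- matrix(0, n - 1L, 3L,
                  dimnames = list(NULL, c("i", "j", "weight")))
  taken <- 0L
  for (k in ord) {
    ri <- find(idx[k, 1L]); rj <- find(idx[k, 2L])
    if (ri != rj) {
      parent[ri] <- rj
      taken <- taken + 1L
      edges[taken, ] <- c(idx[k, 1L], idx[k, 2L], ew[k])
      if (taken == n - 1L) break
    }
  }
  tree <- new("TreeTopology", nodes = labels, edges = edges,
              metrics = numeric(0), degenerate = length(unique(ew)) == 1L)
  tree@metrics <- treeMetrics(tree)
  tree
}

.treeGraph <- function(tree) {
  igraph::graph_from_edgelist(cbind(tree@edges[, "i"], tree@edges[, "j"]),
                              directed = FALSE)
}

#' Normalized topology metrics of a spanning tree
#'
#' With N nodes, M = N-1 edges, L degree-1 nodes (leaves), d the longest
#' path in edges, and BC_max the maximum betweenness centrality normalized
#' to `[0,1]`:
#' \describe{
#'   \item{degree_max_norm}{`max degree / M` - regional importance (hubness)}
#'   \item{leaf_fraction}{`L / M` - reliance of the network on hubs}
#'   \item{diameter_norm}{`d / M` - (inverse) efficiency of the backbone}
#'   \item{tree_hierarchy}{`L / (2 M BC_max)` - balance between hub
#'     reliance and efficient communication}
#' }
#' All four lie in (0, 1]. The two-node tree is degenerate under these
#' formulas (both nodes are leaves, no intermediate node carries
#' betweenness) and is defined to score 1 on every metric.
#'
#' @param x a [TreeTopology-class]
#' @return named numeric of length 4
#' @export
setMethod("treeMetrics", "TreeTopology", function(x) {
  n <- length(x@nodes)
  g <- .treeGraph(x)
  if (igraph::vcount(g) != n || !igraph::is_connected(g) ||
      igraph::ecount(g) != n - 1L)
    stop("not a tree: must be connected and acyclic on all nodes")
  if (n == 2L)
    return(c(degree_max_norm = 1, leaf_fraction = 1, diameter_norm = 1,
             tree_hierarchy = 1))
  m <- n - 1L
  deg <- igraph::degree(g)
  nLeaves <- sum(deg == 1L)
  diam <- igraph::diameter(g, weights = NA)
  bcMax <- max(igraph::betweenness(g, directed = FALSE, normalized = TRUE))
  c(degree_max_norm = max(deg) / m,
    leaf_fraction = nLeaves / m,
    diameter_norm = diam / m,
    tree_hierarchy = nLeaves / (2 * m * bcMax))
})
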