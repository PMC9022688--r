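## Graph-theory characterization of binarized connectomes: proportional
## thresholding, shortest-path efficiency measures, transitivity, degree.
## Metrics are computed directly on the adjacency matrix (BFS distances,
## triangle counting via the adjacency square) so they can be cross-checked
## against independent references.

#' Proportional thresholding of a weighted connectivity matrix
#'
#' Keeps the top \code{floor(target_density * n(n-1)/2)} unique edges by
#' weight and binarizes. Ties are broken deterministically by lexicographic
#' (i, j) order. Density is matched across groups by construction, which is
#' why compared graphs should be thresholded at the same target density.
#'
#' @param W symmetric weighted matrix (e.g. \code{connectome$weights} or a
#'   group z matrix); the diagonal is ignored.
#' @param target_density fraction of possible edges to keep, in \[0, 1\].
#' @return An object of class \code{binary_graph}: \code{adjacency}
#'   (symmetric 0/1, zero diagonal) and \code{density} (realized edge
#'   fraction).
#' @export
proportional_threshold <- function(W, target_density) {
  check_symmetric(W, "weight matrix")
  if (target_density < 0 || target_density > 1)
    stopf("target_density must lie in [0, 1]")
  n <- nrow(W)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  wts <- W[upper.tri(W)]
  m <- floor(target_density * n * (n - 1) / 2)
  keep <- order(-wts, ut[, 1], ut[, 2])[seq_len(m)]
  adj <- matrix(0L, n, n)
  if (m > 0) {
    ii <- ut[keep, , drop = FALSE]
    adj[ii] <- 1L
    adj[ii[, 2:1, drop = FALSE]] <- 1L
  }
  dimnames(adj) <- dimnames(W)
  structure(list(adjacency = adj,
                 density = sum(adj) / (n * (n - 1))),
            class = "binary_graph")
}

as_adjacency <- function(g) {
  if (inherits(g, "binary_graph")) g <- g$adjacency
  if (!is.matrix(g)) stopf("expected a binary_graph or adjacency matrix")
  check_symmetric(g, "adjacency")
  if (!all(g %in% c(0, 1))) stopf("adjacency must be binary")
  if (any(diag(g) != 0)) stopf("self-loops are not allowed")
  g
}

## all-pairs shortest-path lengths of an unweighted graph by matrix BFS;
## Inf for disconnected pairs
bfs_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(n) > 0
  frontier <- diag(n) > 0
  step <- 0L
  amat <- adj > 0
  while (any(frontier)) {
    step <- step + 1L
    nxt <- (frontier %*% amat) > 0 & !reach
    if (!any(nxt)) break
    D[nxt] <- step
    reach <- reach | nxt
    frontier <- nxt
  }
  D
}

#' Global efficiency of a binary graph
#'
#' The average inverse shortest-path length over all ordered node pairs,
#' \code{E = 1/(n(n-1)) * sum_{i != j} 1/d_ij}, with disconnected pairs
#' contributing 0.
#'
#' @param g a \code{binary_graph} or symmetric 0/1 adjacency matrix.
#' @return A value in \[0, 1\]; 1 for a complete graph, 0 for an edgeless
#'   one.
#' @export
global_efficiency <- function(g) {
  adj <- as_adjacency(g)
  n <- nrow(adj)
  if (n < 2L) stopf("at least 2 nodes are required")
  D <- bfs_distances(adj)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency of one node
#'
#' The global efficiency of the subgraph induced by the node's neighbours
#' (the node itself excluded); nodes of degree < 2 have local efficiency 0.
#' A proxy for fault tolerance around the node.
#'
#' @param g a \code{binary_graph} or adjacency matrix.
#' @param node node index, or \code{NULL} to return the vector for all
#'   nodes.
#' @return Local efficiency value(s) in \[0, 1\].
#' @export
local_efficiency <- function(g, node = NULL) {
  adj <- as_adjacency(g)
  one <- function(v) {
    nb <- which(adj[v, ] > 0)
    if (length(nb) < 2L) return(0)
    global_efficiency(adj[nb, nb, drop = FALSE])
  }
  if (is.null(node)) return(vapply(seq_len(nrow(adj)), one, numeric(1)))
  if (node < 1L || node > nrow(adj)) stopf("node %d is not in the graph", node)
  one(node)
}

#' Transitivity of a binary graph
#'
#' \code{T = 3 * (number of triangles) / (number of connected triples)},
#' with 0/0 defined as 0. Triangles are counted via the trace of the cubed
#' adjacency; connected triples as \code{sum_i choose(k_i, 2)}.
#'
#' @param g a \code{binary_graph} or adjacency matrix (n >= 3).
#' @return A value in \[0, 1\].
#' @export
transitivity <- function(g) {
  adj <- as_adjacency(g)
  if (nrow(adj) < 3L) stopf("at least 3 nodes are required")
  k <- rowSums(adj)
  triples <- sum(k * (k - 1) / 2)
  if (triples == 0) return(0)
  tri6 <- sum(diag(adj %*% adj %*% adj))        # = 6 * number of triangles
  (tri6 / 2) / triples
}

#' Node degrees of a binary graph
#'
#' @param g a \code{binary_graph} or adjacency matrix.
#' @return Integer vector of row sums of the adjacency.
#' @export
node_degree <- function(g) {
  adj <- as_adjacency(g)
  as.integer(rowSums(adj))
}

#' Per-node metric table for a thresholded connectome
#'
#' Convenience wrapper returning degree and local efficiency per node plus
#' the graph-level global efficiency and transitivity as attributes.
#'
#' @param g a \code{binary_graph}.
#' @param ids optional node identifiers.
#' @return A data frame with columns \code{id}, \code{degree},
#'   \code{local_efficiency}; attributes \code{global_efficiency},
#'   \code{transitivity}, \code{density}.
#' @export
graph_metric_table <- function(g, ids = NULL) {
  adj <- as_adjacency(g)
  n <- nrow(adj)
  out <- data.frame(id = ids %||% seq_len(n),
                    degree = node_degree(adj),
                    local_efficiency = local_efficiency(adj))
  attr(out, "global_efficiency") <- global_efficiency(adj)
  attr(out, "transitivity") <- if (n >= 3) transitivity(adj) else NA_real_
  attr(out, "density") <- if (inherits(g, "binary_graph")) g$density
                          else sum(adj) / (n * (n - 1))
  out
}
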