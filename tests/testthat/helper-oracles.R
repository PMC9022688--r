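## Independent brute-force references used to validate the graph metrics,
## plus small shared fixtures. Everything here is deliberately naive:
## Floyd-Warshall distances, exhaustive triple enumeration, direct formula
## evaluation.

oracle_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[adj > 0] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_global_efficiency <- function(adj) {
  n <- nrow(adj)
  D <- oracle_distances(adj)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && is.finite(D[i, j])) s <- s + 1 / D[i, j]
  s / (n * (n - 1))
}

oracle_local_efficiency <- function(adj, v) {
  nb <- which(adj[v, ] > 0)
  if (length(nb) < 2) return(0)
  oracle_global_efficiency(adj[nb, nb, drop = FALSE])
}

oracle_transitivity <- function(adj) {
  n <- nrow(adj)
  tri <- 0; triples <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i == j || j == k || i == k) next
    if (adj[i, j] && adj[j, k]) {
      triples <- triples + 1              # ordered connected triple at j
      if (adj[i, k]) tri <- tri + 1       # ordered closed triple
    }
  }
  if (triples == 0) 0 else tri / triples
}

random_graph <- function(n, p = NULL) {
  p <- p %||% stats::runif(1, 0.1, 0.9)
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  on <- up[stats::runif(length(up)) < p]
  adj[on] <- 1L
  adj <- adj + t(adj)
  adj
}

adjacency_from_edges <- function(n, edges) {
  adj <- matrix(0L, n, n)
  for (e in edges) { adj[e[1], e[2]] <- 1L; adj[e[2], e[1]] <- 1L }
  adj
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

## tiny functional spec: 2 clusters x 2 components on a small grid
tiny_rsn_spec <- function(seed = 1L, n_timepoints = 120L, w = 0.7,
                          rho = NULL, noise_sigma = 0.1,
                          n_noise_components = 0L) {
  comps <- list(component_spec(c(5, 5, 5), 1.5, cluster = 1),
                component_spec(c(11, 5, 5), 1.5, cluster = 1),
                component_spec(c(5, 11, 5), 1.5, cluster = 2),
                component_spec(c(11, 11, 5), 1.5, cluster = 2))
  icc <- if (is.null(rho)) NULL else data.frame(a = 1L, b = 2L, rho = rho)
  functional_phantom_spec(grid_shape = c(16L, 16L, 10L),
                          n_timepoints = n_timepoints, tr_seconds = 1,
                          components = comps, cluster_loading = w,
                          inter_cluster_corr = icc,
                          noise_sigma = noise_sigma,
                          n_noise_components = n_noise_components,
                          seed = seed)
}
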