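# Independent brute-force oracles for graph metrics. These deliberately share
# no code with the package: triangle counting by triple loop, shortest paths
# by Floyd-Warshall.

brute_clustering <- function(A) {
  n <- nrow(A)
  if (n == 0) return(0)
  local <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a < b && A[nb[a], nb[b]] == 1) links <- links + 1
      }
    }
    local[i] <- links / (k * (k - 1) / 2)
  }
  mean(local)
}

brute_path_length <- function(A) {
  n <- nrow(A)
  if (n == 0 || sum(A) == 0) return(NA_real_)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  vals <- D[upper.tri(D)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) NA_real_ else mean(vals)
}

random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- rbinom(length(up), 1, p)
  A + t(A)
}

cell_graph_from_adjacency <- function(A) {
  structure(
    list(graph = igraph::graph_from_adjacency_matrix(A, mode = "undirected"),
         coords = NULL, cutoff_um = NA, params = NULL),
    class = "cell_graph"
  )
}
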