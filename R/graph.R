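#' Build the directed KNN sample correlation graph
#'
#' Each sample a is connected to the k samples (excluding itself) whose
#' embeddings are nearest in Euclidean distance; ties are broken by ascending
#' sample index. The graph is directed (neighbourhoods are per-target and the
#' adjacency matrix is not symmetrized), so every node has out-degree exactly
#' k and the zero-filling rule always averages over exactly k neighbours.
#'
#' @param Z Embedding matrix (samples x d), all finite.
#' @param k Number of neighbours per sample, 1 <= k <= n-1 (default 5; a
#'   small k keeps dissimilar samples out of the neighbourhood).
#' @return An object of class `sample_graph`: list with `n`, `k`,
#'   `adjacency` (binary n x n, zero diagonal, row sums k), `neighborhoods`
#'   (list of k nearest sample indices, nearest first) and `distances`
#'   (matching Euclidean distances).
#' @export
#' @examples
#' g <- build_knn_graph(matrix(c(0, 1, 10), 3, 1), k = 1)
#' g$neighborhoods
build_knn_graph <- function(Z, k = 5L) {
  if (is.vector(Z)) Z <- matrix(Z, ncol = 1L)
  stopifnot(is.matrix(Z), is.numeric(Z))
  if (!all(is.finite(Z))) abort("embeddings must be finite")
  n <- nrow(Z)
  k <- as.integer(k)
  if (k < 1L || k >= n) abort("k must satisfy 1 <= k <= n-1 (k=%d, n=%d)", k, n)
  D <- as.matrix(stats::dist(Z))
  neighborhoods <- vector("list", n)
  distances <- matrix(0, n, k)
  A <- matrix(0L, n, n)
  idx <- seq_len(n)
  for (a in idx) {
    d <- D[a, ]
    cand <- idx[-a]
    ord <- cand[order(d[cand], cand)][seq_len(k)]
    neighborhoods[[a]] <- ord
    distances[a, ] <- d[ord]
    A[a, ord] <- 1L
  }
  structure(list(n = n, k = k, adjacency = A,
                 neighborhoods = neighborhoods, distances = distances),
            class = "sample_graph")
}

#' Export the graph as an edge list
#'
#' @param graph A [build_knn_graph()] result.
#' @return Tibble with columns `source`, `target`, `rank` (1 = nearest) and
#'   `distance`.
#' @export
graph_edge_list <- function(graph) {
  stopifnot(inherits(graph, "sample_graph"))
  tibble::tibble(
    source = rep(seq_len(graph$n), each = graph$k),
    target = unlist(graph$neighborhoods),
    rank = rep(seq_len(graph$k), times = graph$n),
    distance = as.vector(t(graph$distances))
  )
}

#' @export
print.sample_graph <- function(x, ...) {
  cat(sprintf("sample_graph: %d nodes, k = %d (directed, %d edges)\n",
              x$n, x$k, x$n * x$k))
  invisible(x)
}
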