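# Exact k-nearest-neighbour graphs: the shared substrate for clustering,
# annotation and the neighbourhood-based integration metrics. Sizes here are
# desk scale (up to a few thousand cells), so brute-force all-pairs distances
# are computed; ties are broken by lower cell index for determinism.

#' Build an exact kNN graph
#'
#' @param emb CellEmbeddingMatrix (or a plain numeric matrix with cells in
#'   rows).
#' @param k neighbours per cell; clipped to `n - 1` with a warning when
#'   `k >= n`.
#' @param metric `"euclidean"` (default) or `"cosine"` (distance
#'   `1 - cosine similarity`).
#' @return object of class `NeighborGraph`: `idx` and `dist` are n x k'
#'   matrices (`k' = min(k, n - 1)`) with each row sorted by ascending
#'   distance, self excluded.
#' @export
knn_graph <- function(emb, k, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  v <- if (inherits(emb, "CellEmbeddingMatrix")) emb$vectors else as.matrix(emb)
  n <- nrow(v)
  assert_that(n >= 2, "need at least 2 cells")
  assert_that(k >= 1, "k must be >= 1")
  if (k >= n) {
    warning("k = ", k, " clipped to n - 1 = ", n - 1)
    k <- n - 1
  }
  d <- pairwise_distances(v, metric)
  diag(d) <- Inf
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    # order() is stable, so equal distances resolve to the lower index
    o <- order(d[i, ])[seq_len(k)]
    idx[i, ] <- o
    dst[i, ] <- d[i, o]
  }
  structure(list(k = k, idx = idx, dist = dst, metric = metric, n = n),
            class = "NeighborGraph")
}

pairwise_distances <- function(v, metric) {
  if (metric == "euclidean") {
    sq <- rowSums(v^2)
    d2 <- outer(sq, sq, "+") - 2 * tcrossprod(v)
    sqrt(pmax(d2, 0))
  } else {
    u <- l2_normalize_rows(v)
    pmin(pmax(1 - tcrossprod(u), 0), 2)
  }
}

# undirected igraph from the union of kNN edges
knn_igraph <- function(graph) {
  from <- rep(seq_len(graph$n), each = ncol(graph$idx))
  edges <- cbind(from, as.vector(t(graph$idx)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}
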