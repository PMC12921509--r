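# Zero-shot tasks on aggregated cell embeddings: graph clustering, kNN
# cell-type annotation, and projection-based batch integration (all batches
# aggregated into the shared embedding space, no trained alignment).

#' Cluster cells on the kNN graph
#'
#' Leiden community detection (modularity objective) on the undirected union
#' of kNN edges. Deterministic for a fixed seed; labels are consecutive
#' integers from 0.
#'
#' @param emb CellEmbeddingMatrix.
#' @param k neighbours for the graph (default 30; a denser graph than the
#'   usual 10-20 keeps modularity's resolution limit from fragmenting
#'   communities of a few hundred cells).
#' @param resolution Leiden resolution parameter (default 1).
#' @param seed integer seed.
#' @param metric distance metric for the graph.
#' @return integer vector of per-cell cluster labels starting at 0.
#' @export
cluster_cells <- function(emb, k = 30, resolution = 1, seed = 0L,
                          metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  n <- if (inherits(emb, "CellEmbeddingMatrix")) length(emb$cell_ids)
       else nrow(emb)
  if (n == 1L) return(0L)
  graph <- suppressWarnings(knn_graph(emb, min(k, n - 1), metric))
  g <- knn_igraph(graph)
  memb <- with_seed(seed, igraph::cluster_leiden(
    g, objective_function = "modularity",
    resolution = resolution, n_iterations = 3)$membership)
  as.integer(memb) - 1L
}

#' kNN cell-type annotation
#'
#' Majority vote over the k nearest training cells; the vote fraction is the
#' winning label's share of the k votes. Ties are broken by the label of the
#' nearest neighbour among the tied labels.
#'
#' @param train CellEmbeddingMatrix of labelled cells.
#' @param train_labels per-cell labels for `train`.
#' @param test CellEmbeddingMatrix to annotate.
#' @param k neighbours (default 10).
#' @param metric distance metric.
#' @return data.frame with columns `cell_id`, `label`, `confidence`.
#' @export
knn_annotate <- function(train, train_labels, test, k = 10,
                         metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  tv <- if (inherits(train, "CellEmbeddingMatrix")) train$vectors else as.matrix(train)
  sv <- if (inherits(test, "CellEmbeddingMatrix")) test$vectors else as.matrix(test)
  assert_that(nrow(tv) >= 1, "empty training set")
  train_labels <- as.character(train_labels)
  assert_that(length(train_labels) == nrow(tv),
              "one label per training cell required")
  if (k > nrow(tv)) {
    warning("k = ", k, " clipped to training size ", nrow(tv))
    k <- nrow(tv)
  }
  d <- cross_distances(sv, tv, metric)
  pred <- character(nrow(sv))
  conf <- numeric(nrow(sv))
  for (i in seq_len(nrow(sv))) {
    o <- order(d[i, ])[seq_len(k)]
    votes <- table(train_labels[o])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      # first neighbour in distance order whose label is among the tied ones
      top <- train_labels[o][match(TRUE, train_labels[o] %in% top)]
    }
    pred[i] <- top
    conf[i] <- max(votes) / k
  }
  ids <- if (inherits(test, "CellEmbeddingMatrix")) test$cell_ids
         else paste0("cell", seq_len(nrow(sv)))
  data.frame(cell_id = ids, label = pred, confidence = conf,
             stringsAsFactors = FALSE)
}

cross_distances <- function(a, b, metric) {
  if (metric == "euclidean") {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    sqrt(pmax(d2, 0))
  } else {
    1 - tcrossprod(l2_normalize_rows(a), l2_normalize_rows(b))
  }
}

#' Project multiple batches into the shared embedding space
#'
#' Intersects feature names across all batches and the embedding table,
#' aggregates each batch independently with an identical feature order, and
#' concatenates the results. No trainable alignment is applied: mixing relies
#' entirely on the embedding space.
#'
#' @param batches named list of ExpressionMatrix objects (>= 2); names become
#'   batch labels (defaults to `batch1`, `batch2`, ...).
#' @param feats FeatureEmbeddingTable.
#' @param mode aggregation mode.
#' @return list with `embedding` (CellEmbeddingMatrix over all cells) and
#'   `batch` (per-cell batch label vector).
#' @export
project_batches <- function(batches, feats, mode = c("wa", "aa")) {
  mode <- match.arg(mode)
  assert_that(length(batches) >= 2, "need at least 2 batches")
  if (is.null(names(batches)) || any(!nzchar(names(batches)))) {
    names(batches) <- paste0("batch", seq_along(batches))
  }
  shared <- Reduce(intersect, lapply(batches, function(b) b$feature_ids))
  shared <- intersect(shared, feats$names)
  if (length(shared) == 0L) {
    stop_validation("no shared features across batches (",
                    paste(names(batches), collapse = ", "),
                    ") and the embedding table")
  }
  parts <- lapply(batches, function(b) {
    cell_embeddings(subset_features(b, shared), feats, mode)
  })
  vec <- do.call(rbind, lapply(parts, function(p) p$vectors))
  ids <- unlist(lapply(parts, function(p) p$cell_ids), use.names = FALSE)
  if (anyDuplicated(ids)) {
    ids <- paste(rep(names(batches), vapply(parts, function(p)
      length(p$cell_ids), 0L)), ids, sep = ":")
  }
  list(embedding = cell_embedding_matrix(ids, vec),
       batch = rep(names(batches),
                   vapply(parts, function(p) length(p$cell_ids), 0L)))
}
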