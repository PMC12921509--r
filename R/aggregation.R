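# Aggregation of feature embeddings into cell embeddings: the core operation.
# A cell's embedding is a weighted sum of its genes' embedding vectors, with
# weights taken from the normalized expression matrix under one of two modes:
#   aa (arithmetic average): every entry of X divided by the gene count m;
#   wa (weighted average):   each row of X divided by its row sum, so weights
#                            sum to 1 per cell and the embedding is a convex
#                            combination of gene vectors.
# Optionally the embedding of each cell's metadata label is added on top.

#' Aggregation weights
#'
#' @param x ExpressionMatrix.
#' @param mode `"aa"` (divide X by the number of features m) or `"wa"` (divide
#'   each row by its sum). Under `wa`, rows with zero sum give all-zero weight
#'   rows (with a warning) rather than NaN.
#' @return an n x m numeric weight matrix.
#' @export
avg_weights <- function(x, mode = c("wa", "aa")) {
  assert_that(inherits(x, "ExpressionMatrix"), "x must be an ExpressionMatrix")
  mode <- match.arg(mode)
  v <- x$values
  if (mode == "aa") return(v / ncol(v))
  totals <- rowSums(v)
  zero <- totals == 0
  if (any(zero)) {
    warning("zero-total cells get all-zero wa weights: ",
            paste(utils::head(x$cell_ids[zero], 5), collapse = ", "),
            if (sum(zero) > 5) sprintf(" (+%d more)", sum(zero) - 5) else "")
    totals[zero] <- 1
  }
  v / totals
}

#' Aggregate feature embeddings into cell embeddings
#'
#' Computes `avg_weights(x, mode) %*% E` where `E` holds the embedding vector
#' of each feature of `x`, aligned by feature name. When per-cell labels and a
#' label embedding table are supplied, each cell's label vector is added to
#' its aggregated embedding.
#'
#' @param x ExpressionMatrix (normalized expression).
#' @param feats FeatureEmbeddingTable covering the features of `x`.
#' @param mode aggregation mode, `"wa"` (default) or `"aa"`.
#' @param labels optional per-cell label vector (length n).
#' @param label_tab optional LabelEmbeddingTable with one row per distinct
#'   label; must have the same dimension as `feats`.
#' @param intersect if `TRUE`, features of `x` missing from `feats` are dropped
#'   (with a warning) instead of raising an error.
#' @return a [cell_embedding_matrix()].
#' @export
cell_embeddings <- function(x, feats, mode = c("wa", "aa"), labels = NULL,
                            label_tab = NULL, intersect = FALSE) {
  assert_that(inherits(x, "ExpressionMatrix"), "x must be an ExpressionMatrix")
  assert_that(inherits(feats, "FeatureEmbeddingTable"),
              "feats must be a FeatureEmbeddingTable")
  mode <- match.arg(mode)
  missing <- setdiff(x$feature_ids, feats$names)
  if (length(missing)) {
    if (!intersect) {
      stop_validation(length(missing), " features lack embeddings: ",
                      paste(utils::head(missing, 20), collapse = ", "))
    }
    warning("dropping ", length(missing), " features without embeddings")
    x <- subset_features(x, setdiff(x$feature_ids, missing))
  }
  e <- feats$vectors[x$feature_ids, , drop = FALSE]
  w <- suppressWarnings(avg_weights(x, mode))
  out <- w %*% e
  if (!is.null(labels)) {
    assert_that(!is.null(label_tab), "labels supplied without label_tab")
    assert_that(length(labels) == nrow(out),
                "labels must have one entry per cell")
    assert_that(label_tab$dim == feats$dim,
                "label embedding dim (", label_tab$dim,
                ") != feature embedding dim (", feats$dim, ")")
    unknown <- setdiff(unique(labels), label_tab$names)
    assert_that(length(unknown) == 0L, "labels without embeddings: ",
                paste(utils::head(unknown, 20), collapse = ", "))
    out <- out + label_tab$vectors[as.character(labels), , drop = FALSE]
  }
  cell_embedding_matrix(x$cell_ids, out)
}

#' Zero out the expression of selected genes
#'
#' In-silico deletion: the listed columns are set to zero but kept in place,
#' so downstream embedding dimensions stay aligned. Under `wa` aggregation the
#' remaining genes' weights renormalize over the reduced row sums.
#'
#' @param x ExpressionMatrix.
#' @param genes character vector of feature names to zero.
#' @return ExpressionMatrix of the same shape.
#' @export
delete_genes <- function(x, genes) {
  assert_that(inherits(x, "ExpressionMatrix"), "x must be an ExpressionMatrix")
  genes <- unique(as.character(genes))
  idx <- match(genes, x$feature_ids)
  assert_that(!anyNA(idx), "unknown genes: ",
              paste(utils::head(genes[is.na(idx)], 20), collapse = ", "))
  v <- x$values
  v[, idx] <- 0
  expression_matrix(v, x$cell_ids, x$feature_ids, x$cell_meta,
                    normalized = x$normalized)
}
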