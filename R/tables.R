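# Containers for feature/label embedding tables and cell embedding matrices.

#' Feature embedding table
#'
#' Maps feature (gene/protein) names to fixed-length real vectors, typically
#' language-model embeddings of per-gene text descriptions. The same container
#' holds label (cell-level metadata) embeddings.
#'
#' @param names character vector of unique feature names.
#' @param vectors numeric matrix with one row per name; the column count is the
#'   embedding dimension `t`.
#' @return object of class `FeatureEmbeddingTable` with fields `names`,
#'   `vectors`, `dim`.
#' @export
feature_embedding_table <- function(names, vectors) {
  names <- as.character(names)
  if (!is.matrix(vectors)) vectors <- matrix(vectors, nrow = length(names))
  storage.mode(vectors) <- "double"
  assert_that(nrow(vectors) == length(names),
              "one vector per name required (", length(names), " names, ",
              nrow(vectors), " vectors)")
  assert_that(!anyDuplicated(names), "duplicate feature names: ",
              paste(utils::head(unique(names[duplicated(names)]), 5),
                    collapse = ", "))
  assert_that(length(vectors) == 0L || all(is.finite(vectors)),
              "embedding values must be finite")
  rownames(vectors) <- names
  structure(list(names = names, vectors = vectors, dim = ncol(vectors)),
            class = "FeatureEmbeddingTable")
}

#' @export
print.FeatureEmbeddingTable <- function(x, ...) {
  cat(sprintf("FeatureEmbeddingTable: %d features, dim %d\n",
              length(x$names), x$dim))
  invisible(x)
}

#' Label embedding table
#'
#' Thin wrapper over [feature_embedding_table()] for cell-level metadata
#' labels (e.g. cell types); kept as a distinct constructor for clarity at
#' call sites.
#'
#' @inheritParams feature_embedding_table
#' @export
label_embedding_table <- function(names, vectors) {
  feature_embedding_table(names, vectors)
}

#' Cell embedding matrix
#'
#' @param cell_ids character vector of cell identifiers.
#' @param vectors numeric matrix, one row of `t` reals per cell.
#' @return object of class `CellEmbeddingMatrix` with fields `cell_ids`,
#'   `vectors`, `dim`.
#' @export
cell_embedding_matrix <- function(cell_ids, vectors) {
  cell_ids <- as.character(cell_ids)
  if (!is.matrix(vectors)) vectors <- matrix(vectors, nrow = length(cell_ids))
  storage.mode(vectors) <- "double"
  assert_that(nrow(vectors) == length(cell_ids),
              "one vector per cell required")
  assert_that(length(vectors) == 0L || all(is.finite(vectors)),
              "cell embedding values must be finite")
  dimnames(vectors) <- NULL
  structure(list(cell_ids = cell_ids, vectors = vectors, dim = ncol(vectors)),
            class = "CellEmbeddingMatrix")
}

#' @export
print.CellEmbeddingMatrix <- function(x, ...) {
  cat(sprintf("CellEmbeddingMatrix: %d cells, dim %d\n",
              length(x$cell_ids), x$dim))
  invisible(x)
}

#' Combine two aligned embedding tables
#'
#' Utility to sum or concatenate two embedding tables over the intersection of
#' their feature names, for mixing embedding sources.
#'
#' @param a,b FeatureEmbeddingTable.
#' @param how `"concat"` (default) or `"sum"`; `"sum"` requires equal dims.
#' @export
combine_embedding_tables <- function(a, b, how = c("concat", "sum")) {
  how <- match.arg(how)
  shared <- intersect(a$names, b$names)
  assert_that(length(shared) > 0, "tables share no feature names")
  va <- a$vectors[shared, , drop = FALSE]
  vb <- b$vectors[shared, , drop = FALSE]
  if (how == "sum") {
    assert_that(a$dim == b$dim, "sum requires equal embedding dims")
    feature_embedding_table(shared, va + vb)
  } else {
    feature_embedding_table(shared, cbind(va, vb))
  }
}
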