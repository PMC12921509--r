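#' Expression matrix container
#'
#' A light container for a cells-by-genes expression matrix with per-cell
#' metadata. Values are nonnegative reals; after [normalize_counts()] they are
#' library-size-scaled log1p expression, which is the representation the
#' aggregation step expects.
#'
#' @param values numeric matrix (cells in rows, features in columns) or a
#'   `Matrix` sparse matrix; coerced to a dense base matrix.
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   rownames of `values`).
#' @param feature_ids character vector of unique feature identifiers (defaults
#'   to colnames of `values`).
#' @param cell_meta optional data.frame keyed by `cell_id` with any of the
#'   columns `cell_type`, `batch`, `condition` (extra columns are kept).
#' @param normalized logical; `TRUE` once values are normalized log expression.
#' @return an object of class `ExpressionMatrix` with fields `values`,
#'   `cell_ids`, `feature_ids`, `cell_meta`, `normalized`.
#' @examples
#' x <- expression_matrix(matrix(rpois(6, 5), 2, 3,
#'   dimnames = list(c("c1", "c2"), c("g1", "g2", "g3"))))
#' dim(x$values)
#' @export
expression_matrix <- function(values, cell_ids = NULL, feature_ids = NULL,
                              cell_meta = NULL, normalized = FALSE) {
  if (inherits(values, "Matrix")) values <- as.matrix(values)
  assert_that(is.matrix(values) && is.numeric(values),
              "values must be a numeric matrix")
  cell_ids <- as.character(cell_ids %||% rownames(values) %||%
                             paste0("cell", seq_len(nrow(values))))
  feature_ids <- as.character(feature_ids %||% colnames(values) %||%
                                paste0("gene", seq_len(ncol(values))))
  x <- structure(list(values = unname(values),
                      cell_ids = cell_ids,
                      feature_ids = feature_ids,
                      cell_meta = cell_meta,
                      normalized = isTRUE(normalized)),
                 class = "ExpressionMatrix")
  validate_expression_matrix(x)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw counts"))
  if (!is.null(x$cell_meta)) {
    cat("  cell_meta columns:",
        paste(setdiff(names(x$cell_meta), "cell_id"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

validate_expression_matrix <- function(x) {
  v <- x$values
  assert_that(length(x$cell_ids) == nrow(v),
              "cell id list length (", length(x$cell_ids),
              ") does not match matrix rows (", nrow(v), ")")
  assert_that(length(x$feature_ids) == ncol(v),
              "feature id list length (", length(x$feature_ids),
              ") does not match matrix columns (", ncol(v), ")")
  assert_that(!anyDuplicated(x$cell_ids), "cell ids must be unique")
  assert_that(!anyDuplicated(x$feature_ids), "feature ids must be unique")
  assert_that(all(is.finite(v)) || length(v) == 0L,
              "expression values must be finite")
  assert_that(length(v) == 0L || min(v) >= 0, "expression values must be >= 0")
  if (!is.null(x$cell_meta)) {
    assert_that(is.data.frame(x$cell_meta), "cell_meta must be a data.frame")
    assert_that("cell_id" %in% names(x$cell_meta),
                "cell_meta must have a cell_id column")
    extra <- setdiff(x$cell_meta$cell_id, x$cell_ids)
    assert_that(length(extra) == 0L,
                "cell_meta rows without a matching cell: ",
                paste(utils::head(extra, 5), collapse = ", "))
    # keep meta aligned with matrix row order
    x$cell_meta <- x$cell_meta[match(x$cell_ids, x$cell_meta$cell_id), ,
                               drop = FALSE]
    rownames(x$cell_meta) <- NULL
  }
  x
}

#' Retrieve a cell metadata column
#'
#' @param x ExpressionMatrix.
#' @param column column name, e.g. `"cell_type"`, `"batch"`, `"condition"`.
#' @return character vector aligned with `x$cell_ids`.
#' @export
cell_meta_column <- function(x, column) {
  assert_that(!is.null(x$cell_meta) && column %in% names(x$cell_meta),
              "cell_meta column '", column, "' not present")
  as.character(x$cell_meta[[column]])
}

#' Library-size normalization and log transform
#'
#' Scales each cell's counts to a common total (`target_sum`) and applies
#' `log1p`, the standard scRNA-seq preprocessing. Cells with zero total counts
#' are kept and remain all-zero.
#'
#' @param raw ExpressionMatrix of nonnegative counts with `normalized = FALSE`.
#' @param target_sum per-cell total after scaling; default `1e4`.
#' @return normalized ExpressionMatrix (`normalized = TRUE`).
#' @export
normalize_counts <- function(raw, target_sum = 1e4) {
  assert_that(inherits(raw, "ExpressionMatrix"), "raw must be an ExpressionMatrix")
  assert_that(!isTRUE(raw$normalized), "input is already normalized")
  assert_that(target_sum > 0, "target_sum must be positive")
  v <- raw$values
  totals <- rowSums(v)
  nz <- totals > 0
  v[nz, ] <- v[nz, , drop = FALSE] * (target_sum / totals[nz])
  v <- log1p(v)
  expression_matrix(v, raw$cell_ids, raw$feature_ids, raw$cell_meta,
                    normalized = TRUE)
}

#' Drop cells with zero total expression
#'
#' @param x ExpressionMatrix.
#' @return ExpressionMatrix restricted to cells with positive row sums.
#' @export
drop_empty_cells <- function(x) {
  keep <- rowSums(x$values) > 0
  subset_cells(x, which(keep))
}

subset_cells <- function(x, idx) {
  meta <- x$cell_meta
  if (!is.null(meta)) {
    meta <- meta[match(x$cell_ids[idx], meta$cell_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  expression_matrix(x$values[idx, , drop = FALSE], x$cell_ids[idx],
                    x$feature_ids, meta, normalized = x$normalized)
}

subset_features <- function(x, feature_names) {
  idx <- match(feature_names, x$feature_ids)
  assert_that(!anyNA(idx), "unknown features: ",
              paste(utils::head(feature_names[is.na(idx)], 5), collapse = ", "))
  expression_matrix(x$values[, idx, drop = FALSE], x$cell_ids,
                    x$feature_ids[idx], x$cell_meta, normalized = x$normalized)
}
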