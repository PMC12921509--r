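# Readers/writers for the on-disk formats: Matrix Market MTX with TSV
# sidecars, dense CSV, optional AnnData h5ad, and embedding tables as TSV.

mtx_sidecar_paths <- function(path) {
  d <- dirname(path)
  list(cells = file.path(d, "cells.tsv"),
       features = file.path(d, "features.tsv"),
       metadata = file.path(d, "metadata.tsv"))
}

#' Read an expression matrix
#'
#' Supported formats: `mtx` (Matrix Market coordinate file with `cells.tsv`
#' and `features.tsv` sidecars and an optional `metadata.tsv`, cells in rows),
#' `csv` (dense; header row of feature names, first column cell ids), and
#' `h5ad` (AnnData; requires the rhdf5 package; reads `X`, `var` names and the
#' `obs` columns cell_type/batch/condition).
#'
#' @param path file path.
#' @param format one of `"mtx"`, `"csv"`, `"h5ad"`; default guesses from the
#'   file extension.
#' @param normalized logical flag stored on the returned object; set `TRUE`
#'   when the file already holds normalized values.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "mtx", "csv", "h5ad"),
                            normalized = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", h5ad = "h5ad",
                     stop_format("cannot guess format from extension of ", path))
  }
  if (!file.exists(path)) stop_format("file not found: ", path)
  switch(format,
         mtx = read_expression_mtx(path, normalized),
         csv = read_expression_csv(path, normalized),
         h5ad = read_expression_h5ad(path, normalized))
}

read_expression_mtx <- function(path, normalized) {
  sc <- mtx_sidecar_paths(path)
  for (nm in c("cells", "features")) {
    if (!file.exists(sc[[nm]])) {
      stop_format("missing sidecar file: ", sc[[nm]])
    }
  }
  m <- as.matrix(Matrix::readMM(path))
  cell_ids <- readLines(sc$cells)
  feature_ids <- readLines(sc$features)
  if (nrow(m) != length(cell_ids)) {
    stop_validation("matrix declares ", nrow(m), " rows but ", sc$cells,
                    " lists ", length(cell_ids), " cells")
  }
  if (ncol(m) != length(feature_ids)) {
    stop_validation("matrix declares ", ncol(m), " columns but ", sc$features,
                    " lists ", length(feature_ids), " features")
  }
  meta <- NULL
  if (file.exists(sc$metadata)) {
    meta <- utils::read.delim(sc$metadata, stringsAsFactors = FALSE,
                              colClasses = "character")
  }
  expression_matrix(m, cell_ids, feature_ids, meta, normalized = normalized)
}

read_expression_csv <- function(path, normalized) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop_format("csv must have a cell-id column: ", path)
  cell_ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  meta_path <- file.path(dirname(path),
                         sub("\\.csv$", ".metadata.tsv", basename(path)))
  meta <- if (file.exists(meta_path)) {
    utils::read.delim(meta_path, stringsAsFactors = FALSE,
                      colClasses = "character")
  }
  expression_matrix(m, cell_ids, colnames(m), meta, normalized = normalized)
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]; `mtx` writes the coordinate file plus
#' `cells.tsv`/`features.tsv` (and `metadata.tsv` when metadata is present)
#' next to it, at full double precision so round trips are exact.
#'
#' @param x ExpressionMatrix.
#' @inheritParams read_expression
#' @return invisibly, `path`.
#' @export
write_expression <- function(x, path, format = c("auto", "mtx", "csv", "h5ad")) {
  assert_that(inherits(x, "ExpressionMatrix"), "x must be an ExpressionMatrix")
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", h5ad = "h5ad",
                     stop_format("cannot guess format from extension of ", path))
  }
  switch(format,
         mtx = write_expression_mtx(x, path),
         csv = write_expression_csv(x, path),
         h5ad = write_expression_h5ad(x, path))
  invisible(path)
}

# Coordinate MTX written by hand with %.17g so values survive a round trip
# bit-exactly (Matrix::writeMM prints fewer digits); read back via readMM.
write_expression_mtx <- function(x, path) {
  v <- x$values
  nz <- which(v != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               sprintf("%d %d %d", nrow(v), ncol(v), nrow(nz))), con)
  if (nrow(nz) > 0) {
    writeLines(sprintf("%d %d %.17g", nz[, 1], nz[, 2], v[nz]), con)
  }
  sc <- mtx_sidecar_paths(path)
  writeLines(x$cell_ids, sc$cells)
  writeLines(x$feature_ids, sc$features)
  if (!is.null(x$cell_meta)) {
    utils::write.table(x$cell_meta, sc$metadata, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
}

write_expression_csv <- function(x, path) {
  df <- data.frame(cell_id = x$cell_ids, check.names = FALSE)
  vals <- as.data.frame(x$values)
  names(vals) <- x$feature_ids
  df <- cbind(df, vals)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(x$cell_meta)) {
    meta_path <- file.path(dirname(path),
                           sub("\\.csv$", ".metadata.tsv", basename(path)))
    utils::write.table(x$cell_meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
}

require_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop_format("h5ad support requires the rhdf5 package")
  }
}

# AnnData stores X row-major with shape (n_obs, n_vars); rhdf5 presents HDF5
# dims in reverse, so a dense X arrives as vars x obs and is transposed here.
read_expression_h5ad <- function(path, normalized) {
  require_rhdf5()
  ls <- rhdf5::h5ls(path)
  x_entries <- ls[ls$group == "/" & ls$name == "X", ]
  if (nrow(x_entries) == 0) stop_format("no X entry in ", path)
  if (x_entries$otype[1] == "H5I_GROUP") {
    data <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    attrs <- rhdf5::h5readAttributes(path, "X")
    shape <- as.integer(attrs$shape)
    enc <- attrs[["encoding-type"]] %||% "csr_matrix"
    if (grepl("csr", enc)) {
      m <- Matrix::sparseMatrix(j = indices + 1L, p = indptr, x = data,
                                dims = rev(shape))
      m <- as.matrix(Matrix::t(m))
    } else {
      m <- as.matrix(Matrix::sparseMatrix(i = indices + 1L, p = indptr,
                                          x = data, dims = shape))
    }
  } else {
    m <- t(as.matrix(rhdf5::h5read(path, "X")))
  }
  cell_ids <- as.character(read_h5ad_index(path, "obs"))
  feature_ids <- as.character(read_h5ad_index(path, "var"))
  meta <- data.frame(cell_id = cell_ids, stringsAsFactors = FALSE)
  obs_ls <- ls[ls$group == "/obs", , drop = FALSE]
  for (col in intersect(c("cell_type", "batch", "condition"), obs_ls$name)) {
    meta[[col]] <- read_h5ad_column(path, paste0("obs/", col))
  }
  if (ncol(meta) == 1L) meta <- NULL
  expression_matrix(m, cell_ids, feature_ids, meta, normalized = normalized)
}

read_h5ad_index <- function(path, group) {
  attrs <- rhdf5::h5readAttributes(path, group)
  idx_name <- attrs[["_index"]] %||% "_index"
  read_h5ad_column(path, paste0(group, "/", idx_name))
}

read_h5ad_column <- function(path, name) {
  ls <- rhdf5::h5ls(path)
  entry <- ls[paste0(sub("^/?", "/", ls$group), "/", ls$name) ==
                paste0("/", name), , drop = FALSE]
  if (nrow(entry) > 0 && entry$otype[1] == "H5I_GROUP") {
    codes <- as.integer(rhdf5::h5read(path, paste0(name, "/codes")))
    cats <- as.character(rhdf5::h5read(path, paste0(name, "/categories")))
    return(cats[codes + 1L])
  }
  as.character(rhdf5::h5read(path, name))
}

write_expression_h5ad <- function(x, path) {
  require_rhdf5()
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  # transpose so the stored (reversed) dims read back as (n_obs, n_vars)
  rhdf5::h5write(t(x$values), path, "X")
  rhdf5::h5createGroup(path, "obs")
  rhdf5::h5write(x$cell_ids, path, "obs/_index")
  if (!is.null(x$cell_meta)) {
    for (col in setdiff(names(x$cell_meta), "cell_id")) {
      rhdf5::h5write(as.character(x$cell_meta[[col]]), path,
                     paste0("obs/", col))
    }
  }
  rhdf5::h5createGroup(path, "var")
  rhdf5::h5write(x$feature_ids, path, "var/_index")
  rhdf5::h5closeAll()
}

#' Read a feature/label embedding table
#'
#' Tabular text with the feature (or label) name in the first column and `t`
#' numeric columns; tab-separated by default.
#'
#' @param path file path.
#' @param header logical; whether the file has a header row.
#' @param sep field separator.
#' @return a [feature_embedding_table()].
#' @export
read_embedding_table <- function(path, header = TRUE, sep = "\t") {
  if (!file.exists(path)) stop_format("file not found: ", path)
  lines <- readLines(path)
  if (header && length(lines)) lines <- lines[-1]
  if (!length(lines)) {
    return(feature_embedding_table(character(), matrix(numeric(), 0, 0)))
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop_format("ragged row ", bad + header, " in ", path, ": expected ",
                widths[1], " fields, found ", widths[bad])
  }
  names <- vapply(fields, `[[`, "", 1L)
  vecs <- t(vapply(fields, function(f) as.numeric(f[-1]),
                   numeric(widths[1] - 1L)))
  feature_embedding_table(names, vecs)
}

#' Write a feature/label embedding table
#'
#' @param tab FeatureEmbeddingTable.
#' @param path file path.
#' @param header logical; write a header row.
#' @export
write_embedding_table <- function(tab, path, header = TRUE) {
  assert_that(inherits(tab, "FeatureEmbeddingTable"),
              "tab must be a FeatureEmbeddingTable")
  lines <- character(0)
  if (header) {
    lines <- paste(c("name", paste0("d", seq_len(tab$dim))), collapse = "\t")
  }
  if (length(tab$names)) {
    body <- vapply(seq_along(tab$names), function(i) {
      paste(c(tab$names[i], sprintf("%.17g", tab$vectors[i, ])),
            collapse = "\t")
    }, "")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a cell embedding matrix as TSV
#'
#' @param emb CellEmbeddingMatrix.
#' @param path file path.
#' @export
write_cell_embeddings <- function(emb, path) {
  tab <- feature_embedding_table(emb$cell_ids, emb$vectors)
  write_embedding_table(tab, path)
}

#' Read a cell embedding matrix from TSV
#'
#' @param path file path.
#' @export
read_cell_embeddings <- function(path) {
  tab <- read_embedding_table(path)
  cell_embedding_matrix(tab$names, tab$vectors)
}
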