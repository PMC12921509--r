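# Readers, writers and normalization.

test_that("mtx round trip restores values, ids, metadata and structural zeros", {
  d <- withr::local_tempdir()
  meta <- data.frame(cell_id = c("c01", "c02", "c03"),
                     cell_type = c("A", "B", "A"),
                     batch = c("b1", "b1", "b2"),
                     stringsAsFactors = FALSE)
  v <- matrix(c(1.5, 0, 0.25, 0, 0, 3.75), 3, 2)
  x <- expression_matrix(v, meta$cell_id, c("g01", "g02"), meta,
                         normalized = TRUE)
  p <- file.path(d, "matrix.mtx")
  write_expression(x, p)
  y <- read_expression(p, normalized = TRUE)
  expect_identical(y$values, x$values)   # zeros restored, full precision
  expect_identical(y$cell_ids, x$cell_ids)
  expect_identical(y$feature_ids, x$feature_ids)
  expect_identical(y$cell_meta$cell_type, meta$cell_type)
  expect_identical(names(y$cell_meta), names(meta))

  set.seed(7)
  big <- expression_matrix(matrix(runif(60), 10, 6), normalized = TRUE)
  p2 <- file.path(d, "sub"); dir.create(p2)
  write_expression(big, file.path(p2, "m.mtx"))
  expect_equal(read_expression(file.path(p2, "m.mtx"))$values, big$values,
               tolerance = 0)
})

test_that("csv and mtx encodings of the same matrix agree elementwise", {
  d <- withr::local_tempdir()
  set.seed(11)
  x <- expression_matrix(matrix(runif(20, 0, 10), 5, 4), normalized = TRUE)
  write_expression(x, file.path(d, "m.mtx"))
  write_expression(x, file.path(d, "m.csv"))
  a <- read_expression(file.path(d, "m.mtx"))
  b <- read_expression(file.path(d, "m.csv"))
  expect_equal(a$values, b$values, tolerance = 0)
  expect_identical(a$cell_ids, b$cell_ids)
  expect_identical(a$feature_ids, b$feature_ids)
})

test_that("missing sidecars and dimension mismatches are rejected by name", {
  d <- withr::local_tempdir()
  x <- random_expression(3, 2)
  p <- file.path(d, "matrix.mtx")
  write_expression(x, p)
  file.remove(file.path(d, "features.tsv"))
  expect_error(read_expression(p), "features.tsv")

  writeLines(c("g01", "g02"), file.path(d, "features.tsv"))
  writeLines(c("c1", "c2", "c3", "c4"), file.path(d, "cells.tsv"))
  expect_error(read_expression(p), "4 cells")
})

test_that("empty matrix (0 cells) round trips through mtx and csv", {
  d <- withr::local_tempdir()
  x <- expression_matrix(matrix(numeric(), 0, 3), character(0),
                         c("g1", "g2", "g3"), normalized = TRUE)
  for (f in c("m.mtx", "m.csv")) {
    write_expression(x, file.path(d, f))
    y <- read_expression(file.path(d, f))
    expect_identical(dim(y$values), c(0L, 3L))
    expect_identical(y$feature_ids, x$feature_ids)
  }
})

test_that("feature reordering in file plus sidecar permutes the matrix consistently", {
  d <- withr::local_tempdir()
  x <- random_expression(4, 5, seed = 3)
  write_expression(x, file.path(d, "m.mtx"))
  perm <- c(3, 1, 5, 2, 4)
  xp <- expression_matrix(x$values[, perm], x$cell_ids, x$feature_ids[perm],
                          normalized = TRUE)
  d2 <- file.path(d, "perm"); dir.create(d2)
  write_expression(xp, file.path(d2, "m.mtx"))
  y <- read_expression(file.path(d2, "m.mtx"))
  expect_identical(y$values[, match(x$feature_ids, y$feature_ids)], x$values)
})

test_that("embedding table round trips and rejects malformed input", {
  d <- withr::local_tempdir()
  tab <- random_feats(c("GSN", "ACTB", "TP53"), 4)
  p <- file.path(d, "emb.tsv")
  write_embedding_table(tab, p)
  back <- read_embedding_table(p)
  expect_identical(back$dim, 4L)
  expect_equal(unname(back$vectors), unname(tab$vectors), tolerance = 0)
  expect_identical(back$names, tab$names)

  writeLines(c("name\td1\td2", "a\t1\t2", "b\t3"), p)
  expect_error(read_embedding_table(p), "ragged row 3")
  expect_error(feature_embedding_table(c("a", "a"), matrix(1:4, 2)),
               "duplicate")
})

test_that("normalize_counts scales rows to target then log1p, keeping zero cells", {
  x <- expression_matrix(matrix(c(10, 0, 0, 0), 2, 2), normalized = FALSE)
  y <- normalize_counts(x, target_sum = 10)
  expect_equal(y$values[1, ], c(log(11), 0))
  expect_equal(y$values[2, ], c(0, 0))   # zero-total cell: no division error
  expect_true(y$normalized)

  set.seed(5)
  counts <- matrix(rpois(60, 4), 6, 10)
  z <- normalize_counts(expression_matrix(counts), target_sum = 1e4)
  oracle <- counts
  for (i in 1:6) {
    s <- sum(counts[i, ])
    for (j in 1:10) {
      oracle[i, j] <- log1p(if (s > 0) counts[i, j] * 1e4 / s else 0)
    }
  }
  expect_equal(z$values, oracle, tolerance = 1e-12)
})

test_that("normalization treats duplicated cells identically", {
  set.seed(6)
  counts <- matrix(rpois(20, 6), 2, 10)
  dup <- rbind(counts, counts[1, ])
  y <- normalize_counts(expression_matrix(dup))
  expect_identical(y$values[1, ], y$values[3, ])
})

test_that("h5ad written by anndata reads back with values, obs and var intact", {
  skip_if_not_installed("rhdf5")
  d <- withr::local_tempdir()
  p <- file.path(d, "toy.h5ad")
  script <- sprintf("
import anndata as ad, numpy as np, pandas as pd
X = np.arange(12, dtype=float).reshape(3, 4)
obs = pd.DataFrame({'cell_type': ['A','B','A'], 'batch': ['b1','b2','b1']},
                   index=['c1','c2','c3'])
var = pd.DataFrame(index=['g1','g2','g3','g4'])
ad.AnnData(X=X, obs=obs, var=var).write_h5ad('%s')
", p)
  res <- suppressWarnings(system2("python", "-", input = script,
                                  stdout = TRUE, stderr = TRUE))
  expect_true(file.exists(p))
  x <- read_expression(p, normalized = TRUE)
  expect_identical(x$cell_ids, c("c1", "c2", "c3"))
  expect_identical(x$feature_ids, c("g1", "g2", "g3", "g4"))
  expect_equal(x$values[2, 3], 6)
  expect_identical(cell_meta_column(x, "cell_type"), c("A", "B", "A"))

  # and our own h5ad round trip
  p2 <- file.path(d, "own.h5ad")
  write_expression(x, p2)
  y <- read_expression(p2, normalized = TRUE)
  expect_equal(y$values, x$values, tolerance = 0)
  expect_identical(y$cell_ids, x$cell_ids)
  expect_identical(cell_meta_column(y, "batch"), c("b1", "b2", "b1"))
})

test_that("invalid containers are rejected", {
  expect_error(expression_matrix(matrix(-1, 1, 1)), ">= 0")
  expect_error(expression_matrix(matrix(NA_real_, 1, 1)), "finite")
  expect_error(expression_matrix(matrix(1, 2, 2), c("a", "a"), c("g1", "g2")),
               "unique")
  x <- random_expression(3, 2)
  expect_error(normalize_counts(normalize_counts(expression_matrix(
    matrix(1, 2, 2)))), "already normalized")
})
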