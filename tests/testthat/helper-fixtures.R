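# Shared fixtures: tiny random matrices and embeddings built in code.

random_expression <- function(n, m, seed = 1, normalized = TRUE,
                              meta = NULL) {
  set.seed(seed)
  v <- matrix(runif(n * m, 0, 5), n, m)
  expression_matrix(v, sprintf("c%02d", seq_len(n)),
                    sprintf("g%02d", seq_len(m)), meta,
                    normalized = normalized)
}

random_feats <- function(feature_ids, t, seed = 2) {
  set.seed(seed)
  feature_embedding_table(feature_ids,
                          matrix(rnorm(length(feature_ids) * t),
                                 length(feature_ids), t))
}

emb_subset <- function(emb, idx) {
  cell_embedding_matrix(emb$cell_ids[idx], emb$vectors[idx, , drop = FALSE])
}

small_blobs <- function(n_per = 60, dim = 8, sep = 4, seed = 0) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * dim, 0), n_per, dim),
             matrix(rnorm(n_per * dim, sep), n_per, dim))
  list(emb = cell_embedding_matrix(paste0("c", seq_len(2 * n_per)), x),
       labels = rep(c("A", "B"), each = n_per))
}

# straight-line aggregation oracle: explicit per-cell loop over features
loop_cell_embeddings <- function(values, evecs, mode) {
  n <- nrow(values); m <- ncol(values); t <- ncol(evecs)
  out <- matrix(0, n, t)
  for (i in seq_len(n)) {
    w <- if (mode == "aa") values[i, ] / m else {
      s <- sum(values[i, ]); if (s == 0) rep(0, m) else values[i, ] / s
    }
    for (j in seq_len(m)) out[i, ] <- out[i, ] + w[j] * evecs[j, ]
  }
  out
}

# literal neighbour-walk rule: count neighbours extracted from the
# distance-sorted list before any label would be observed a second time
loop_lisi_raw <- function(neighbor_labels_list) {
  counts <- vapply(neighbor_labels_list, function(labs) {
    seen <- character(0)
    cnt <- 0L
    for (l in labs) {
      if (l %in% seen) break
      seen <- c(seen, l); cnt <- cnt + 1L
    }
    cnt
  }, 0L)
  mean(counts)
}
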