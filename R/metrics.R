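# Evaluation metrics for clustering, batch integration, annotation and
# expression prediction. The integration metrics follow the scIB conventions:
# every score is oriented so that higher = better and lies in [0, 1], and the
# batch-mixing scores (ASW_batch, PCR, GC, kBET, iLISI) and the
# bio-conservation scores (ASW_label, NMI, ARI, cLISI) are averaged into the
# composites S_batch and S_bio.

check_paired_labels <- function(a, b) {
  assert_that(length(a) == length(b),
              "label vectors differ in length (", length(a), " vs ",
              length(b), ")")
  assert_that(length(a) >= 2, "need at least 2 observations")
}

#' Normalized mutual information
#'
#' Mutual information between two labelings divided by the arithmetic mean of
#' their entropies. Returns 0 when either labeling is constant (zero entropy).
#'
#' @param labels_a,labels_b label vectors of equal length.
#' @return value in `[0, 1]`.
#' @export
nmi <- function(labels_a, labels_b) {
  check_paired_labels(labels_a, labels_b)
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  p <- tab / n
  pa <- rowSums(p)
  pb <- colSums(p)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 || hb == 0) return(0)
  outer_p <- outer(pa, pb)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer_p[nz]))
  mi / mean(c(ha, hb))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two labelings, corrected for chance; can
#' be negative for labelings that agree less than expected at random.
#'
#' @inheritParams nmi
#' @return real, at most 1.
#' @export
ari <- function(labels_a, labels_b) {
  check_paired_labels(labels_a, labels_b)
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  s_ij <- sum_comb(tab)
  s_a <- sum_comb(rowSums(tab))
  s_b <- sum_comb(colSums(tab))
  expected <- s_a * s_b / choose(n, 2)
  max_index <- (s_a + s_b) / 2
  if (max_index == expected) return(0)
  (s_ij - expected) / (max_index - expected)
}

silhouette_widths <- function(emb, labels) {
  v <- if (inherits(emb, "CellEmbeddingMatrix")) emb$vectors else as.matrix(emb)
  labels <- as.character(labels)
  assert_that(length(labels) == nrow(v), "one label per cell required")
  assert_that(length(unique(labels)) >= 2,
              "silhouette needs at least 2 distinct labels")
  d <- pairwise_distances(v, "euclidean")
  n <- nrow(v)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1L
    if (n_own == 0L) { s[i] <- 0; next }  # singleton convention
    a_i <- sum(d[i, own]) / n_own
    b_i <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(d[i, labels == l])
    }, 0))
    s[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  s
}

#' Cell-type average silhouette width score
#'
#' Mean silhouette width of cells under their type labels, mapped from
#' `[-1, 1]` to `[0, 1]` via `(s + 1) / 2`. Higher = better type separation.
#'
#' @param emb CellEmbeddingMatrix or numeric matrix.
#' @param labels per-cell type labels (>= 2 distinct).
#' @return value in `[0, 1]`.
#' @export
asw_label <- function(emb, labels) {
  (mean(silhouette_widths(emb, labels)) + 1) / 2
}

#' Batch average silhouette width score
#'
#' As [asw_label()] but over batch labels with the orientation inverted:
#' `1 - (s + 1) / 2`, so perfect batch mixing (silhouette near 0) scores near
#' 0.5 and fully separated batches score near 0.
#'
#' @param emb CellEmbeddingMatrix or numeric matrix.
#' @param batch_labels per-cell batch labels (>= 2 batches).
#' @return value in `[0, 1]`.
#' @export
asw_batch <- function(emb, batch_labels) {
  1 - (mean(silhouette_widths(emb, batch_labels)) + 1) / 2
}

# Per-cell simplified LISI walk: traverse the distance-sorted neighbour list
# and count how many neighbours are extracted before any label would be seen
# a second time.
lisi_raw_counts <- function(graph, labels) {
  labels <- as.character(labels)
  vapply(seq_len(graph$n), function(i) {
    nb_labels <- labels[graph$idx[i, ]]
    count <- 0L
    seen <- character(0)
    for (l in nb_labels) {
      if (l %in% seen) break
      seen <- c(seen, l)
      count <- count + 1L
    }
    count
  }, 0L)
}

#' Simplified local inverse Simpson's index
#'
#' For each cell, walks its distance-sorted neighbour list counting neighbours
#' extracted before any label repeats; the counts are averaged into a raw
#' score and normalized: `iLISI = (raw - 1) / (B - 1)` over `B` batches
#' (higher = better mixing) and `cLISI = 1 - (raw - 1) / (C - 1)` over `C`
#' cell types (higher = purer neighbourhoods). Clipped to `[0, 1]`.
#'
#' @param graph NeighborGraph from [knn_graph()].
#' @param labels per-cell batch or type labels.
#' @param mode `"ilisi"` or `"clisi"`.
#' @param n_classes number of batches/types for the normalization; default the
#'   number of distinct labels.
#' @return value in `[0, 1]`.
#' @export
lisi <- function(graph, labels, mode = c("ilisi", "clisi"), n_classes = NULL) {
  mode <- match.arg(mode)
  assert_that(length(labels) == graph$n, "one label per cell required")
  n_classes <- n_classes %||% length(unique(labels))
  assert_that(n_classes >= 2,
              "LISI normalization needs >= 2 classes, got ", n_classes)
  raw <- mean(lisi_raw_counts(graph, labels))
  val <- (raw - 1) / (n_classes - 1)
  if (mode == "clisi") val <- 1 - val
  min(max(val, 0), 1)
}

#' Graph connectivity
#'
#' For each cell type, the fraction of that type's cells in the largest
#' connected component of the kNN subgraph induced on the type; averaged over
#' types. 1 when every type forms a single connected community.
#'
#' @param graph NeighborGraph.
#' @param type_labels per-cell type labels.
#' @return value in `(0, 1]`.
#' @export
graph_connectivity <- function(graph, type_labels) {
  type_labels <- as.character(type_labels)
  assert_that(length(type_labels) == graph$n, "one label per cell required")
  g <- knn_igraph(graph)
  scores <- vapply(unique(type_labels), function(tp) {
    cells <- which(type_labels == tp)
    sub <- igraph::induced_subgraph(g, cells)
    comp <- igraph::components(sub)
    max(comp$csize) / length(cells)
  }, 0)
  mean(scores)
}

#' Principal-component regression batch score
#'
#' Computes PCs of the embedding, regresses each PC score on batch indicators,
#' and accumulates batch-explained variance as the variance-fraction-weighted
#' sum of the per-PC R-squared values. The returned score is
#' `1 - batch_variance`, so higher = less batch signal; set
#' `raw = TRUE` for the batch-variance itself.
#'
#' @param emb_or_expr CellEmbeddingMatrix or numeric matrix (cells in rows).
#' @param batch_labels per-cell batch labels (>= 2 batches).
#' @param n_pcs number of PCs (default `min(50, n - 1, dim)`).
#' @param raw return the batch-explained variance fraction instead.
#' @return value in `[0, 1]`.
#' @export
pc_regression_score <- function(emb_or_expr, batch_labels, n_pcs = NULL,
                                raw = FALSE) {
  v <- if (inherits(emb_or_expr, "CellEmbeddingMatrix")) emb_or_expr$vectors
       else as.matrix(emb_or_expr)
  batch_labels <- factor(batch_labels)
  assert_that(nlevels(batch_labels) >= 2, "need >= 2 batches")
  assert_that(length(batch_labels) == nrow(v), "one label per cell required")
  n_pcs <- n_pcs %||% min(50L, nrow(v) - 1L, ncol(v))
  assert_that(n_pcs >= 1 && n_pcs <= min(nrow(v) - 1L, ncol(v)),
              "n_pcs out of range")
  pca <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  scores <- pca$x[, seq_len(n_pcs), drop = FALSE]
  vars <- pca$sdev[seq_len(n_pcs)]^2
  # R2 of a PC on batch indicators = 1 - within-batch SS / total SS
  r2s <- vapply(seq_len(n_pcs), function(i) {
    if (vars[i] < 1e-12) return(0)
    s <- scores[, i]
    within <- sum(unlist(lapply(split(s, batch_labels),
                                function(g) (g - mean(g))^2)))
    1 - within / sum((s - mean(s))^2)
  }, 0)
  batch_var <- sum((vars / sum(vars)) * r2s)
  if (raw) batch_var else 1 - batch_var
}

#' kBET batch-mixing score
#'
#' Per cell, a chi-squared goodness-of-fit test of the batch composition of
#' its k nearest neighbours against the global batch proportions; the score is
#' the fraction of cells whose neighbourhood is NOT rejected at level `alpha`
#' (acceptance rate), so higher = better mixing.
#'
#' @param graph NeighborGraph (k of 10+ recommended).
#' @param batch_labels per-cell batch labels.
#' @param alpha significance level (default 0.05); a neighbourhood is accepted
#'   when its p-value exceeds `alpha`.
#' @return value in `[0, 1]`.
#' @export
kbet_score <- function(graph, batch_labels, alpha = 0.05) {
  batch_labels <- factor(batch_labels)
  assert_that(length(batch_labels) == graph$n, "one label per cell required")
  glob <- table(batch_labels)
  assert_that(all(glob > 0), "batch with zero cells: ",
              paste(names(glob)[glob == 0], collapse = ", "))
  assert_that(nlevels(batch_labels) >= 2, "need >= 2 batches")
  props <- as.numeric(glob) / sum(glob)
  k <- ncol(graph$idx)
  dof <- nlevels(batch_labels) - 1L
  pvals <- vapply(seq_len(graph$n), function(i) {
    obs <- tabulate(as.integer(batch_labels[graph$idx[i, ]]),
                    nbins = nlevels(batch_labels))
    expd <- k * props
    stat <- sum((obs - expd)^2 / expd)
    stats::pchisq(stat, dof, lower.tail = FALSE)
  }, 0)
  mean(pvals > alpha)
}

#' Full integration report
#'
#' Computes every batch-mixing and bio-conservation metric on one shared kNN
#' graph and composes `s_batch = mean(asw_batch, pcr, gc, kbet, ilisi)` and
#' `s_bio = mean(asw_label, nmi, ari, clisi)`. NMI/ARI compare Leiden clusters
#' of the embedding against the type labels; negative ARI is clipped to 0
#' before entering the composite.
#'
#' @param emb CellEmbeddingMatrix.
#' @param type_labels per-cell type labels (>= 2 types).
#' @param batch_labels per-cell batch labels (>= 2 batches).
#' @param k neighbours for the shared graph used by GC/kBET/LISI (default 50,
#'   clipped to n - 1).
#' @param cluster_k neighbours for the clustering graph (default 30).
#' @param resolution Leiden resolution; when `scan_resolution = TRUE` the
#'   resolutions 0.1, 0.2, ..., 2.0 are scanned and the best NMI/ARI reported
#'   (scIB-style "optimal" clustering).
#' @param seed seed for clustering.
#' @param scan_resolution logical, default `FALSE`.
#' @return object of class `IntegrationReport`: a list with fields
#'   `asw_label`, `nmi`, `ari`, `clisi`, `asw_batch`, `pcr`, `gc`, `kbet`,
#'   `ilisi`, `s_batch`, `s_bio`.
#' @export
integration_report <- function(emb, type_labels, batch_labels, k = 50,
                               cluster_k = 30, resolution = 1, seed = 0L,
                               scan_resolution = FALSE) {
  type_labels <- as.character(type_labels)
  batch_labels <- as.character(batch_labels)
  assert_that(length(unique(type_labels)) >= 2, "need >= 2 cell types")
  assert_that(length(unique(batch_labels)) >= 2, "need >= 2 batches")
  n <- length(emb$cell_ids)
  graph <- suppressWarnings(knn_graph(emb, min(k, n - 1)))
  resolutions <- if (scan_resolution) seq(0.1, 2.0, by = 0.1) else resolution
  nmi_v <- ari_v <- -Inf
  for (r in resolutions) {
    cl <- cluster_cells(emb, k = cluster_k, resolution = r, seed = seed)
    nmi_v <- max(nmi_v, nmi(cl, type_labels))
    ari_v <- max(ari_v, ari(cl, type_labels))
  }
  rep <- list(
    asw_label = asw_label(emb, type_labels),
    nmi = nmi_v,
    ari = ari_v,
    clisi = lisi(graph, type_labels, "clisi"),
    asw_batch = asw_batch(emb, batch_labels),
    pcr = pc_regression_score(emb, batch_labels),
    gc = graph_connectivity(graph, type_labels),
    kbet = kbet_score(graph, batch_labels),
    ilisi = lisi(graph, batch_labels, "ilisi")
  )
  rep$s_batch <- mean(c(rep$asw_batch, rep$pcr, rep$gc, rep$kbet, rep$ilisi))
  rep$s_bio <- mean(c(rep$asw_label, rep$nmi, max(rep$ari, 0), rep$clisi))
  structure(rep, class = "IntegrationReport")
}

#' @export
print.IntegrationReport <- function(x, ...) {
  cat(sprintf(paste0("IntegrationReport: s_batch %.3f  s_bio %.3f\n",
                     "  batch: asw %.3f pcr %.3f gc %.3f kbet %.3f ilisi %.3f\n",
                     "  bio:   asw %.3f nmi %.3f ari %.3f clisi %.3f\n"),
              x$s_batch, x$s_bio, x$asw_batch, x$pcr, x$gc, x$kbet, x$ilisi,
              x$asw_label, x$nmi, x$ari, x$clisi))
  invisible(x)
}

#' Clipped n-gram precision (single-n BLEU)
#'
#' The fraction of candidate n-grams that also occur in the reference, with
#' per-n-gram counts clipped at the reference count. Tokens are compared after
#' lowercasing; candidates shorter than `n` tokens score 0 by convention.
#'
#' @param candidate,reference character strings (whitespace-tokenized) or
#'   token vectors.
#' @param n n-gram order (default 1).
#' @return value in `[0, 1]`.
#' @export
bleu_n <- function(candidate, reference, n = 1L) {
  assert_that(n >= 1, "n must be >= 1")
  tok <- function(x) {
    if (length(x) == 1L) x <- strsplit(trimws(x), "\\s+")[[1]]
    tolower(x[nzchar(x)])
  }
  cand <- tok(candidate)
  ref <- tok(reference)
  if (length(cand) < n) return(0)
  ngrams <- function(tk) {
    vapply(seq_len(length(tk) - n + 1L), function(i) {
      paste(tk[i:(i + n - 1L)], collapse = " ")
    }, "")
  }
  cg <- table(ngrams(cand))
  rg <- if (length(ref) >= n) table(ngrams(ref)) else table(character())
  clipped <- vapply(names(cg), function(s) {
    min(cg[[s]], if (s %in% names(rg)) rg[[s]] else 0)
  }, 0)
  sum(clipped) / sum(cg)
}

#' Classification scores
#'
#' Accuracy plus macro-averaged precision, recall and F1 over the classes
#' present in the true labels; a class never predicted contributes precision 0
#' (micro averaging available via `average = "micro"`).
#'
#' @param pred_labels,true_labels label vectors of equal length.
#' @param average `"macro"` (default) or `"micro"`.
#' @return named list with `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_scores <- function(pred_labels, true_labels,
                                  average = c("macro", "micro")) {
  average <- match.arg(average)
  check_paired_labels(pred_labels, true_labels)
  pred <- as.character(pred_labels)
  true <- as.character(true_labels)
  acc <- mean(pred == true)
  classes <- sort(unique(true))
  tp <- vapply(classes, function(cl) sum(pred == cl & true == cl), 0)
  fp <- vapply(classes, function(cl) sum(pred == cl & true != cl), 0)
  fn <- vapply(classes, function(cl) sum(pred != cl & true == cl), 0)
  if (average == "micro") {
    prec <- sum(tp) / max(sum(tp) + sum(fp), 1)
    rec <- sum(tp) / max(sum(tp) + sum(fn), 1)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  } else {
    p_cl <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
    r_cl <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
    f_cl <- ifelse(p_cl + r_cl == 0, 0, 2 * p_cl * r_cl / (p_cl + r_cl))
    prec <- mean(p_cl)
    rec <- mean(r_cl)
    f1 <- mean(f_cl)
  }
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

#' Coefficient of determination
#'
#' `R2 = 1 - SS_res / SS_tot`.
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @return real (at most 1; negative when worse than the mean predictor).
#' @export
r2 <- function(y_true, y_pred) {
  assert_that(length(y_true) == length(y_pred), "length mismatch")
  ss_tot <- sum((y_true - mean(y_true))^2)
  assert_that(ss_tot > 0, "R2 undefined for constant y_true")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Mean per-gene Pearson correlation
#'
#' Pearson correlation between observed and predicted expression computed per
#' gene (column) and averaged; genes constant in either matrix are skipped
#' with a warning.
#'
#' @param y_true,y_pred cells x genes matrices of equal shape.
#' @return value in `[-1, 1]`.
#' @export
pcc_genes <- function(y_true, y_pred) {
  assert_that(all(dim(y_true) == dim(y_pred)), "shape mismatch")
  keep <- vapply(seq_len(ncol(y_true)), function(j) {
    stats::sd(y_true[, j]) > 0 && stats::sd(y_pred[, j]) > 0
  }, TRUE)
  if (!all(keep)) {
    warning("skipping ", sum(!keep), " zero-variance genes")
  }
  assert_that(any(keep), "no gene with variance in both matrices")
  mean(vapply(which(keep), function(j) {
    stats::cor(y_true[, j], y_pred[, j])
  }, 0))
}

#' Mean squared error over all matrix entries
#'
#' @param y_true,y_pred matrices of equal shape.
#' @return nonnegative real.
#' @export
mse_genes <- function(y_true, y_pred) {
  assert_that(all(dim(y_true) == dim(y_pred)), "shape mismatch")
  mean((y_true - y_pred)^2)
}
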