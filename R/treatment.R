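# In-silico treatment screen: candidate genes (top DEGs between diseased and
# control cells) are deleted one at a time; a gene whose deletion moves the
# mean diseased embedding toward the mean control embedding — i.e. raises the
# cosine similarity between the two condition means by more than a small
# threshold — is flagged as a potential therapeutic target.
#     Score(g) = CS_new - CS_old,   candidate iff Score(g) > 1e-4.

#' Select top differentially expressed genes between two conditions
#'
#' Per-gene two-sample Wilcoxon rank-sum test between diseased and control
#' cells with Benjamini-Hochberg adjustment, ranked by adjusted p-value and
#' then by absolute mean log-expression difference.
#'
#' @param x ExpressionMatrix (normalized).
#' @param condition_labels per-cell condition labels.
#' @param diseased,control condition values to compare (each with >= 2 cells).
#' @param n_top number of genes to return (default 10).
#' @return character vector of gene names, strongest first.
#' @export
select_top_degs <- function(x, condition_labels, diseased, control,
                            n_top = 10) {
  condition_labels <- as.character(condition_labels)
  assert_that(length(condition_labels) == length(x$cell_ids),
              "one condition label per cell required")
  for (lab in c(diseased, control)) {
    assert_that(sum(condition_labels == lab) >= 2,
                "condition '", lab, "' needs >= 2 cells")
  }
  vd <- x$values[condition_labels == diseased, , drop = FALSE]
  vc <- x$values[condition_labels == control, , drop = FALSE]
  pvals <- vapply(seq_len(ncol(vd)), function(j) {
    if (all(vd[, j] == vd[1, j]) && all(vc[, j] == vd[1, j])) return(1)
    suppressWarnings(stats::wilcox.test(vd[, j], vc[, j])$p.value)
  }, 0)
  padj <- stats::p.adjust(pvals, method = "BH")
  effect <- abs(colMeans(vd) - colMeans(vc))
  ord <- order(padj, -effect)
  x$feature_ids[utils::head(ord, n_top)]
}

#' Cosine similarity between condition mean embeddings
#'
#' @param emb CellEmbeddingMatrix.
#' @param condition_labels per-cell condition labels.
#' @param diseased,control condition values.
#' @return value in `[-1, 1]`.
#' @export
condition_cosine <- function(emb, condition_labels, diseased, control) {
  condition_labels <- as.character(condition_labels)
  assert_that(length(condition_labels) == length(emb$cell_ids),
              "one condition label per cell required")
  mu_d <- colMeans(emb$vectors[condition_labels == diseased, , drop = FALSE])
  mu_c <- colMeans(emb$vectors[condition_labels == control, , drop = FALSE])
  nd <- sqrt(sum(mu_d^2)); nc <- sqrt(sum(mu_c^2))
  assert_that(nd > 0 && nc > 0, "zero mean embedding vector")
  sum(mu_d * mu_c) / (nd * nc)
}

embed_pipeline <- function(x, feats, mode, model = NULL) {
  emb <- cell_embeddings(x, feats, mode)
  if (!is.null(model)) emb <- adaptor_embed(model, emb)
  emb
}

#' Score one gene by in-silico deletion
#'
#' Embeds the data (aggregation, then the trained adaptor latent when a model
#' is supplied) to get `CS_old`; zeroes the gene's expression, re-aggregates
#' (under `wa` the remaining genes renormalize over the reduced row sums) and
#' re-embeds with the same trained model to get `CS_new`.
#'
#' @param g gene name.
#' @param x ExpressionMatrix.
#' @param feats FeatureEmbeddingTable.
#' @param mode aggregation mode.
#' @param model optional TrainedAdaptor used as the embedding function.
#' @inheritParams condition_cosine
#' @return named list `cs_old`, `cs_new`, `score`.
#' @export
score_gene <- function(g, x, feats, mode = c("wa", "aa"), model = NULL,
                       condition_labels, diseased, control) {
  mode <- match.arg(mode)
  assert_that(g %in% x$feature_ids, "unknown gene: ", g)
  cs_old <- condition_cosine(embed_pipeline(x, feats, mode, model),
                             condition_labels, diseased, control)
  cs_new <- condition_cosine(
    embed_pipeline(delete_genes(x, g), feats, mode, model),
    condition_labels, diseased, control)
  list(cs_old = cs_old, cs_new = cs_new, score = cs_new - cs_old)
}

#' Screen candidate genes for therapeutic targets
#'
#' Scores each candidate gene with [score_gene()] and flags candidates whose
#' score strictly exceeds `threshold`.
#'
#' @inheritParams score_gene
#' @param candidates gene list; defaults to [select_top_degs()] output with
#'   `n_top = 10`.
#' @param threshold candidacy threshold on the score (default `1e-4`, strict
#'   inequality).
#' @param n_top candidate pool size when `candidates` is NULL.
#' @return data.frame with columns `gene`, `cs_old`, `cs_new`, `score`,
#'   `is_candidate`, sorted by score descending.
#' @export
screen_targets <- function(x, feats, mode = c("wa", "aa"), model = NULL,
                           condition_labels, diseased, control,
                           candidates = NULL, threshold = 1e-4, n_top = 10) {
  mode <- match.arg(mode)
  if (is.null(candidates)) {
    candidates <- select_top_degs(x, condition_labels, diseased, control,
                                  n_top = n_top)
  }
  rows <- lapply(candidates, function(g) {
    s <- score_gene(g, x, feats, mode, model, condition_labels, diseased,
                    control)
    data.frame(gene = g, cs_old = s$cs_old, cs_new = s$cs_new,
               score = s$score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$is_candidate <- out$score > threshold
  out[order(-out$score), , drop = FALSE]
}
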