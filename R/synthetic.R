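# Seeded generators for embedding tables and expression data with the
# statistical structure the pipeline assumes: gene-function groups that double
# as embedding blocks and expression programs (coupling the two modalities),
# negative-binomial counts with log-scale type programs and additive batch
# offsets, and a disease fixture with a planted driver gene plus a correlated
# downstream module.

#' Synthetic data specification
#'
#' @param n_cells cells per generated condition (default 400).
#' @param n_genes genes (default 100).
#' @param n_cell_types cell types (default 2).
#' @param n_batches batches (default 1).
#' @param n_gene_groups gene-function groups (default 10).
#' @param embed_dim embedding dimension t (default 64).
#' @param type_separation log-scale mean elevation of a type's gene programs
#'   (default 2).
#' @param batch_shift scale of the additive log-space per-gene batch offsets
#'   (default 1; batch 1 is the unshifted reference).
#' @param group_coherence weight of the shared group anchor vs private noise
#'   in gene embeddings, in `[0, 1]` (default 0.8).
#' @param nb_dispersion negative-binomial size parameter; smaller = more
#'   overdispersed counts (default 2).
#' @param planted_driver_genes number of disease driver genes (default 1).
#' @param driver_effect log-scale elevation of driver genes in diseased cells
#'   (default 3); the downstream module responds at 0.15 x this value.
#' @param seed integer seed.
#' @export
synth_spec <- function(n_cells = 400L, n_genes = 100L, n_cell_types = 2L,
                       n_batches = 1L, n_gene_groups = 10L, embed_dim = 64L,
                       type_separation = 2, batch_shift = 1,
                       group_coherence = 0.8, nb_dispersion = 2,
                       planted_driver_genes = 1L, driver_effect = 3,
                       seed = 0L) {
  assert_that(group_coherence >= 0 && group_coherence <= 1,
              "group_coherence must be in [0, 1]")
  assert_that(nb_dispersion > 0, "nb_dispersion must be positive")
  spec <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
               n_cell_types = as.integer(n_cell_types),
               n_batches = as.integer(n_batches),
               n_gene_groups = as.integer(n_gene_groups),
               embed_dim = as.integer(embed_dim),
               type_separation = type_separation, batch_shift = batch_shift,
               group_coherence = group_coherence,
               nb_dispersion = nb_dispersion,
               planted_driver_genes = as.integer(planted_driver_genes),
               driver_effect = driver_effect, seed = as.integer(seed))
  for (f in c("n_cells", "n_genes", "n_cell_types", "n_batches",
              "n_gene_groups", "embed_dim")) {
    assert_that(spec[[f]] >= 1, f, " must be >= 1")
  }
  structure(spec, class = "SynthSpec")
}

synth_gene_names <- function(spec) sprintf("g%03d", seq_len(spec$n_genes))

# Group assignment shared by the embedding and expression generators. Driver
# genes (the first planted_driver_genes genes) get private singleton groups so
# their embedding direction is unique; remaining genes are assigned round-robin
# to the regular groups.
synth_gene_groups <- function(spec) {
  groups <- rep_len(seq_len(spec$n_gene_groups), spec$n_genes)
  d <- spec$planted_driver_genes
  if (d > 0 && d < spec$n_genes) {
    groups[seq_len(d)] <- spec$n_gene_groups + seq_len(d)
  }
  groups
}

#' Generate a gene embedding table with group block structure
#'
#' Each gene's vector is `normalize(c * anchor_g + (1 - c) * noise)` where
#' `anchor_g` is its group's shared unit vector and `c` is the group
#' coherence, emulating embeddings in which genes with similar roles lie
#' proximally.
#'
#' @param spec [synth_spec()].
#' @return list with `table` (FeatureEmbeddingTable) and `groups` (per-gene
#'   integer group ids).
#' @export
synth_feature_embeddings <- function(spec) {
  groups <- synth_gene_groups(spec)
  with_seed(spec$seed + 1L, {
    t <- spec$embed_dim
    n_anchor <- max(groups)
    anchors <- l2_normalize_rows(matrix(stats::rnorm(n_anchor * t),
                                        n_anchor, t))
    noise <- l2_normalize_rows(matrix(stats::rnorm(spec$n_genes * t),
                                      spec$n_genes, t))
    vecs <- spec$group_coherence * anchors[groups, , drop = FALSE] +
      (1 - spec$group_coherence) * noise
    vecs <- l2_normalize_rows(vecs)
    list(table = feature_embedding_table(synth_gene_names(spec), vecs),
         groups = groups)
  })
}

# per-type log-scale programs over genes: type k elevates the regular groups
# assigned to it (round-robin); driver singleton groups stay baseline
synth_type_programs <- function(spec, baseline) {
  groups <- synth_gene_groups(spec)
  programs <- matrix(rep(baseline, each = spec$n_cell_types),
                     spec$n_cell_types, spec$n_genes)
  for (g in seq_len(spec$n_gene_groups)) {
    ty <- ((g - 1L) %% spec$n_cell_types) + 1L
    programs[ty, groups == g] <- programs[ty, groups == g] +
      spec$type_separation
  }
  programs
}

synth_counts <- function(spec, log_mu) {
  counts <- matrix(stats::rnbinom(length(log_mu), mu = exp(log_mu),
                                  size = spec$nb_dispersion),
                   nrow(log_mu), ncol(log_mu))
  counts
}

#' Generate a synthetic expression dataset
#'
#' Negative-binomial counts around `exp(baseline + type program + batch
#' offset)`, then library-size log-normalization. Cell types and batches are
#' interleaved over cells so types are represented in every batch.
#'
#' @param spec [synth_spec()].
#' @param n_cells override for the number of cells (default `spec$n_cells`).
#' @return list with `expression` (normalized ExpressionMatrix with cell_type
#'   and batch metadata), `programs` (types x genes log-mean matrix),
#'   `groups` (per-gene group ids).
#' @export
synth_expression <- function(spec, n_cells = spec$n_cells) {
  with_seed(spec$seed + 2L, {
    baseline <- stats::rnorm(spec$n_genes, 0, 0.3)
    programs <- synth_type_programs(spec, baseline)
    batch_offsets <- matrix(0, spec$n_batches, spec$n_genes)
    if (spec$n_batches > 1) {
      for (b in 2:spec$n_batches) {
        batch_offsets[b, ] <- stats::rnorm(spec$n_genes, 0, spec$batch_shift)
      }
    }
    types <- rep_len(seq_len(spec$n_cell_types), n_cells)
    batches <- rep_len(rep(seq_len(spec$n_batches),
                           each = spec$n_cell_types), n_cells)
    log_mu <- programs[types, , drop = FALSE] +
      batch_offsets[batches, , drop = FALSE]
    counts <- synth_counts(spec, log_mu)
    meta <- data.frame(cell_id = sprintf("c%04d", seq_len(n_cells)),
                       cell_type = paste0("type", types),
                       batch = paste0("batch", batches),
                       stringsAsFactors = FALSE)
    raw <- expression_matrix(counts, meta$cell_id, synth_gene_names(spec),
                             meta, normalized = FALSE)
    list(expression = normalize_counts(raw), programs = programs,
         groups = synth_gene_groups(spec))
  })
}

#' Generate a synthetic disease dataset with planted driver genes
#'
#' Control cells follow [synth_expression()]'s generative model; diseased
#' cells are drawn from the same programs with the driver genes elevated by
#' `driver_effect` and a downstream module (20% of the first regular gene
#' group) elevated by `0.15 * driver_effect`. Zeroing a driver therefore
#' moves the aggregated diseased mean embedding toward the control mean.
#'
#' @param spec [synth_spec()] with `planted_driver_genes >= 1`.
#' @return list with `expression` (normalized ExpressionMatrix with
#'   cell_type and condition metadata; `n_cells` control + `n_cells` diseased
#'   cells), `drivers` (driver gene names), `module_genes` (downstream module
#'   gene names).
#' @export
synth_disease <- function(spec) {
  assert_that(spec$planted_driver_genes >= 1,
              "planted_driver_genes must be >= 1")
  genes <- synth_gene_names(spec)
  groups <- synth_gene_groups(spec)
  drivers <- genes[seq_len(spec$planted_driver_genes)]
  g1 <- setdiff(which(groups == 1L), seq_len(spec$planted_driver_genes))
  module_idx <- g1[seq_len(max(1L, floor(0.2 * length(g1))))]
  with_seed(spec$seed + 3L, {
    baseline <- stats::rnorm(spec$n_genes, 0, 0.3)
    programs <- synth_type_programs(spec, baseline)
    disease_shift <- numeric(spec$n_genes)
    disease_shift[seq_len(spec$planted_driver_genes)] <- spec$driver_effect
    disease_shift[module_idx] <- 0.15 * spec$driver_effect
    n <- spec$n_cells
    types <- rep_len(seq_len(spec$n_cell_types), n)
    log_mu_ctrl <- programs[types, , drop = FALSE]
    log_mu_dis <- sweep(log_mu_ctrl, 2, disease_shift, "+")
    counts <- rbind(synth_counts(spec, log_mu_ctrl),
                    synth_counts(spec, log_mu_dis))
    meta <- data.frame(cell_id = sprintf("c%04d", seq_len(2L * n)),
                       cell_type = paste0("type", c(types, types)),
                       condition = rep(c("control", "disease"), each = n),
                       stringsAsFactors = FALSE)
    raw <- expression_matrix(counts, meta$cell_id, genes, meta,
                             normalized = FALSE)
    list(expression = normalize_counts(raw), drivers = drivers,
         module_genes = genes[module_idx])
  })
}
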