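# Metric formulas: clustering agreement, silhouette scores, LISI walk, graph
# connectivity, PC regression, kBET, BLEU, classification and regression
# scores, and the composite report.

test_that("nmi matches a contingency-entropy oracle and handles endpoints", {
  a <- c(1, 1, 2, 2, 3, 3)
  b <- c(1, 1, 2, 3, 3, 3)
  # direct oracle from the contingency table
  tab <- table(a, b) / 6
  pa <- rowSums(tab); pb <- colSums(tab)
  mi <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb)) {
    if (tab[i, j] > 0) mi <- mi + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
  }
  h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  expect_equal(nmi(a, b), unname(mi / mean(c(h(pa), h(pb)))),
               tolerance = 1e-12)

  expect_equal(nmi(a, a), 1.0)
  expect_equal(nmi(c("x", "y", "x"), c("A", "A", "A")), 0.0)
  expect_equal(nmi(a, b), nmi(b, a))
  # invariance to label renaming
  expect_equal(nmi(a, b), nmi(letters[a], LETTERS[b]))
  expect_error(nmi(1:3, 1:4), "length")
})

test_that("ari matches the pair-count closed form", {
  expect_equal(ari(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(ari(c(1, 1, 2, 2), c("b", "b", "a", "a")), 1.0)
  expect_equal(ari(c(1, 1, 1, 1), c(1, 2, 1, 2)), 0.0)
  a <- c(1, 1, 1, 2, 2, 3); b <- c(1, 2, 1, 2, 2, 3)
  expect_equal(ari(a, b), ari(b, a))
  skip_if_not_installed("mclust")
  set.seed(30)
  for (i in 1:5) {
    x <- sample(1:3, 12, replace = TRUE)
    y <- sample(1:4, 12, replace = TRUE)
    expect_equal(ari(x, y), mclust::adjustedRandIndex(x, y),
                 tolerance = 1e-12)
  }
})

test_that("silhouette scores match the loop/cluster oracle and map endpoints", {
  pts <- rbind(c(0, 0), c(0.5, 0), c(0.2, 0.3),
               c(10, 10), c(10.5, 10), c(10.2, 10.3))
  labs <- rep(c("A", "B"), each = 3)
  got <- asw_label(pts, labs)
  skip_if_not_installed("cluster")
  sil <- cluster::silhouette(as.integer(factor(labs)), dist(pts))
  expect_equal(got, (mean(sil[, "sil_width"]) + 1) / 2, tolerance = 1e-12)
  expect_equal(asw_batch(pts, labs), 1 - got, tolerance = 1e-12)

  # duplicated tight blobs: raw silhouette exactly 1 -> asw_label 1, asw_batch 0
  dup <- rbind(c(0, 0), c(0, 0), c(100, 100), c(100, 100))
  labs2 <- c("A", "A", "B", "B")
  expect_equal(asw_label(dup, labs2), 1.0)
  expect_equal(asw_batch(dup, labs2), 0.0)
  expect_error(asw_label(dup, rep("A", 4)), "2 distinct")
})

test_that("perfectly mixed duplicated batches give asw_batch near 0.5", {
  set.seed(31)
  cloud <- matrix(rnorm(100), 50, 2)
  emb <- rbind(cloud, cloud)
  batch <- rep(c("b1", "b2"), each = 50)
  expect_equal(asw_batch(emb, batch), 0.5, tolerance = 0.05)
})

test_that("lisi walk matches the literal rule, with exact endpoints", {
  # hand-built graph whose neighbour lists strictly alternate A,B -> raw 2
  g <- structure(list(k = 3, n = 4,
                      idx = rbind(c(2L, 3L, 4L), c(1L, 4L, 3L),
                                  c(4L, 1L, 2L), c(3L, 2L, 1L)),
                      dist = matrix(1:3, 4, 3, byrow = TRUE),
                      metric = "euclidean"),
                 class = "NeighborGraph")
  batch <- c("A", "B", "A", "B")
  expect_equal(lisi(g, batch, "ilisi"), 1.0)
  # all one batch would break normalization; mono-batch neighbourhoods:
  # two far clouds, each pure -> raw 1 -> ilisi 0, and clisi 1 under types
  pure <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 50), 10, 2))
  lab <- rep(c("A", "B"), each = 10)
  g2 <- knn_graph(pure, 5)
  expect_equal(lisi(g2, lab, "ilisi"), 0.0)
  expect_equal(lisi(g2, lab, "clisi"), 1.0)

  # random instance vs a literal re-implementation of the walk
  set.seed(32)
  v <- matrix(rnorm(40), 20, 2)
  labs <- sample(c("x", "y", "z"), 20, replace = TRUE)
  g3 <- knn_graph(v, 8)
  nb_labels <- lapply(1:20, function(i) labs[g3$idx[i, ]])
  raw <- loop_lisi_raw(nb_labels)
  expect_equal(lisi(g3, labs, "ilisi", n_classes = 3), (raw - 1) / 2,
               tolerance = 1e-12)
  expect_equal(lisi(g3, labs, "clisi", n_classes = 3), 1 - (raw - 1) / 2,
               tolerance = 1e-12)
  expect_error(lisi(g3, rep("A", 20), "ilisi"), ">= 2")
})

test_that("graph connectivity is the mean largest-component fraction per type", {
  # one type fully connected
  line <- cbind(1:6, 0)
  g <- knn_graph(line, 2)
  expect_equal(graph_connectivity(g, rep("A", 6)), 1.0)
  # one type split into two equal unreachable clumps -> 0.5
  clumps <- cbind(c(0, 1, 100, 101), 0)
  g2 <- knn_graph(clumps, 1)
  expect_equal(graph_connectivity(g2, rep("A", 4)), 0.5)

  # random graph vs an independent union-find oracle
  set.seed(33)
  v <- matrix(rnorm(60), 30, 2)
  labs <- sample(c("A", "B"), 30, replace = TRUE)
  g3 <- knn_graph(v, 2)
  find <- function(p, i) { while (p[i] != i) i <- p[i]; i }
  oracle <- vapply(unique(labs), function(tp) {
    cells <- which(labs == tp)
    p <- seq_along(cells)
    for (a in seq_along(cells)) for (b in g3$idx[cells[a], ]) {
      j <- match(b, cells)
      if (!is.na(j)) {
        ra <- find(p, a); rb <- find(p, j)
        p[ra] <- rb
      }
    }
    roots <- vapply(seq_along(cells), function(i) find(p, i), 0L)
    max(table(roots)) / length(cells)
  }, 0)
  expect_equal(graph_connectivity(g3, labs), mean(oracle), tolerance = 1e-12)
})

test_that("pc regression scores batch-free and batch-dominated data correctly", {
  set.seed(34)
  v <- matrix(rnorm(100 * 10), 100, 10)
  batch <- sample(c("a", "b"), 100, replace = TRUE)
  expect_equal(pc_regression_score(v, batch), 1, tolerance = 0.05)
  # duplicated batches of identical data: no batch-aligned variance
  dup <- rbind(v, v)
  expect_equal(pc_regression_score(dup, rep(c("a", "b"), each = 100)), 1,
               tolerance = 0.05)

  # constructed orthogonal design: PC1 = batch indicator exactly
  x <- cbind(c(0, 0, 4, 4), c(1, -1, 1, -1), 0)
  b2 <- c("A", "A", "B", "B")
  # variances 16/3 and 4/3 -> varfractions 0.8 / 0.2, R2 = 1 / 0
  expect_equal(pc_regression_score(x, b2, n_pcs = 2, raw = TRUE), 0.8,
               tolerance = 1e-10)
  expect_equal(pc_regression_score(x, b2, n_pcs = 2), 0.2, tolerance = 1e-10)
  expect_error(pc_regression_score(v, rep("a", 100)), "2 batches")
})

test_that("kbet accepts mirrored compositions and rejects disjoint batches", {
  set.seed(35)
  cloud <- matrix(rnorm(120), 60, 2)
  dup <- rbind(cloud, cloud)
  batch <- rep(c("a", "b"), each = 60)
  g <- knn_graph(dup, 15)
  expect_gt(kbet_score(g, batch), 0.9)
  # alpha = 1: every test rejects by construction
  expect_equal(kbet_score(g, batch, alpha = 1), 0)

  apart <- rbind(cloud, cloud + 100)
  g2 <- knn_graph(apart, 15)
  expect_lt(kbet_score(g2, batch), 0.05)
})

test_that("integration report composites are exact means of their components", {
  spec <- synth_spec(n_cells = 150, n_genes = 60, n_cell_types = 2,
                     n_batches = 2, batch_shift = 0.5,
                     planted_driver_genes = 0, seed = 2)
  sim <- synth_expression(spec)
  emb <- cell_embeddings(sim$expression,
                         synth_feature_embeddings(spec)$table, "wa")
  rep <- integration_report(emb, cell_meta_column(sim$expression, "cell_type"),
                            cell_meta_column(sim$expression, "batch"),
                            seed = 0)
  expect_equal(rep$s_batch,
               mean(c(rep$asw_batch, rep$pcr, rep$gc, rep$kbet, rep$ilisi)),
               tolerance = 1e-12)
  expect_equal(rep$s_bio,
               mean(c(rep$asw_label, rep$nmi, max(rep$ari, 0), rep$clisi)),
               tolerance = 1e-12)
  for (f in c("asw_label", "nmi", "clisi", "asw_batch", "pcr", "gc", "kbet",
              "ilisi", "s_batch", "s_bio")) {
    expect_gte(rep[[f]], 0)
    expect_lte(rep[[f]], 1)
  }
})

test_that("bleu_n implements clipped n-gram precision", {
  expect_equal(bleu_n("the cat sat", "the cat sat"), 1.0)
  expect_equal(bleu_n("aa bb", "cc dd"), 0.0)
  expect_equal(bleu_n("the the the", "the cat", n = 1), 1 / 3)
  expect_equal(bleu_n("the cat", "the cat sat on the mat", n = 2), 1.0)
  expect_equal(bleu_n("x", "x y", n = 2), 0)   # too short: 0 by convention
  expect_equal(bleu_n("The CAT", "the cat"), 1.0)  # lowercased tokens
  expect_error(bleu_n("a", "a", n = 0), ">= 1")
  # bijective token renaming preserves the score
  expect_equal(bleu_n("a b a c", "a b d", n = 1),
               bleu_n("q w q e", "q w r", n = 1))
})

test_that("classification scores match hand-computed macro values", {
  perfect <- classification_scores(c("A", "B"), c("A", "B"))
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1,
                                  f1 = 1))
  # confusion [[2,1],[0,3]]: true A {A,A,B}, true B {B,B,B}
  pred <- c("A", "A", "B", "B", "B", "B")
  true <- c("A", "A", "A", "B", "B", "B")
  s <- classification_scores(pred, true)
  expect_equal(s$accuracy, 5 / 6)
  expect_equal(s$precision, mean(c(2 / 2, 3 / 4)))
  expect_equal(s$recall, mean(c(2 / 3, 3 / 3)))
  f1a <- 2 * (1 * 2 / 3) / (1 + 2 / 3)
  f1b <- 2 * (3 / 4 * 1) / (3 / 4 + 1)
  expect_equal(s$f1, mean(c(f1a, f1b)))

  # constant predictions on a 3-class truth
  true3 <- c("A", "A", "B", "B", "C", "C")
  s3 <- classification_scores(rep("A", 6), true3)
  expect_equal(s3$accuracy, 2 / 6)
  expect_equal(s3$recall, mean(c(1, 0, 0)))
  expect_equal(s3$precision, mean(c(2 / 6, 0, 0)))
  # micro averaging reduces to accuracy for single-label problems
  expect_equal(classification_scores(pred, true, average = "micro")$precision,
               5 / 6)
})

test_that("r2, pcc_genes and mse_genes match loop oracles", {
  y <- c(1, 2, 3, 4); f <- c(1.1, 1.9, 3.2, 3.8)
  expect_equal(r2(y, y), 1.0)
  expect_equal(r2(y, rep(mean(y), 4)), 0.0)
  expect_equal(r2(y, f), 1 - sum((y - f)^2) / sum((y - mean(y))^2),
               tolerance = 1e-12)
  expect_error(r2(rep(2, 4), f), "constant")

  set.seed(36)
  a <- matrix(rnorm(50), 10, 5); b <- matrix(rnorm(50), 10, 5)
  expect_equal(pcc_genes(a, a), 1.0)
  expect_equal(pcc_genes(a, -a), -1.0)
  oracle <- mean(sapply(1:5, function(j) cor(a[, j], b[, j])))
  expect_equal(pcc_genes(a, b), oracle, tolerance = 1e-10)
  b2 <- b; b2[, 3] <- 7
  expect_warning(p <- pcc_genes(a, b2), "zero-variance")
  expect_equal(p, mean(sapply(c(1, 2, 4, 5), function(j) cor(a[, j], b2[, j]))),
               tolerance = 1e-10)

  expect_equal(mse_genes(a, a), 0.0)
  expect_equal(mse_genes(a, a + 3), 9.0, tolerance = 1e-12)
  expect_equal(mse_genes(a, b), mean((a - b)^2), tolerance = 1e-12)
})
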