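# Fine-tuning adaptor: a light feed-forward encoder over cell embeddings
# trained with a joint loss
#     L_total = L_classifier + lambda * L_contrastive
# where L_classifier is softmax cross-entropy on the class labels and
# L_contrastive is a supervised contrastive loss (normalized-temperature
# cross-entropy over same-class positives within each mini-batch) on the
# L2-normalized last hidden representation. Training is plain mini-batch Adam
# with manual backpropagation; everything is seeded, so runs are bit-for-bit
# reproducible.

#' Adaptor configuration
#'
#' @param input_dim embedding dimension t of the input cells.
#' @param hidden_dims hidden layer sizes; the last entry is the latent
#'   dimension used downstream. Default `c(256, 64)`.
#' @param lambda_contrastive weight of the contrastive term (default 100,
#'   favouring label-aware clustering of the latent space).
#' @param temperature softmax temperature of the contrastive loss (default
#'   0.1).
#' @param epochs training epochs (default 100).
#' @param batch_size mini-batch size (default 128).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed integer seed controlling initialization and batch order.
#' @param validation_split fraction held out (stratified) for best-epoch
#'   selection by validation classifier loss; 0 disables selection and the
#'   final epoch is kept. Default 0.1.
#' @export
adaptor_config <- function(input_dim, hidden_dims = c(256L, 64L),
                           lambda_contrastive = 100, temperature = 0.1,
                           epochs = 100L, batch_size = 128L,
                           learning_rate = 1e-3, seed = 0L,
                           validation_split = 0.1) {
  assert_that(length(hidden_dims) >= 1, "hidden_dims must be nonempty")
  assert_that(lambda_contrastive >= 0, "lambda_contrastive must be >= 0")
  assert_that(temperature > 0, "temperature must be positive")
  assert_that(validation_split >= 0 && validation_split < 1,
              "validation_split must be in [0, 1)")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 lambda_contrastive = lambda_contrastive,
                 temperature = temperature,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 seed = as.integer(seed),
                 validation_split = validation_split),
            class = "AdaptorConfig")
}

init_params <- function(cfg, n_classes) {
  dims <- c(cfg$input_dim, cfg$hidden_dims, n_classes)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- dims[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * dims[l + 1], sd = sqrt(2 / fan_in)),
                 fan_in, dims[l + 1]),
      b = numeric(dims[l + 1]))
  }
  layers
}

# forward pass; returns per-layer post-activations (ReLU on hidden layers,
# identity on the classifier head)
forward_pass <- function(layers, x) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1]] <- x
  n_hidden <- length(layers) - 1L
  for (l in seq_along(layers)) {
    z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    acts[[l + 1]] <- if (l <= n_hidden) pmax(z, 0) else z
  }
  acts
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

cross_entropy <- function(probs, y_idx) {
  -mean(log(pmax(probs[cbind(seq_along(y_idx), y_idx)], 1e-300)))
}

# Supervised contrastive loss on latent h and its gradient wrt h.
# For each anchor i with positive set P(i) (same class, != i):
#   L_i = -(1/|P(i)|) sum_{p in P(i)} log( exp(s_ip) / sum_{a != i} exp(s_ia) )
# with s_ij = <u_i, u_j> / tau on the normalized latent u; the loss is the
# mean over anchors with at least one positive.
supcon_loss_grad <- function(h, y_idx, tau, want_grad = TRUE) {
  n <- nrow(h)
  norms <- pmax(sqrt(rowSums(h^2)), 1e-12)
  u <- h / norms
  s <- tcrossprod(u) / tau
  same <- outer(y_idx, y_idx, "==")
  diag(same) <- FALSE
  n_pos <- rowSums(same)
  valid <- which(n_pos > 0)
  if (length(valid) == 0L) {
    return(list(loss = 0, grad = if (want_grad) matrix(0, n, ncol(h))))
  }
  # row-wise log-sum-exp over a != i
  s_off <- s
  diag(s_off) <- -Inf
  m <- apply(s_off, 1, max)
  lse <- m + log(rowSums(exp(s_off - m)))
  loss <- 0
  g <- matrix(0, n, n)  # dL/ds
  for (i in valid) {
    pos <- which(same[i, ])
    loss <- loss - sum(s[i, pos] - lse[i]) / n_pos[i]
    if (want_grad) {
      p_row <- exp(s_off[i, ] - lse[i])  # softmax over a != i
      g[i, ] <- g[i, ] + p_row
      g[i, pos] <- g[i, pos] - 1 / n_pos[i]
    }
  }
  loss <- loss / length(valid)
  if (!want_grad) return(list(loss = loss, grad = NULL))
  g <- g / length(valid)
  du <- (g + t(g)) %*% u / tau
  # back through row normalization u = h / ||h||
  dh <- (du - u * rowSums(du * u)) / norms
  list(loss = loss, grad = dh)
}

adam_step <- function(param, grad, state, lr, step,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^step)
  vhat <- state$v / (1 - beta2^step)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Train the fine-tuning adaptor
#'
#' @param emb CellEmbeddingMatrix of training cells.
#' @param labels per-cell class labels (>= 2 classes, each with >= 2 cells).
#' @param cfg [adaptor_config()]; default configuration if omitted.
#' @return object of class `TrainedAdaptor`: encoder + head parameters,
#'   `classes`, per-epoch `loss_trace` (data.frame with columns `epoch`,
#'   `total`, `classifier`, `contrastive`), the config, and `best_epoch`.
#' @export
train_adaptor <- function(emb, labels, cfg = NULL) {
  x <- if (inherits(emb, "CellEmbeddingMatrix")) emb$vectors else as.matrix(emb)
  labels <- as.character(labels)
  assert_that(length(labels) == nrow(x), "one label per cell required")
  if (is.null(cfg)) cfg <- adaptor_config(ncol(x))
  assert_that(cfg$input_dim == ncol(x), "input_dim (", cfg$input_dim,
              ") != embedding dim (", ncol(x), ")")
  classes <- sort(unique(labels))
  assert_that(length(classes) >= 2, "need >= 2 classes")
  counts <- table(labels)
  small <- names(counts)[counts < 2]
  assert_that(length(small) == 0L,
              "classes with a single cell (no contrastive positives): ",
              paste(small, collapse = ", "))
  y_idx <- match(labels, classes)

  with_seed(cfg$seed, {
    n <- nrow(x)
    # stratified train/validation split for best-epoch selection
    val_idx <- integer(0)
    if (cfg$validation_split > 0) {
      for (cl in classes) {
        members <- which(labels == cl)
        n_val <- floor(length(members) * cfg$validation_split)
        if (n_val >= 1 && length(members) - n_val >= 2) {
          val_idx <- c(val_idx, sample(members, n_val))
        }
      }
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    layers <- init_params(cfg, length(classes))
    states <- lapply(layers, function(l) list(
      W = list(m = l$W * 0, v = l$W * 0),
      b = list(m = l$b * 0, v = l$b * 0)))
    step <- 0L
    n_hidden <- length(layers) - 1L
    trace <- data.frame(epoch = seq_len(cfg$epochs), total = NA_real_,
                        classifier = NA_real_, contrastive = NA_real_,
                        val_classifier = NA_real_)
    best <- list(epoch = NA_integer_, val = Inf, layers = NULL)

    for (ep in seq_len(cfg$epochs)) {
      perm <- sample(tr_idx)
      starts <- seq(1, length(perm), by = cfg$batch_size)
      ep_clf <- ep_con <- 0
      for (s0 in starts) {
        bidx <- perm[s0:min(s0 + cfg$batch_size - 1L, length(perm))]
        xb <- x[bidx, , drop = FALSE]
        yb <- y_idx[bidx]
        acts <- forward_pass(layers, xb)
        latent <- acts[[length(acts) - 1L]]
        probs <- softmax_rows(acts[[length(acts)]])
        l_clf <- cross_entropy(probs, yb)
        con <- supcon_loss_grad(latent, yb, cfg$temperature)
        ep_clf <- ep_clf + l_clf * length(bidx)
        ep_con <- ep_con + con$loss * length(bidx)
        # backprop
        nb <- length(bidx)
        dlogits <- probs
        dlogits[cbind(seq_len(nb), yb)] <- dlogits[cbind(seq_len(nb), yb)] - 1
        dlogits <- dlogits / nb
        grads <- vector("list", length(layers))
        head_l <- length(layers)
        grads[[head_l]] <- list(W = crossprod(latent, dlogits),
                                b = colSums(dlogits))
        dh <- tcrossprod(dlogits, layers[[head_l]]$W) +
          cfg$lambda_contrastive * con$grad
        for (l in rev(seq_len(n_hidden))) {
          dz <- dh * (acts[[l + 1L]] > 0)
          grads[[l]] <- list(W = crossprod(acts[[l]], dz), b = colSums(dz))
          if (l > 1L) dh <- tcrossprod(dz, layers[[l]]$W)
        }
        step <- step + 1L
        for (l in seq_along(layers)) {
          if (!all(is.finite(grads[[l]]$W))) {
            stop("NaN/Inf gradient at epoch ", ep, ", layer ", l,
                 "; try a lower learning_rate or temperature")
          }
          upd <- adam_step(layers[[l]]$W, grads[[l]]$W, states[[l]]$W,
                           cfg$learning_rate, step)
          layers[[l]]$W <- upd$param; states[[l]]$W <- upd$state
          upd <- adam_step(layers[[l]]$b, grads[[l]]$b, states[[l]]$b,
                           cfg$learning_rate, step)
          layers[[l]]$b <- upd$param; states[[l]]$b <- upd$state
        }
      }
      ep_clf <- ep_clf / length(tr_idx)
      ep_con <- ep_con / length(tr_idx)
      trace$classifier[ep] <- ep_clf
      trace$contrastive[ep] <- ep_con
      trace$total[ep] <- ep_clf + cfg$lambda_contrastive * ep_con
      if (length(val_idx)) {
        acts <- forward_pass(layers, x[val_idx, , drop = FALSE])
        val_l <- cross_entropy(softmax_rows(acts[[length(acts)]]),
                               y_idx[val_idx])
        trace$val_classifier[ep] <- val_l
        if (val_l < best$val) best <- list(epoch = ep, val = val_l,
                                           layers = layers)
      }
    }
    if (!is.null(best$layers)) layers <- best$layers else best$epoch <- cfg$epochs
    structure(list(layers = layers, classes = classes, loss_trace = trace,
                   config = cfg, best_epoch = best$epoch),
              class = "TrainedAdaptor")
  })
}

#' @export
print.TrainedAdaptor <- function(x, ...) {
  cat(sprintf(
    "TrainedAdaptor: %d -> %s -> %d classes; %d epochs (best %d), lambda %g\n",
    x$config$input_dim, paste(x$config$hidden_dims, collapse = "-"),
    length(x$classes), x$config$epochs, x$best_epoch,
    x$config$lambda_contrastive))
  invisible(x)
}

#' Encode cells through a trained adaptor
#'
#' Deterministic forward pass up to the last hidden (pre-classifier) layer.
#'
#' @param model TrainedAdaptor.
#' @param emb CellEmbeddingMatrix with the model's input dimension.
#' @return CellEmbeddingMatrix of latent vectors (dim = last hidden size).
#' @export
adaptor_embed <- function(model, emb) {
  assert_that(inherits(model, "TrainedAdaptor"), "model must be a TrainedAdaptor")
  x <- if (inherits(emb, "CellEmbeddingMatrix")) emb$vectors else as.matrix(emb)
  assert_that(ncol(x) == model$config$input_dim,
              "input dim (", ncol(x), ") != model input_dim (",
              model$config$input_dim, ")")
  acts <- forward_pass(model$layers, x)
  ids <- if (inherits(emb, "CellEmbeddingMatrix")) emb$cell_ids
         else paste0("cell", seq_len(nrow(x)))
  cell_embedding_matrix(ids, acts[[length(acts) - 1L]])
}

#' Predict class probabilities with the classifier head
#'
#' @param model TrainedAdaptor.
#' @param emb CellEmbeddingMatrix.
#' @return matrix of class probabilities (columns named by class).
#' @export
adaptor_predict <- function(model, emb) {
  x <- if (inherits(emb, "CellEmbeddingMatrix")) emb$vectors else as.matrix(emb)
  acts <- forward_pass(model$layers, x)
  p <- softmax_rows(acts[[length(acts)]])
  colnames(p) <- model$classes
  p
}

#' Fine-tuned kNN annotation
#'
#' Encodes training and test cells through the adaptor latent space, then
#' annotates by [knn_annotate()].
#'
#' @inheritParams knn_annotate
#' @param model TrainedAdaptor.
#' @export
annotate_finetuned <- function(model, train, train_labels, test, k = 10,
                               metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  knn_annotate(adaptor_embed(model, train), train_labels,
               adaptor_embed(model, test), k = k, metric = metric)
}

#' Save / load a trained adaptor
#'
#' Portable JSON container: flat weight arrays plus the config manifest.
#'
#' @param model TrainedAdaptor.
#' @param path file path (JSON).
#' @export
save_adaptor <- function(model, path) {
  payload <- list(
    classes = model$classes,
    best_epoch = model$best_epoch,
    config = unclass(model$config),
    loss_trace = model$loss_trace,
    layers = lapply(model$layers, function(l) {
      list(W = as.vector(l$W), dim = dim(l$W), b = l$b)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_adaptor
#' @export
load_adaptor <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(adaptor_config, p$config[names(p$config) %in%
    names(formals(adaptor_config))])
  layers <- lapply(seq_len(nrow(p$layers) %||% length(p$layers$W)), function(i) {
    list(W = matrix(p$layers$W[[i]], p$layers$dim[[i]][1], p$layers$dim[[i]][2]),
         b = as.numeric(p$layers$b[[i]]))
  })
  structure(list(layers = layers, classes = p$classes,
                 loss_trace = as.data.frame(p$loss_trace), config = cfg,
                 best_epoch = p$best_epoch),
            class = "TrainedAdaptor")
}
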