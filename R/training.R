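# The training recipe: stratified splits, Adam with L2 and global
# gradient-norm clipping, early stopping on development-set F1, and the
# k-fold cross-validation harness.

#' Training configuration
#'
#' Optimization and stopping settings. The published recipe fixes the
#' gradient-norm clip at 5 and the early-stopping patience at 6 epochs on
#' development F1; learning rate, batch size, L2 coefficient and epoch cap
#' are configurable (defaults 1e-3, 32, 1e-5, 50).
#'
#' @param learning_rate Adam step size.
#' @param l2_lambda coefficient of the squared-parameter-norm penalty
#'   added to the mean cross-entropy objective (embeddings excluded).
#' @param clip_norm global gradient-norm clip (default 5; `Inf` disables).
#' @param patience early-stopping patience in epochs (default 6).
#' @param max_epochs epoch cap.
#' @param batch_size documents per optimization step.
#' @param seed seed covering parameter shuffling, noise and dropout draws.
#' @param split_fractions corpus split fractions, e.g. `c(0.8, 0.1, 0.1)`
#'   for train/dev/eval or `c(0.95, 0.05)` for the final train/dev split.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3,
                         l2_lambda = 1e-5,
                         clip_norm = 5,
                         patience = 6L,
                         max_epochs = 50L,
                         batch_size = 32L,
                         seed = 1L,
                         split_fractions = c(0.8, 0.1, 0.1)) {
  assert_scalar_number(learning_rate, "learning_rate", 0, Inf)
  assert_scalar_number(l2_lambda, "l2_lambda", 0, Inf)
  if (!(is.numeric(clip_norm) && length(clip_norm) == 1L && clip_norm > 0)) {
    validation_error("clip_norm must be a positive number (possibly Inf)")
  }
  patience <- as.integer(patience)
  if (is.na(patience) || patience < 1L) validation_error("patience must be >= 1")
  if (any(split_fractions <= 0) || abs(sum(split_fractions) - 1) > 1e-8) {
    validation_error("split fractions must be positive and sum to 1")
  }
  structure(
    list(learning_rate = learning_rate, l2_lambda = l2_lambda,
         clip_norm = clip_norm, patience = patience,
         max_epochs = as.integer(max_epochs),
         batch_size = as.integer(batch_size), seed = as.integer(seed),
         split_fractions = split_fractions),
    class = "train_config"
  )
}

#' Split a labeled corpus into disjoint subsets
#'
#' Seeded, reproducible partition into `length(fractions)` subsets whose
#' sizes are the rounded fraction counts. With `stratify = TRUE`
#' (default) the split is drawn per class, so each subset's class balance
#' matches the corpus within one document per class — important when a 5%
#' development slice must preserve a 42/58 balance.
#'
#' @param labels binary label vector for the corpus (no `NA`).
#' @param fractions positive fractions summing to 1, e.g.
#'   `c(0.8, 0.1, 0.1)`.
#' @param seed integer seed.
#' @param stratify preserve per-class proportions.
#' @return A list of disjoint, exhaustive integer index vectors, one per
#'   fraction.
#' @export
split_corpus <- function(labels, fractions, seed = 1L, stratify = TRUE) {
  labels <- as.integer(labels)
  if (anyNA(labels)) validation_error("corpus must be fully labeled to split")
  n <- length(labels)
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8) {
    validation_error("split fractions must be positive and sum to 1")
  }
  ns <- length(fractions)
  take <- function(idx) {
    sizes <- round(fractions * length(idx))
    sizes[ns] <- length(idx) - sum(sizes[-ns])
    if (any(sizes < 0)) sizes <- pmax(sizes, 0L)
    ends <- cumsum(sizes)
    starts <- c(1L, head(ends, -1L) + 1L)
    lapply(seq_len(ns), function(i) {
      if (sizes[i] == 0L) integer(0) else idx[starts[i]:ends[i]]
    })
  }
  parts <- with_seed(seed, {
    if (stratify) {
      per_class <- lapply(sort(unique(labels)), function(cl) {
        take(sample(which(labels == cl)))
      })
      lapply(seq_len(ns), function(i) {
        sort(unlist(lapply(per_class, `[[`, i)))
      })
    } else {
      take(sample(n))
    }
  })
  if (any(lengths(parts) == 0L)) {
    validation_error("a split received zero documents; use larger fractions or corpus")
  }
  parts
}

# ---- early stopping ---------------------------------------------------

# Stateful monitor: strict improvement (">") resets the patience counter;
# `patience` consecutive non-improving epochs trigger the stop.
make_early_stopper <- function(patience) {
  env <- new.env(parent = emptyenv())
  env$best <- -Inf
  env$best_epoch <- 0L
  env$wait <- 0L
  env$epoch <- 0L
  list(
    update = function(metric) {
      env$epoch <- env$epoch + 1L
      improved <- metric > env$best
      if (improved) {
        env$best <- metric
        env$best_epoch <- env$epoch
        env$wait <- 0L
      } else {
        env$wait <- env$wait + 1L
      }
      list(improved = improved, stop = env$wait >= patience)
    },
    state = function() as.list(env)
  )
}

#' Simulate the early-stopping monitor on a metric sequence
#'
#' Applies the patience rule used during training — stop once the
#' monitored metric has failed to exceed its best value for `patience`
#' consecutive epochs, keep the best epoch's snapshot — to a given F1
#' sequence.
#'
#' @param metrics numeric vector of per-epoch development F1 values.
#' @param patience patience in epochs (default 6).
#' @return List with `best_epoch`, `stopped_epoch` and `best_metric`.
#' @export
early_stop_trace <- function(metrics, patience = 6L) {
  es <- make_early_stopper(patience)
  stopped <- length(metrics)
  for (i in seq_along(metrics)) {
    if (es$update(metrics[[i]])$stop) {
      stopped <- i
      break
    }
  }
  st <- es$state()
  list(best_epoch = st$best_epoch, stopped_epoch = stopped,
       best_metric = st$best)
}

# ---- parameter flattening for the optimizer ---------------------------

seq_leaves <- function(p, prefix) {
  out <- list(p$fwd$W, p$fwd$U_zr, p$fwd$U_c, p$fwd$b,
              p$bwd$W, p$bwd$U_zr, p$bwd$U_c, p$bwd$b,
              p$att$W, p$att$b)
  names(out) <- paste0(prefix, c("fW", "fUzr", "fUc", "fb",
                                 "bW", "bUzr", "bUc", "bb", "aW", "ab"))
  out
}

param_leaves <- function(params) {
  c(list(emb = params$emb),
    seq_leaves(params$sent, "s_"),
    seq_leaves(params$doc, "d_"),
    list(out_w = params$out$w, out_b = params$out$b))
}

grad_seq_leaves <- function(g, prefix) {
  out <- list(g$fwd$dW, g$fwd$dU_zr, g$fwd$dU_c, g$fwd$db,
              g$bwd$dW, g$bwd$dU_zr, g$bwd$dU_c, g$bwd$db,
              g$att$dW, g$att$db)
  names(out) <- paste0(prefix, c("fW", "fUzr", "fUc", "fb",
                                 "bW", "bUzr", "bUc", "bb", "aW", "ab"))
  out
}

grad_leaves <- function(g, params) {
  c(list(emb = if (is.null(g$emb)) params$emb * 0 else g$emb),
    grad_seq_leaves(g$sent, "s_"),
    grad_seq_leaves(g$doc, "d_"),
    list(out_w = g$out$dw, out_b = g$out$db))
}

flatten_leaves <- function(leaves) unlist(leaves, use.names = FALSE)

rebuild_params <- function(params, flat) {
  leaves <- param_leaves(params)
  pos <- 0L
  new <- vector("list", length(leaves))
  for (i in seq_along(leaves)) {
    n <- length(leaves[[i]])
    chunk <- flat[pos + seq_len(n)]
    if (is.matrix(leaves[[i]])) {
      chunk <- matrix(chunk, nrow(leaves[[i]]), ncol(leaves[[i]]))
    }
    new[[i]] <- chunk
    pos <- pos + n
  }
  params$emb <- new[[1L]]
  assign_seq <- function(p, off) {
    p$fwd$W <- new[[off + 1L]]; p$fwd$U_zr <- new[[off + 2L]]
    p$fwd$U_c <- new[[off + 3L]]; p$fwd$b <- new[[off + 4L]]
    p$bwd$W <- new[[off + 5L]]; p$bwd$U_zr <- new[[off + 6L]]
    p$bwd$U_c <- new[[off + 7L]]; p$bwd$b <- new[[off + 8L]]
    p$att$W <- new[[off + 9L]]; p$att$b <- new[[off + 10L]]
    p
  }
  params$sent <- assign_seq(params$sent, 1L)
  params$doc <- assign_seq(params$doc, 11L)
  params$out$w <- new[[22L]]
  params$out$b <- new[[23L]]
  params
}

#' One Adam update on a flat parameter vector
#'
#' Standard adaptive-moment estimation with bias correction; exposed for
#' testing single optimization steps.
#'
#' @param theta flat parameter vector.
#' @param grad flat gradient vector.
#' @param state list with `m`, `v`, `t` (use [adam_state()] to start).
#' @param lr learning rate; `beta1`, `beta2`, `eps` the usual moments.
#' @return List with updated `theta` and `state`.
#' @export
adam_step <- function(theta, grad, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  m_hat <- state$m / (1 - beta1^state$t)
  v_hat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * m_hat / (sqrt(v_hat) + eps)
  list(theta = theta, state = state)
}

#' @rdname adam_step
#' @param n parameter-vector length.
#' @export
adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

# ---- fitting ----------------------------------------------------------

#' Fit a hierarchical BGRU model
#'
#' Minimizes mean binary cross-entropy plus `l2_lambda` times the squared
#' parameter norm (embeddings excluded from the penalty) with Adam. Each
#' update's gradient is globally rescaled to norm at most `clip_norm`.
#' After every epoch the development-set F1 (threshold 0.5) is recorded;
#' training stops when F1 has not exceeded its best value for `patience`
#' consecutive epochs or at `max_epochs`, and the best epoch's parameter
#' snapshot is returned.
#'
#' @param model an initialized (untrained) [hbgru_init()] model.
#' @param train a list with `matrices` (list of `document_matrix`) and
#'   `labels` (binary vector), e.g. a subset of [encode_corpus()] output.
#' @param dev development set in the same form.
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return A list with `model` (best snapshot) and `history` (class
#'   `train_history`: per-epoch data frame with attributes `best_epoch`
#'   and `stopped_epoch`).
#' @export
hbgru_fit <- function(model, train, dev, config = train_config(),
                      verbose = FALSE) {
  stopifnot(inherits(model, "hbgru_model"), inherits(config, "train_config"))
  n <- length(train$matrices)
  if (n == 0L || length(dev$matrices) == 0L) {
    validation_error("train and dev sets must be non-empty")
  }
  y <- as.numeric(train$labels)
  y_dev <- as.integer(dev$labels)
  if (anyNA(y) || anyNA(y_dev)) validation_error("train and dev sets must be labeled")

  flat <- flatten_leaves(param_leaves(model$params))
  opt <- adam_state(length(flat))
  n_emb <- length(model$params$emb)
  l2_mask <- c(numeric(n_emb), rep(1, length(flat) - n_emb))
  es <- make_early_stopper(config$patience)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        dev_precision = numeric(), dev_recall = numeric(),
                        dev_f1 = numeric())
  best_flat <- flat
  stopped <- 0L

  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(n)
      epoch_loss <- 0
      n_batches <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        batch <- ord[start:min(start + config$batch_size - 1L, n)]
        gsum <- numeric(length(flat))
        loss_sum <- 0
        for (i in batch) {
          fw <- hbgru_forward(model, train$matrices[[i]], training = TRUE,
                              keep_cache = TRUE)
          cache <- attr(fw, "cache")
          loss_sum <- loss_sum + bce_loss(fw$p, y[[i]])
          g <- hbgru_backward(model, cache, fw$p - y[[i]])
          gsum <- gsum + flatten_leaves(grad_leaves(g, model$params))
        }
        grad <- gsum / length(batch) + 2 * config$l2_lambda * l2_mask * flat
        loss <- loss_sum / length(batch) +
          config$l2_lambda * sum((l2_mask * flat)^2)
        if (!is.finite(loss)) {
          stop_hbgru("non-finite loss at epoch %d; reduce the learning rate",
                     epoch, class = "hbgru_numeric_error")
        }
        grad <- clip_gradients(grad, config$clip_norm)
        upd <- adam_step(flat, grad, opt, lr = config$learning_rate)
        flat <- upd$theta
        opt <- upd$state
        model$params <- rebuild_params(model$params, flat)
        epoch_loss <- epoch_loss + loss
        n_batches <- n_batches + 1L
      }
      pred <- hbgru_predict(model, dev$matrices, threshold = 0.5)
      met <- precision_recall_f1(y_dev, pred$label)
      history[epoch, ] <- list(epoch, epoch_loss / n_batches,
                               met$precision, met$recall, met$f1)
      if (verbose) {
        message(sprintf("epoch %2d  loss %.4f  dev F1 %.4f",
                        epoch, epoch_loss / n_batches, met$f1))
      }
      st <- es$update(met$f1)
      if (st$improved) best_flat <- flat
      stopped <- epoch
      if (st$stop) break
    }
  })
  model$params <- rebuild_params(model$params, best_flat)
  state <- es$state()
  attr(history, "best_epoch") <- state$best_epoch
  attr(history, "stopped_epoch") <- stopped
  attr(history, "best_f1") <- state$best
  class(history) <- c("train_history", class(history))
  list(model = model, history = history)
}

#' Stratified k-fold cross-validation
#'
#' Splits the labeled corpus into `k` stratified folds; each fold is held
#' out once while a fresh model is trained on the remaining documents (a
#' slice of which, sized by the dev fraction of
#' `train_config$split_fractions[2]`, serves as the early-stopping
#' development set). Reports per-fold precision/recall/F1 on the held-out
#' fold and the mean F1, the protocol behind per-fold score tables.
#'
#' @param dataset a list with `matrices` and `labels`.
#' @param k number of folds (default 5).
#' @param config a [model_config()].
#' @param embedding an `hbgru_embedding` used to initialize each fold's
#'   model.
#' @param tc a [train_config()].
#' @param seed seed for the fold assignment and per-fold training.
#' @return List with `folds` (list of `hbgru_metrics`), `f1` (per-fold
#'   vector), `mean_f1` and `fold_id` (the fold assignment).
#' @export
kfold_cv <- function(dataset, k = 5L, config = model_config(), embedding,
                     tc = train_config(), seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) validation_error("k must be >= 2")
  labels <- as.integer(dataset$labels)
  if (anyNA(labels)) validation_error("corpus must be labeled for cross-validation")
  n <- length(labels)
  fold_id <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      # continue the round-robin across classes so fold totals balance
      fold_id[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold_id == f)
    rest <- which(fold_id != f)
    if (length(unique(labels[test_idx])) < 2L ||
        length(unique(labels[rest])) < 2L) {
      validation_error("fold %d contains a single class; use fewer folds", f)
    }
    dev_frac <- if (length(tc$split_fractions) >= 2L) {
      tc$split_fractions[[2L]]
    } else {
      0.1
    }
    parts <- split_corpus(labels[rest], c(1 - dev_frac, dev_frac),
                          seed = seed + f)
    tr_idx <- rest[parts[[1L]]]
    dv_idx <- rest[parts[[2L]]]
    fold_tc <- tc
    fold_tc$seed <- tc$seed + f
    model <- hbgru_init(config, embedding, seed = seed + f)
    fit <- hbgru_fit(model,
                     list(matrices = dataset$matrices[tr_idx],
                          labels = labels[tr_idx]),
                     list(matrices = dataset$matrices[dv_idx],
                          labels = labels[dv_idx]),
                     fold_tc)
    pred <- hbgru_predict(fit$model, dataset$matrices[test_idx])
    fold_metrics[[f]] <- precision_recall_f1(labels[test_idx], pred$label)
  }
  f1s <- vapply(fold_metrics, `[[`, numeric(1), "f1")
  list(folds = fold_metrics, f1 = f1s, mean_f1 = mean(f1s),
       fold_id = fold_id)
}
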