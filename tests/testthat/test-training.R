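test_that("corpus splits have the rounded sizes and are reproducible", {
  labels <- rep(c(1L, 0L), c(42, 58))
  p <- split_corpus(labels, c(0.8, 0.1, 0.1), seed = 4)
  expect_equal(lengths(p), c(80L, 10L, 10L))
  expect_equal(sort(unlist(p)), 1:100)

  p95 <- split_corpus(labels, c(0.95, 0.05), seed = 4)
  expect_equal(lengths(p95), c(95L, 5L))

  expect_identical(split_corpus(labels, c(0.8, 0.1, 0.1), seed = 4), p)
  expect_false(identical(split_corpus(labels, c(0.8, 0.1, 0.1), seed = 5), p))

  # stratification keeps the class balance within one document per class
  for (part in p) {
    expect_equal(sum(labels[part] == 1), round(0.42 * length(part)),
                 tolerance = 0, ignore_attr = TRUE)
  }
  expect_error(split_corpus(labels, c(0.99, 0.005, 0.005), seed = 1),
               class = "hbgru_validation_error")
  expect_error(split_corpus(labels, c(0.5, 0.4), seed = 1),
               class = "hbgru_validation_error")
})

test_that("the patience counter stops a scripted F1 sequence where expected", {
  trace <- early_stop_trace(c(0.5, 0.6, 0.6, 0.6, 0.6, 0.6, 0.6, 0.6),
                            patience = 6)
  expect_equal(trace$best_epoch, 2)
  expect_equal(trace$stopped_epoch, 8)
  expect_equal(trace$best_metric, 0.6)

  # strictly improving sequence never triggers the stop
  rising <- early_stop_trace(seq(0.1, 0.9, by = 0.1), patience = 6)
  expect_equal(rising$best_epoch, 9)
  expect_equal(rising$stopped_epoch, 9)

  # ties are not improvements
  flat <- early_stop_trace(c(0.7, 0.7, 0.7), patience = 2)
  expect_equal(flat$best_epoch, 1)
  expect_equal(flat$stopped_epoch, 3)
})

test_that("gradient clipping rescales the global norm", {
  g <- list(a = c(3, 4), b = matrix(c(5, 0, 0, sqrt(50)), 2))  # norm 10
  nrm <- gradient_global_norm(g)
  clipped <- clip_gradients(g, 5)
  expect_equal(gradient_global_norm(clipped), 5, tolerance = 1e-12)
  # direction is preserved
  expect_equal(clipped$a / 5, g$a / nrm, tolerance = 1e-12)

  small <- list(a = c(0.3, 0.4))
  expect_identical(clip_gradients(small, 5), small)
  expect_identical(clip_gradients(g, Inf), g)

  # a flat gradient vector of norm 10 clips to norm 5
  flat <- c(rep(10 / sqrt(2), 2))
  expect_equal(sqrt(sum(clip_gradients(flat, 5)^2)), 5, tolerance = 1e-12)
})

test_that("one Adam step matches the hand-derived update on 1-d logistic", {
  # model: p = sigmoid(w * x), BCE loss, single example x = 2, y = 1
  w <- 0.5; x <- 2; y <- 1
  p <- 1 / (1 + exp(-w * x))
  grad <- (p - y) * x
  st <- adam_state(1)
  upd <- adam_step(w, grad, st, lr = 1e-3)
  # by hand: t=1, m_hat = grad, v_hat = grad^2, step = lr*grad/(|grad|+eps)
  expect_equal(upd$theta, w - 1e-3 * grad / (abs(grad) + 1e-8),
               tolerance = 1e-6)
  expect_equal(upd$state$t, 1L)
})

test_that("batch loss uses mean reduction: duplicates change nothing", {
  fx <- tiny_encoded_corpus(n = 4, seed = 67)
  model <- tiny_model(fx$enc)
  mat <- fx$enc$matrices[[1]]
  fw <- hbgru_forward(model, mat, keep_cache = TRUE)
  g1 <- hbgru:::hbgru_backward(model, attr(fw, "cache"), fw$p - 1)
  flat1 <- hbgru:::flatten_leaves(hbgru:::grad_leaves(g1, model$params))
  # mean gradient over the same document twice equals the single gradient
  flat2 <- (flat1 + flat1) / 2
  expect_equal(flat2, flat1)
  loss1 <- hbgru:::bce_loss(fw$p, 1)
  expect_equal(mean(c(loss1, loss1)), loss1)
})

test_that("fitting reduces the loss and obeys the early-stopping bound", {
  fx <- tiny_encoded_corpus(n = 60, seed = 71)
  model <- tiny_model(fx$enc, E = 8, S = 4, D = 4)
  parts <- split_corpus(fx$enc$labels, c(0.8, 0.2), seed = 2)
  ds <- function(ix) list(matrices = fx$enc$matrices[ix],
                          labels = fx$enc$labels[ix])
  tc <- train_config(max_epochs = 6, seed = 5, learning_rate = 0.01,
                     patience = 3)
  fit <- hbgru_fit(model, ds(parts[[1]]), ds(parts[[2]]), tc)
  h <- fit$history
  expect_lt(h$loss[nrow(h)], h$loss[1])
  expect_true(all(c("loss", "dev_precision", "dev_recall", "dev_f1")
                  %in% names(h)))
  best <- attr(h, "best_epoch")
  stopped <- attr(h, "stopped_epoch")
  expect_lte(stopped - best, tc$patience)
  expect_equal(max(h$dev_f1), attr(h, "best_f1"))
  # returned model is the best snapshot: its dev F1 equals the recorded best
  pred <- hbgru_predict(fit$model, ds(parts[[2]])$matrices)
  m <- precision_recall_f1(ds(parts[[2]])$labels, pred$label)
  expect_equal(m$f1, attr(h, "best_f1"))
})

test_that("training is reproducible under the same seed", {
  fx <- tiny_encoded_corpus(n = 30, seed = 73)
  parts <- split_corpus(fx$enc$labels, c(0.8, 0.2), seed = 2)
  ds <- function(ix) list(matrices = fx$enc$matrices[ix],
                          labels = fx$enc$labels[ix])
  tc <- train_config(max_epochs = 2, seed = 9)
  run <- function() {
    model <- tiny_model(fx$enc, E = 6, S = 3, D = 3, regularized = TRUE)
    hbgru_fit(model, ds(parts[[1]]), ds(parts[[2]]), tc)
  }
  f1 <- run()
  f2 <- run()
  expect_identical(f1$model$params, f2$model$params)
  expect_equal(f1$history$loss, f2$history$loss)
})

test_that("cross-validation partitions every document into exactly one fold", {
  fx <- tiny_encoded_corpus(n = 100, seed = 79)
  emb <- init_embedding_matrix(fx$enc$vocab, dim = 6, seed = 1)
  mcfg <- model_config(embedding_dim = 6, sentence_size = 2, document_size = 2,
                       dropout_embedding = 0, dropout_gru = 0,
                       dropout_attention = 0, noise_sigma = 0)
  tc <- train_config(max_epochs = 1, batch_size = 64, seed = 3)
  cv <- kfold_cv(list(matrices = fx$enc$matrices, labels = fx$enc$labels),
                 k = 5, config = mcfg, embedding = emb, tc = tc, seed = 8)
  expect_equal(unname(table(cv$fold_id)), rep(20L, 5), ignore_attr = TRUE)
  expect_equal(length(cv$f1), 5)
  expect_equal(cv$mean_f1, mean(cv$f1))
  # stratified: per-fold positive counts stay within one of the target
  pos_per_fold <- tapply(fx$enc$labels, cv$fold_id, sum)
  expect_true(all(abs(pos_per_fold - sum(fx$enc$labels) / 5) <= 1))
  # same seed reproduces the same fold assignment
  cv2 <- kfold_cv(list(matrices = fx$enc$matrices, labels = fx$enc$labels),
                  k = 5, config = mcfg, embedding = emb, tc = tc, seed = 8)
  expect_identical(cv2$fold_id, cv$fold_id)
  expect_equal(cv2$f1, cv$f1)
  expect_error(kfold_cv(list(matrices = fx$enc$matrices,
                             labels = fx$enc$labels),
                        k = 1, config = mcfg, embedding = emb, tc = tc),
               class = "hbgru_validation_error")
})
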