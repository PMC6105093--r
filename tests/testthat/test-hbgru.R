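test_that("attention pooling handles singleton and uniform cases", {
  params <- list(W = c(0.3, -0.2), b = 0.1)
  h1 <- matrix(c(1.5, -0.7), nrow = 1)
  res <- attention_pool(h1, params)
  expect_equal(res$alpha, 1)
  expect_equal(res$v, as.numeric(h1))

  H <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE)
  res0 <- attention_pool(H, list(W = c(0, 0), b = 0))
  expect_equal(res0$alpha, rep(1 / 3, 3))
  expect_equal(res0$v, colMeans(H))

  expect_error(attention_pool(H, params, mask = c(FALSE, FALSE, FALSE)),
               class = "hbgru_validation_error")
})

test_that("masked attention matches the brute-force oracle", {
  W <- c(0.4, -0.3)
  b <- 0.05
  H <- matrix(c(0.2, -0.1, 0.5, 0.3, 9, 9), nrow = 3, byrow = TRUE)
  mask <- c(TRUE, TRUE, FALSE)
  res <- attention_pool(H, list(W = W, b = b), mask)
  ref <- oracle_attention(H, W, b, mask)
  expect_equal(res$v, ref$v, tolerance = 1e-12)
  expect_equal(res$alpha, ref$alpha, tolerance = 1e-12)
  expect_equal(res$alpha[3], 0)
  expect_equal(sum(res$alpha), 1, tolerance = 1e-6)
})

test_that("attention weights over valid positions always sum to one", {
  set.seed(99)
  for (rep in 1:200) {
    T_ <- sample(2:8, 1)
    h2 <- 2 * sample(1:4, 1)
    H <- matrix(rnorm(T_ * h2), T_, h2)
    mask <- c(TRUE, runif(T_ - 1) < 0.7)
    res <- attention_pool(H, list(W = rnorm(h2), b = rnorm(1)), mask)
    expect_equal(sum(res$alpha), 1, tolerance = 1e-6)
    expect_true(all(res$alpha[!mask] == 0))
    expect_true(all(res$alpha >= 0))
  }
})

test_that("the sequence encoder equals a step-by-step scalar recurrence oracle", {
  set.seed(5)
  for (rep in 1:8) {
    E <- sample(2:4, 1)
    S <- sample(2:4, 1)
    T_ <- sample(1:5, 1)
    params <- seq_encoder_init(E, S)
    X <- matrix(rnorm(T_ * E), T_, E)
    mask <- if (T_ == 1) TRUE else c(TRUE, runif(T_ - 1) < 0.7)
    enc <- encode_sequence(X, mask, params)
    ref <- oracle_encode_sequence(X, mask, params)
    expect_equal(enc$v, ref$v, tolerance = 1e-5)
    expect_equal(enc$alpha, ref$alpha, tolerance = 1e-5)
    # annotations agree at valid positions
    expect_equal(enc$annotations[mask, ], ref$annotations[mask, , drop = FALSE],
                 tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("annotations and pooled vectors have length twice the GRU size", {
  params <- seq_encoder_init(10, 150)
  X <- matrix(rnorm(3 * 10), 3, 10)
  enc <- encode_sequence(X, params = params)
  expect_equal(length(enc$v), 300)
  expect_equal(ncol(enc$annotations), 300)
})

test_that("padding appended after the valid content changes nothing", {
  set.seed(12)
  params <- seq_encoder_init(3, 4)
  X <- matrix(rnorm(4 * 3), 4, 3)
  base <- encode_sequence(X, rep(TRUE, 4), params)
  padded <- encode_sequence(rbind(X, matrix(0, 3, 3)),
                            c(rep(TRUE, 4), rep(FALSE, 3)), params)
  expect_equal(padded$v, base$v, tolerance = 1e-12)
  expect_equal(padded$alpha[1:4], base$alpha, tolerance = 1e-12)
})

test_that("the document vector concatenates title and abstract halves", {
  fx <- tiny_encoded_corpus(n = 6, seed = 41)
  model <- tiny_model(fx$enc, E = 8, S = 3, D = 4)
  rep1 <- hbgru_forward(model, fx$enc$matrices[[1]])
  expect_equal(length(rep1$d), 2 * 3 + 2 * 4)
  expect_equal(rep1$d[1:6], rep1$t)
  expect_equal(rep1$d[7:14], rep1$a)
  expect_true(rep1$p > 0 && rep1$p < 1)
  expect_equal(sum(rep1$word_alpha[1, ]), 1, tolerance = 1e-6)
})

test_that("inference is deterministic; training mode injects noise", {
  fx <- tiny_encoded_corpus(n = 4, seed = 43)
  model <- tiny_model(fx$enc, regularized = TRUE)
  mat <- fx$enc$matrices[[1]]
  p1 <- hbgru_forward(model, mat)$p
  p2 <- hbgru_forward(model, mat)$p
  expect_identical(p1, p2)
  set.seed(1); q1 <- hbgru_forward(model, mat, training = TRUE)$p
  set.seed(2); q2 <- hbgru_forward(model, mat, training = TRUE)$p
  expect_false(identical(q1, q2))
})

test_that("the title shortcut bypasses the document encoder", {
  fx <- tiny_encoded_corpus(n = 6, seed = 47)
  model <- tiny_model(fx$enc)
  mat <- fx$enc$matrices[[1]]
  base <- hbgru_forward(model, mat)
  K <- sum(mat$sentence_mask)
  expect_gt(K, 2)

  # perturbing an abstract sentence leaves the t half of d unchanged
  pert <- mat
  pert$values[2, mat$word_mask[2, ]] <-
    rev(pert$values[2, mat$word_mask[2, ]])
  pert$values[2, 1] <- token_index(model$vocab, "<unk>")
  rep_p <- hbgru_forward(model, pert)
  expect_identical(rep_p$t, base$t)

  # perturbing the title leaves the a half unchanged (t never enters the
  # document encoder)
  tpert <- mat
  tpert$values[1, 1] <- token_index(model$vocab, "<unk>")
  rep_t <- hbgru_forward(model, tpert)
  expect_identical(rep_t$a, base$a)
  expect_false(identical(rep_t$t, base$t))

  # swapping two abstract rows changes a but never t
  swap <- mat
  swap$values[2:3, ] <- mat$values[3:2, ]
  swap$word_mask[2:3, ] <- mat$word_mask[3:2, ]
  rep_s <- hbgru_forward(model, swap)
  expect_identical(rep_s$t, base$t)
  expect_false(identical(rep_s$a, base$a))
})

test_that("a title-only document yields a zero abstract vector", {
  fx <- tiny_encoded_corpus(n = 4, seed = 53)
  model <- tiny_model(fx$enc)
  tok <- structure(list(sentences = list(c("kinase", "binds"))),
                   doc_id = "solo", label = NA_integer_,
                   class = "tokenized_document")
  mat <- encode_document(tok, model$vocab, fx$cfg)
  rep_ <- hbgru_forward(model, mat)
  expect_equal(rep_$a, numeric(2 * model$config$document_size))
  expect_equal(rep_$d, c(rep_$t, numeric(2 * model$config$document_size)))
})

test_that("prediction thresholds probabilities with ties going positive", {
  fx <- tiny_encoded_corpus(n = 8, seed = 59)
  model <- tiny_model(fx$enc)
  preds <- hbgru_predict(model, fx$enc$matrices, threshold = 0.5)
  expect_equal(nrow(preds), 8)
  expect_equal(preds$label, as.integer(preds$probability >= 0.5))
  # a threshold at an observed probability classifies that document positive
  thr <- preds$probability[3]
  at_tie <- hbgru_predict(model, fx$enc$matrices, threshold = thr)
  expect_equal(at_tie$label[3], 1L)
  expect_equal(at_tie$label, as.integer(at_tie$probability >= thr))
  expect_error(hbgru_predict(model, fx$enc$matrices, threshold = 0),
               class = "hbgru_validation_error")
})

test_that("model checkpoints round-trip", {
  fx <- tiny_encoded_corpus(n = 4, seed = 61)
  model <- tiny_model(fx$enc)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(back$params, model$params)
  p1 <- hbgru_forward(model, fx$enc$matrices[[1]])$p
  p2 <- hbgru_forward(back, fx$enc$matrices[[1]])$p
  expect_identical(p1, p2)
})
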