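# Independent reference implementations used as oracles. These are
# deliberately written as naive scalar loops, sharing no code with the
# package's vectorized forward pass.

# Scalar-loop GRU over one sequence. X: T x E matrix, mask: length-T
# logical, blk: parameter block with W (E x 3H), U_zr (H x 2H),
# U_c (H x H), b (3H). Masked steps carry the state through.
oracle_gru_direction <- function(X, mask, blk, reverse = FALSE) {
  H <- ncol(blk$U_c)
  E <- nrow(blk$W)
  T_ <- nrow(X)
  Wz <- blk$W[, 1:H, drop = FALSE]
  Wr <- blk$W[, H + 1:H, drop = FALSE]
  Wc <- blk$W[, 2 * H + 1:H, drop = FALSE]
  Uz <- blk$U_zr[, 1:H, drop = FALSE]
  Ur <- blk$U_zr[, H + 1:H, drop = FALSE]
  Uc <- blk$U_c
  bz <- blk$b[1:H]
  br <- blk$b[H + 1:H]
  bc <- blk$b[2 * H + 1:H]
  h <- numeric(H)
  states <- matrix(0, T_, H)
  steps <- if (reverse) T_:1 else 1:T_
  for (t in steps) {
    if (mask[[t]]) {
      z <- numeric(H); r <- numeric(H); cc <- numeric(H)
      for (k in 1:H) {
        az <- bz[k]; ar <- br[k]
        for (e in 1:E) {
          az <- az + X[t, e] * Wz[e, k]
          ar <- ar + X[t, e] * Wr[e, k]
        }
        for (j in 1:H) {
          az <- az + h[j] * Uz[j, k]
          ar <- ar + h[j] * Ur[j, k]
        }
        z[k] <- 1 / (1 + exp(-az))
        r[k] <- 1 / (1 + exp(-ar))
      }
      for (k in 1:H) {
        ac <- bc[k]
        for (e in 1:E) ac <- ac + X[t, e] * Wc[e, k]
        for (j in 1:H) ac <- ac + r[j] * h[j] * Uc[j, k]
        cc[k] <- tanh(ac)
      }
      h <- (1 - z) * h + z * cc
    }
    states[t, ] <- h
  }
  states
}

# Scalar attention pooling: tanh scores, exponentiate over valid
# positions only, normalize, weighted sum.
oracle_attention <- function(H, W, b, mask) {
  T_ <- nrow(H)
  e <- numeric(T_)
  for (t in 1:T_) e[t] <- tanh(sum(W * H[t, ]) + b)
  num <- ifelse(mask, exp(e), 0)
  alpha <- num / sum(num)
  v <- numeric(ncol(H))
  for (t in 1:T_) v <- v + alpha[t] * H[t, ]
  list(v = v, alpha = alpha, e = e)
}

oracle_encode_sequence <- function(X, mask, params) {
  f <- oracle_gru_direction(X, mask, params$fwd, reverse = FALSE)
  b <- oracle_gru_direction(X, mask, params$bwd, reverse = TRUE)
  Hcat <- cbind(f, b)
  c(oracle_attention(Hcat, params$att$W, params$att$b, mask),
    list(annotations = Hcat))
}

# ---- shared fixtures --------------------------------------------------

tiny_encoded_corpus <- function(n = 40, seed = 7, location = "title",
                                strength = 1, max_sentences = 6,
                                max_words = 10, annotate = FALSE) {
  spec <- synthetic_spec(n_documents = n, signal_location = location,
                         signal_strength = strength, seed = seed,
                         sentence_range = c(2L, 4L), words_range = c(4L, 8L))
  corp <- generate_corpus(spec)
  cfg <- preprocess_config(max_sentences = max_sentences,
                           max_words = max_words,
                           annotate_entities = annotate,
                           tokenization_option = "both")
  enc <- encode_corpus(corp$documents,
                       if (annotate) corp$annotations else NULL,
                       config = cfg)
  list(corpus = corp, enc = enc, cfg = cfg)
}

tiny_model <- function(enc, E = 8, S = 3, D = 4, seed = 11, regularized = FALSE) {
  emb <- init_embedding_matrix(enc$vocab, dim = E, seed = seed)
  cfg <- if (regularized) {
    model_config(embedding_dim = E, sentence_size = S, document_size = D)
  } else {
    model_config(embedding_dim = E, sentence_size = S, document_size = D,
                 dropout_embedding = 0, dropout_gru = 0,
                 dropout_attention = 0, noise_sigma = 0)
  }
  hbgru_init(cfg, emb, seed = seed)
}

# A fabricated labeled tokenized document, for statistics tests.
stub_tokenized <- function(label, n_sentences = 1, words = c("w")) {
  structure(
    list(sentences = replicate(n_sentences, words, simplify = FALSE)),
    doc_id = "stub", label = label, class = "tokenized_document"
  )
}
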