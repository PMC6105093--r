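# The hierarchical bi-directional GRU attention network. One reusable
# sequence encoder (bi-directional GRU + scalar-score attention pooling)
# is instantiated twice: at the word level to turn each sentence into a
# vector, and at the sentence level to turn the abstract vectors into a
# document vector. The title's sentence vector bypasses the document
# encoder through a shortcut and is concatenated directly into the final
# feature vector d = t || a, classified by a single logistic neuron.
#
# Forward and backward passes are implemented directly with matrix
# algebra. Within a document all sentences are processed as one batch by
# the word-level encoder (rows = sentences, steps = word positions).

#' Model hyper-parameter configuration
#'
#' Defaults are the published optimal hyper-parameters: 200-dimensional
#' embeddings with dropout 0.2 and Gaussian input noise sigma 0.2; GRU
#' size 150 per direction with dropout 0.3 at both levels; scalar (size-1)
#' attention with dropout 0.3 at both levels.
#'
#' @param embedding_dim `E`, embedding dimension.
#' @param sentence_size `S`, sentence-level GRU size per direction.
#' @param document_size `D`, document-level GRU size per direction.
#' @param dropout_embedding,dropout_gru,dropout_attention dropout rates in
#'   `[0, 1)` at the three sites (embedded inputs, GRU annotation outputs,
#'   attention-pooled vectors).
#' @param noise_sigma standard deviation of the zero-mean Gaussian noise
#'   added to embedded inputs during training (a data-augmentation
#'   regularizer: the network never sees the exact same sentence twice).
#' @param freeze_embeddings keep the embedding matrix fixed during
#'   training (default: trainable).
#' @return A `model_config` list.
#' @export
model_config <- function(embedding_dim = 200L,
                         sentence_size = 150L,
                         document_size = 150L,
                         dropout_embedding = 0.2,
                         dropout_gru = 0.3,
                         dropout_attention = 0.3,
                         noise_sigma = 0.2,
                         freeze_embeddings = FALSE) {
  for (nm in c("embedding_dim", "sentence_size", "document_size")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 1) {
      validation_error("`%s` must be a positive integer", nm)
    }
  }
  for (nm in c("dropout_embedding", "dropout_gru", "dropout_attention")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v >= 1) {
      validation_error("`%s` must lie in [0, 1)", nm)
    }
  }
  assert_scalar_number(noise_sigma, "noise_sigma", 0, Inf)
  structure(
    list(embedding_dim = as.integer(embedding_dim),
         sentence_size = as.integer(sentence_size),
         document_size = as.integer(document_size),
         dropout_embedding = dropout_embedding,
         dropout_gru = dropout_gru,
         dropout_attention = dropout_attention,
         noise_sigma = noise_sigma,
         freeze_embeddings = isTRUE(freeze_embeddings)),
    class = "model_config"
  )
}

glorot_limit <- function(fan_in, fan_out) sqrt(6 / (fan_in + fan_out))

glorot_matrix <- function(nr, nc, fan_in, fan_out) {
  lim <- glorot_limit(fan_in, fan_out)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# One GRU direction: W (input x 3H, gate blocks z|r|c), U_zr (H x 2H),
# U_c (H x H), b (3H).
gru_block_init <- function(input_size, hidden) {
  list(W = glorot_matrix(input_size, 3L * hidden, input_size, hidden),
       U_zr = glorot_matrix(hidden, 2L * hidden, hidden, hidden),
       U_c = glorot_matrix(hidden, hidden, hidden, hidden),
       b = numeric(3L * hidden))
}

#' Initialize sequence-encoder parameters
#'
#' One bi-directional GRU (forward + backward blocks) plus the attention
#' layer: a weight vector `W` of length `2 * hidden` and a scalar bias
#' `b`, producing one scalar score per position (attention size 1).
#' Recurrent/input weights use variance-scaled (Glorot) uniform
#' initialization; biases start at zero. Draws come from the current RNG
#' state — seed at the caller.
#'
#' @param input_size input vector length per position.
#' @param hidden GRU size per direction.
#' @return A `seq_encoder_params` list with `fwd`, `bwd`, `att` and the
#'   sizes.
#' @export
seq_encoder_init <- function(input_size, hidden) {
  structure(
    list(fwd = gru_block_init(input_size, hidden),
         bwd = gru_block_init(input_size, hidden),
         att = list(W = stats::runif(2L * hidden,
                                     -glorot_limit(2L * hidden, 1L),
                                     glorot_limit(2L * hidden, 1L)),
                    b = 0),
         input_size = as.integer(input_size),
         hidden = as.integer(hidden)),
    class = "seq_encoder_params"
  )
}

# ---- GRU forward/backward over a batch of K rows and T steps ----------

# X_list: list over t of K x input matrices; mask: K x T logical.
# reverse = TRUE reads positions T..1. Masked positions carry the state
# through unchanged, so padding never alters states across valid content.
gru_dir_forward <- function(X_list, mask, blk, reverse = FALSE) {
  T_ <- length(X_list)
  K <- nrow(X_list[[1L]])
  H <- ncol(blk$U_c)
  ord <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  Hprev <- matrix(0, K, H)
  states <- vector("list", T_)
  caches <- vector("list", T_)
  i1 <- seq_len(H)
  i2 <- H + i1
  i3 <- 2L * H + i1
  for (t in ord) {
    X <- X_list[[t]]
    m <- as.numeric(mask[, t])
    pre_x <- X %*% blk$W
    zr <- pre_x[, c(i1, i2), drop = FALSE] + Hprev %*% blk$U_zr
    z <- sigmoid(sweep(zr[, i1, drop = FALSE], 2L, blk$b[i1], `+`))
    r <- sigmoid(sweep(zr[, i2, drop = FALSE], 2L, blk$b[i2], `+`))
    c_pre <- sweep(pre_x[, i3, drop = FALSE] + (r * Hprev) %*% blk$U_c,
                   2L, blk$b[i3], `+`)
    cc <- tanh(c_pre)
    h_new <- (1 - z) * Hprev + z * cc
    h <- m * h_new + (1 - m) * Hprev
    states[[t]] <- h
    caches[[t]] <- list(X = X, Hprev = Hprev, z = z, r = r, cc = cc, m = m)
    Hprev <- h
  }
  list(states = states, caches = caches, ord = ord)
}

gru_step_backward <- function(cache, blk, dh) {
  H <- ncol(blk$U_c)
  i1 <- seq_len(H)
  m <- cache$m
  dh_new <- m * dh
  dHprev <- (1 - m) * dh
  dz <- dh_new * (cache$cc - cache$Hprev)
  dcc <- dh_new * cache$z
  dHprev <- dHprev + dh_new * (1 - cache$z)
  dc_pre <- dcc * (1 - cache$cc^2)
  dr_h <- dc_pre %*% t(blk$U_c)
  dr <- dr_h * cache$Hprev
  dHprev <- dHprev + dr_h * cache$r
  dz_pre <- dz * cache$z * (1 - cache$z)
  dr_pre <- dr * cache$r * (1 - cache$r)
  dpre <- cbind(dz_pre, dr_pre, dc_pre)
  list(dW = crossprod(cache$X, dpre),
       dU_zr = crossprod(cache$Hprev, cbind(dz_pre, dr_pre)),
       dU_c = crossprod(cache$r * cache$Hprev, dc_pre),
       db = colSums(dpre),
       dX = dpre %*% t(blk$W),
       dHprev = dHprev + cbind(dz_pre, dr_pre) %*% t(blk$U_zr))
}

gru_dir_backward <- function(fwd_out, blk, dH_list) {
  T_ <- length(dH_list)
  K <- nrow(dH_list[[1L]])
  H <- ncol(blk$U_c)
  g <- list(dW = blk$W * 0, dU_zr = blk$U_zr * 0, dU_c = blk$U_c * 0,
            db = blk$b * 0)
  dX_list <- vector("list", T_)
  carry <- matrix(0, K, H)
  for (t in rev(fwd_out$ord)) {
    res <- gru_step_backward(fwd_out$caches[[t]], blk, dH_list[[t]] + carry)
    g$dW <- g$dW + res$dW
    g$dU_zr <- g$dU_zr + res$dU_zr
    g$dU_c <- g$dU_c + res$dU_c
    g$db <- g$db + res$db
    dX_list[[t]] <- res$dX
    carry <- res$dHprev
  }
  list(grads = g, dX_list = dX_list)
}

# ---- masked attention over annotations --------------------------------

# Hd_list: list over t of K x 2H matrices (annotations, post-dropout);
# mask K x T. Scores e = tanh(W.h + b); alpha = softmax over valid t.
attention_forward <- function(Hd_list, mask, att) {
  T_ <- length(Hd_list)
  K <- nrow(Hd_list[[1L]])
  e <- matrix(0, K, T_)
  for (t in seq_len(T_)) {
    e[, t] <- tanh(Hd_list[[t]] %*% att$W + att$b)
  }
  w <- exp(e) * mask
  denom <- rowSums(w)
  if (any(denom == 0)) validation_error("attention over fully masked sequence")
  alpha <- w / denom
  v <- matrix(0, K, ncol(Hd_list[[1L]]))
  for (t in seq_len(T_)) {
    v <- v + alpha[, t] * Hd_list[[t]]
  }
  list(v = v, alpha = alpha, e = e)
}

attention_backward <- function(Hd_list, mask, att, fw, dv) {
  T_ <- length(Hd_list)
  alpha <- fw$alpha
  dalpha <- matrix(0, nrow(alpha), T_)
  dHd_list <- vector("list", T_)
  for (t in seq_len(T_)) {
    dalpha[, t] <- rowSums(dv * Hd_list[[t]])
    dHd_list[[t]] <- alpha[, t] * dv
  }
  de <- alpha * (dalpha - rowSums(alpha * dalpha))
  dpre <- de * (1 - fw$e^2) * mask
  dW <- numeric(length(att$W))
  for (t in seq_len(T_)) {
    dW <- dW + colSums(dpre[, t] * Hd_list[[t]])
    dHd_list[[t]] <- dHd_list[[t]] + outer(dpre[, t], att$W)
  }
  list(dW = dW, db = sum(dpre), dHd_list = dHd_list)
}

#' Attention pooling over a sequence of annotation vectors
#'
#' Scores each position with `e_j = tanh(W . h_j + b)`, normalizes the
#' scores with a masked softmax restricted to valid positions (masked
#' positions get weight exactly 0), and returns the weighted sum of the
#' annotations. This is the pooling layer used at both hierarchy levels.
#'
#' @param H a `T x 2H` numeric matrix of annotation vectors (rows =
#'   positions), or a list of equal-length numeric vectors.
#' @param params a `seq_encoder_params` (its `att` component is used) or a
#'   list with elements `W` (length `2H`) and `b` (scalar).
#' @param mask logical vector of length `T`; `TRUE` marks valid positions.
#'   Default: all valid.
#' @return An `attention_result` list: `v` (pooled vector), `alpha`
#'   (weights, summing to 1 over valid positions), `e` (raw scores).
#' @export
attention_pool <- function(H, params, mask = NULL) {
  if (is.list(H) && !is.data.frame(H)) H <- do.call(rbind, H)
  H <- as.matrix(H)
  T_ <- nrow(H)
  if (is.null(mask)) mask <- rep(TRUE, T_)
  if (length(mask) != T_) validation_error("mask length must equal sequence length")
  if (!any(mask)) validation_error("all positions are masked")
  att <- if (inherits(params, "seq_encoder_params")) params$att else params
  if (length(att$W) != ncol(H)) {
    validation_error("attention weight length %d != annotation length %d",
                     length(att$W), ncol(H))
  }
  Hd_list <- lapply(seq_len(T_), function(t) H[t, , drop = FALSE])
  fw <- attention_forward(Hd_list, matrix(mask, nrow = 1L), att)
  structure(list(v = as.numeric(fw$v), alpha = as.numeric(fw$alpha),
                 e = as.numeric(fw$e)),
            class = "attention_result")
}

#' Encode a sequence with the bi-directional GRU + attention
#'
#' The reusable sequence encoder: a forward GRU reads positions `1..T`, a
#' backward GRU reads `T..1`, per-position annotations are the
#' concatenation of both hidden states (length `2 * hidden`), and
#' [attention_pool()] reduces them to one fixed-length vector. Masked
#' (padded) positions carry the recurrent state through unchanged and are
#' excluded from the attention softmax, so padding appended after the
#' valid content never changes the result. Inference-mode (no dropout, no
#' noise).
#'
#' @param X `T x input_size` numeric matrix of input vectors.
#' @param mask logical vector of length `T` (default all valid).
#' @param params a `seq_encoder_params` from [seq_encoder_init()].
#' @return An `attention_result` with pooled vector of length
#'   `2 * hidden`, plus element `annotations` (`T x 2*hidden` matrix).
#' @export
encode_sequence <- function(X, mask = NULL, params) {
  stopifnot(inherits(params, "seq_encoder_params"))
  X <- as.matrix(X)
  T_ <- nrow(X)
  if (T_ < 1L) validation_error("sequence must have at least one position")
  if (is.null(mask)) mask <- rep(TRUE, T_)
  if (!any(mask)) validation_error("all positions are masked")
  if (ncol(X) != params$input_size) {
    validation_error("input size %d != encoder input size %d",
                     ncol(X), params$input_size)
  }
  X_list <- lapply(seq_len(T_), function(t) X[t, , drop = FALSE])
  mask_mat <- matrix(mask, nrow = 1L)
  f <- gru_dir_forward(X_list, mask_mat, params$fwd, reverse = FALSE)
  b <- gru_dir_forward(X_list, mask_mat, params$bwd, reverse = TRUE)
  Hcat <- lapply(seq_len(T_), function(t) cbind(f$states[[t]], b$states[[t]]))
  fw <- attention_forward(Hcat, mask_mat, params$att)
  structure(
    list(v = as.numeric(fw$v), alpha = as.numeric(fw$alpha),
         e = as.numeric(fw$e),
         annotations = do.call(rbind, lapply(Hcat, as.numeric))),
    class = "attention_result"
  )
}

# ---- the full hierarchical model --------------------------------------

#' Initialize a hierarchical BGRU model
#'
#' Builds the full parameter set: trainable embedding matrix (from an
#' [init_embedding_matrix()] object), word-level sequence encoder of size
#' `S` per direction reading embedded words, sentence-level encoder of
#' size `D` per direction reading the abstract's sentence vectors, and
#' the logistic output layer over `d = t || a` (length `2S + 2D`).
#'
#' @param config a [model_config()].
#' @param embedding an `hbgru_embedding` from [init_embedding_matrix()];
#'   its dimension must match `config$embedding_dim`.
#' @param seed integer seed for parameter initialization.
#' @return An object of class `hbgru_model`: list with `params`, `config`,
#'   `vocab`.
#' @export
hbgru_init <- function(config, embedding, seed = 1L) {
  stopifnot(inherits(config, "model_config"),
            inherits(embedding, "hbgru_embedding"))
  E <- config$embedding_dim
  if (ncol(embedding$weights) != E) {
    validation_error("embedding dimension %d != config embedding_dim %d",
                     ncol(embedding$weights), E)
  }
  S <- config$sentence_size
  D <- config$document_size
  params <- with_seed(seed, {
    list(
      emb = embedding$weights,
      sent = seq_encoder_init(E, S),
      doc = seq_encoder_init(2L * S, D),
      out = list(w = stats::runif(2L * S + 2L * D,
                                  -glorot_limit(2L * S + 2L * D, 1L),
                                  glorot_limit(2L * S + 2L * D, 1L)),
                 b = 0)
    )
  })
  structure(list(params = params, config = config, vocab = embedding$vocab),
            class = "hbgru_model")
}

#' @export
print.hbgru_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Hierarchical BGRU model: E=%d, S=%d, D=%d (d length %d), vocab %d\n",
    cfg$embedding_dim, cfg$sentence_size, cfg$document_size,
    2L * (cfg$sentence_size + cfg$document_size), nrow(x$params$emb)))
  invisible(x)
}

# Bernoulli keep-mask with inverted scaling; identity when p = 0 or not
# training.
dropout_mask <- function(nr, nc, p, training) {
  if (!training || p <= 0) return(NULL)
  matrix(stats::rbinom(nr * nc, 1L, 1 - p) / (1 - p), nr, nc)
}

apply_mask <- function(X, mask) if (is.null(mask)) X else X * mask

#' Forward pass on one encoded document
#'
#' Embeds every valid row of the document matrix, encodes each sentence
#' with the word-level encoder (all sentences of the document processed as
#' one batch), takes `t` = the title row's sentence vector, feeds the
#' abstract sentence vectors — and only those — to the document-level
#' encoder to obtain `a`, concatenates `d = t || a`, and applies the
#' logistic output layer. In training mode Gaussian noise (sigma from the
#' config) is added to the embedded inputs and dropout is applied at the
#' configured sites, drawing from the current RNG state; in inference mode
#' the pass is deterministic. For a title-only document `a` is the zero
#' vector, keeping the shortcut meaningful.
#'
#' @param model an `hbgru_model`.
#' @param mat a `document_matrix` from [encode_document()].
#' @param training training-mode flag (noise + dropout).
#' @param keep_cache retain intermediate quantities for backpropagation
#'   (internal use).
#' @return A `document_representation` list: `t`, `a`, `d`, `p`
#'   (probability), `word_alpha` (attention weights per sentence),
#'   `sentence_alpha`, and invisibly the cache when requested.
#' @export
hbgru_forward <- function(model, mat, training = FALSE, keep_cache = FALSE) {
  stopifnot(inherits(model, "hbgru_model"), inherits(mat, "document_matrix"))
  params <- model$params
  cfg <- model$config
  valid <- which(mat$sentence_mask)
  if (length(valid) == 0L || !mat$sentence_mask[[1L]]) {
    validation_error("document has no valid title row")
  }
  if (!all(diff(valid) == 1L)) valid <- seq_len(max(valid))  # contiguous rows
  K <- length(valid)
  if (!any(mat$word_mask[1L, ])) validation_error("empty title row")
  used_cols <- which(colSums(mat$word_mask[valid, , drop = FALSE]) > 0L)
  T_ <- if (length(used_cols)) max(used_cols) else 1L
  wmask <- mat$word_mask[valid, seq_len(T_), drop = FALSE]
  if (is.vector(wmask)) wmask <- matrix(wmask, nrow = K)
  E <- cfg$embedding_dim
  S <- cfg$sentence_size
  D <- cfg$document_size

  idx <- mat$values[valid, seq_len(T_), drop = FALSE] + 1L
  X_list <- vector("list", T_)
  emb_masks <- vector("list", T_)
  for (t in seq_len(T_)) {
    X <- params$emb[idx[, t], , drop = FALSE]
    if (training && cfg$noise_sigma > 0) {
      X <- X + matrix(stats::rnorm(K * E, 0, cfg$noise_sigma), K, E)
    }
    emb_masks[t] <- list(dropout_mask(K, E, cfg$dropout_embedding, training))
    X_list[[t]] <- apply_mask(X, emb_masks[[t]])
  }

  f <- gru_dir_forward(X_list, wmask, params$sent$fwd, reverse = FALSE)
  b <- gru_dir_forward(X_list, wmask, params$sent$bwd, reverse = TRUE)
  Hcat <- vector("list", T_)
  gru_masks <- vector("list", T_)
  for (t in seq_len(T_)) {
    Hc <- cbind(f$states[[t]], b$states[[t]])
    gru_masks[t] <- list(dropout_mask(K, 2L * S, cfg$dropout_gru, training))
    Hcat[[t]] <- apply_mask(Hc, gru_masks[[t]])
  }
  att_w <- attention_forward(Hcat, wmask, params$sent$att)
  v_mask <- dropout_mask(K, 2L * S, cfg$dropout_attention, training)
  V <- apply_mask(att_w$v, v_mask)

  t_vec <- V[1L, ]
  doc_cache <- NULL
  a_mask <- NULL
  if (K > 1L) {
    A_list <- lapply(2:K, function(i) V[i, , drop = FALSE])
    ones <- matrix(TRUE, 1L, K - 1L)
    df <- gru_dir_forward(A_list, ones, params$doc$fwd, reverse = FALSE)
    db <- gru_dir_forward(A_list, ones, params$doc$bwd, reverse = TRUE)
    DHcat <- vector("list", K - 1L)
    dgru_masks <- vector("list", K - 1L)
    for (j in seq_len(K - 1L)) {
      DH <- cbind(df$states[[j]], db$states[[j]])
      dgru_masks[j] <- list(dropout_mask(1L, 2L * D, cfg$dropout_gru, training))
      DHcat[[j]] <- apply_mask(DH, dgru_masks[[j]])
    }
    att_d <- attention_forward(DHcat, ones, params$doc$att)
    a_mask <- dropout_mask(1L, 2L * D, cfg$dropout_attention, training)
    a_vec <- as.numeric(apply_mask(att_d$v, a_mask))
    doc_cache <- list(A_list = A_list, df = df, db = db, DHcat = DHcat,
                      dgru_masks = dgru_masks, att_d = att_d, ones = ones)
    sent_alpha <- as.numeric(att_d$alpha)
  } else {
    a_vec <- numeric(2L * D)
    sent_alpha <- numeric(0)
  }
  d <- c(t_vec, a_vec)
  logit <- sum(params$out$w * d) + params$out$b
  p <- sigmoid(logit)

  rep_ <- structure(
    list(t = t_vec, a = a_vec, d = d, p = p,
         word_alpha = att_w$alpha, sentence_alpha = sent_alpha),
    class = "document_representation"
  )
  if (keep_cache) {
    attr(rep_, "cache") <- list(
      valid = valid, K = K, T_ = T_, wmask = wmask, idx = idx,
      X_list = X_list, emb_masks = emb_masks, f = f, b = b,
      Hcat = Hcat, gru_masks = gru_masks, att_w = att_w,
      v_mask = v_mask, V = V, doc = doc_cache, a_mask = a_mask,
      d = d, p = p)
  }
  rep_
}

#' Predict relevance probabilities for encoded documents
#'
#' Runs the deterministic inference-mode forward pass on each document and
#' thresholds the probability; ties at the threshold classify positive.
#'
#' @param model an `hbgru_model`.
#' @param matrices list of `document_matrix` objects.
#' @param threshold classification threshold in (0, 1), default 0.5.
#' @return A data frame with columns `doc_id`, `probability`, `label`, in
#'   input order.
#' @export
hbgru_predict <- function(model, matrices, threshold = 0.5) {
  assert_scalar_number(threshold, "threshold", 0, 1)
  if (threshold <= 0 || threshold >= 1) {
    validation_error("threshold must lie strictly in (0, 1)")
  }
  probs <- vapply(matrices, function(m) hbgru_forward(model, m)$p, numeric(1))
  ids <- vapply(matrices, function(m) {
    as.character(attr(m, "doc_id") %||% NA_character_)
  }, character(1))
  data.frame(doc_id = ids, probability = probs,
             label = as.integer(probs >= threshold),
             stringsAsFactors = FALSE)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file holding the parameters, the model
#' configuration and the vocabulary.
#'
#' @param model an `hbgru_model`.
#' @param path checkpoint file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "hbgru_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "hbgru_model")) validation_error("not an hbgru checkpoint: %s", path)
  m
}
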