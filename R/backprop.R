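# Analytic backpropagation through the full hierarchy, plus the small
# parameter-structure algebra (map/add/scale/norm) used by the optimizer.

# ---- parameter-structure algebra --------------------------------------

# Apply f elementwise to every numeric leaf of a (possibly nested) list,
# optionally pairing with the matching leaf of b.
param_map <- function(a, f, b = NULL) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) {
      if (is.list(a[[nm]]) || is.numeric(a[[nm]])) {
        out[[nm]] <- param_map(a[[nm]], f, if (!is.null(b)) b[[nm]])
      }
    }
    out
  } else if (is.numeric(a)) {
    if (is.null(b)) f(a) else f(a, b)
  } else {
    a
  }
}

param_zero <- function(a) param_map(a, function(x) x * 0)
param_add <- function(a, b) param_map(a, `+`, b)
param_scale <- function(a, s) param_map(a, function(x) x * s)

param_sq_norm <- function(a) {
  if (is.list(a)) {
    sum(vapply(a, function(x) {
      if (is.list(x) || is.numeric(x)) param_sq_norm(x) else 0
    }, numeric(1)))
  } else if (is.numeric(a)) {
    sum(a^2)
  } else {
    0
  }
}

#' Clip the global gradient norm
#'
#' Rescales the whole gradient vector so its Euclidean norm does not
#' exceed `clip_norm` (global rescaling, not per-parameter clamping), the
#' standard guard against exploding recurrent gradients.
#'
#' @param grads a (possibly nested) list of numeric gradient arrays.
#' @param clip_norm positive clipping threshold; `Inf` disables clipping.
#' @return The rescaled gradient structure.
#' @export
clip_gradients <- function(grads, clip_norm = 5) {
  assert_scalar_number(clip_norm, "clip_norm", 0, Inf)
  nrm <- sqrt(param_sq_norm(grads))
  if (is.finite(clip_norm) && nrm > clip_norm && nrm > 0) {
    param_scale(grads, clip_norm / nrm)
  } else {
    grads
  }
}

#' @rdname clip_gradients
#' @return `gradient_global_norm()`: the Euclidean norm over every leaf.
#' @export
gradient_global_norm <- function(grads) sqrt(param_sq_norm(grads))

# ---- backward pass ----------------------------------------------------

seq_grad_zero <- function(p) {
  list(fwd = list(dW = p$fwd$W * 0, dU_zr = p$fwd$U_zr * 0,
                  dU_c = p$fwd$U_c * 0, db = p$fwd$b * 0),
       bwd = list(dW = p$bwd$W * 0, dU_zr = p$bwd$U_zr * 0,
                  dU_c = p$bwd$U_c * 0, db = p$bwd$b * 0),
       att = list(dW = p$att$W * 0, db = 0))
}

add_blk <- function(a, b) {
  list(dW = a$dW + b$dW, dU_zr = a$dU_zr + b$dU_zr,
       dU_c = a$dU_c + b$dU_c, db = a$db + b$db)
}

# Gradient of the loss w.r.t. every parameter for one document, given
# dlogit = dL/d(pre-sigmoid output). Mirrors hbgru_forward step by step
# in reverse; dropout masks recorded in the cache are replayed.
hbgru_backward <- function(model, cache, dlogit) {
  params <- model$params
  cfg <- model$config
  S <- cfg$sentence_size
  D <- cfg$document_size
  K <- cache$K
  T_ <- cache$T_

  g <- list(
    emb = NULL,
    sent = seq_grad_zero(params$sent),
    doc = seq_grad_zero(params$doc),
    out = list(dw = dlogit * cache$d, db = dlogit)
  )
  dd <- dlogit * params$out$w
  dt <- dd[seq_len(2L * S)]
  da <- dd[2L * S + seq_len(2L * D)]

  dV <- matrix(0, K, 2L * S)
  dV[1L, ] <- dt
  if (K > 1L) {
    dc <- cache$doc
    da_m <- matrix(da, 1L)
    if (!is.null(cache$a_mask)) da_m <- da_m * cache$a_mask
    attb <- attention_backward(dc$DHcat, dc$ones, params$doc$att, dc$att_d, da_m)
    g$doc$att$dW <- attb$dW
    g$doc$att$db <- attb$db
    dDH <- attb$dHd_list
    for (j in seq_len(K - 1L)) {
      if (!is.null(dc$dgru_masks[[j]])) dDH[[j]] <- dDH[[j]] * dc$dgru_masks[[j]]
    }
    dDf <- lapply(dDH, function(x) x[, seq_len(D), drop = FALSE])
    dDb <- lapply(dDH, function(x) x[, D + seq_len(D), drop = FALSE])
    rf <- gru_dir_backward(dc$df, params$doc$fwd, dDf)
    rb <- gru_dir_backward(dc$db, params$doc$bwd, dDb)
    g$doc$fwd <- add_blk(g$doc$fwd, rf$grads)
    g$doc$bwd <- add_blk(g$doc$bwd, rb$grads)
    for (j in seq_len(K - 1L)) {
      dV[j + 1L, ] <- dV[j + 1L, ] + rf$dX_list[[j]] + rb$dX_list[[j]]
    }
  }

  if (!is.null(cache$v_mask)) dV <- dV * cache$v_mask
  attw <- attention_backward(cache$Hcat, cache$wmask, params$sent$att,
                             cache$att_w, dV)
  g$sent$att$dW <- attw$dW
  g$sent$att$db <- attw$db
  dH <- attw$dHd_list
  for (t in seq_len(T_)) {
    if (!is.null(cache$gru_masks[[t]])) dH[[t]] <- dH[[t]] * cache$gru_masks[[t]]
  }
  dHf <- lapply(dH, function(x) x[, seq_len(S), drop = FALSE])
  dHb <- lapply(dH, function(x) x[, S + seq_len(S), drop = FALSE])
  rf <- gru_dir_backward(cache$f, params$sent$fwd, dHf)
  rb <- gru_dir_backward(cache$b, params$sent$bwd, dHb)
  g$sent$fwd <- add_blk(g$sent$fwd, rf$grads)
  g$sent$bwd <- add_blk(g$sent$bwd, rb$grads)

  if (!cfg$freeze_embeddings) {
    demb <- params$emb * 0
    for (t in seq_len(T_)) {
      dX <- rf$dX_list[[t]] + rb$dX_list[[t]]
      if (!is.null(cache$emb_masks[[t]])) dX <- dX * cache$emb_masks[[t]]
      rows <- cache$idx[, t]
      for (k in seq_len(K)) {
        demb[rows[[k]], ] <- demb[rows[[k]], ] + dX[k, ]
      }
    }
    demb[1L, ] <- 0  # padding row stays fixed
    g$emb <- demb
  }
  g
}

# Binary cross-entropy on one probability, numerically guarded.
bce_loss <- function(p, y) {
  eps <- 1e-12
  -(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}
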