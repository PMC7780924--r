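# Internal transformer-encoder machinery: parameter initialisation,
# forward pass, hand-derived backward pass, and Adam.
#
# Layout conventions:
#   - a batch of B sequences padded to length L is stacked row-wise into a
#     (B*L) x d matrix; row (b-1)*L + t is position t of sequence b.
#   - token ids are 0-based (vocabulary indices); +1 when indexing rows of
#     the embedding matrix.
#   - post-layer-norm residual blocks, as in the original bidirectional
#     encoder: H1 = LN(X + MHA(X)); H2 = LN(H1 + FFN(H1)).
# The backward pass is verified against finite differences in the test
# suite; keep any change here in lock-step with those tests.

LN_EPS <- 1e-5

init_matrix <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

# Parameters as a nested list; Adam state mirrors the structure.
init_encoder_params <- function(cfg) {
  d <- cfg$hidden_dim; ff <- cfg$ff_dim; V <- cfg$vocab_size; L <- cfg$max_len
  layers <- lapply(seq_len(cfg$num_layers), function(l) {
    list(
      Wq = init_matrix(d, d), bq = numeric(d),
      Wk = init_matrix(d, d), bk = numeric(d),
      Wv = init_matrix(d, d), bv = numeric(d),
      Wo = init_matrix(d, d), bo = numeric(d),
      ln1_g = rep(1, d), ln1_b = numeric(d),
      W1 = init_matrix(d, ff), b1 = numeric(ff),
      W2 = init_matrix(ff, d), b2 = numeric(d),
      ln2_g = rep(1, d), ln2_b = numeric(d)
    )
  })
  list(
    tok_emb = init_matrix(V, d),
    pos_emb = init_matrix(L, d),
    emb_ln_g = rep(1, d), emb_ln_b = numeric(d),
    layers = layers,
    mlm_W = init_matrix(d, V), mlm_b = numeric(V)
  )
}

# GELU uses the tanh approximation throughout (the form popularised by
# the reference BERT codebase): 0.5 x (1 + tanh(sqrt(2/pi)(x + 0.044715 x^3)))
GELU_C <- sqrt(2 / pi)

layernorm_forward <- function(X, g, b) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc * Xc)
  inv <- 1 / sqrt(v + LN_EPS)
  Xhat <- Xc * inv
  n <- nrow(X)
  list(Y = Xhat * rep(g, each = n) + rep(b, each = n),
       Xhat = Xhat, inv = inv)
}

layernorm_backward <- function(dY, cache, g) {
  Xhat <- cache$Xhat
  dg <- colSums(dY * Xhat)
  db <- colSums(dY)
  dXhat <- dY * rep(g, each = nrow(dY))
  m1 <- rowMeans(dXhat)
  m2 <- rowMeans(dXhat * Xhat)
  dX <- cache$inv * (dXhat - m1 - Xhat * m2)
  list(dX = dX, dg = dg, db = db)
}

# Row-wise softmax of a matrix of logits.
softmax_rows <- function(S) {
  rmax <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - rmax)
  E / rowSums(E)
}

# Scaled dot-product attention for one (already projected) query/key/value
# triple.  `key_mask` is a logical vector over key positions (TRUE = real
# token); masked keys receive -Inf logits so each attention row is a
# distribution over unmasked positions only.  Exported surface lives in
# protein_lm.R; this internal returns caches for the backward pass.
sdp_attention <- function(Q, K, V, key_mask = NULL) {
  if (ncol(Q) != ncol(K)) {
    stop("attention: query width ", ncol(Q), " != key width ", ncol(K))
  }
  if (nrow(K) != nrow(V)) {
    stop("attention: ", nrow(K), " keys vs ", nrow(V), " values")
  }
  scal <- 1 / sqrt(ncol(Q))
  S <- tcrossprod(Q, K) * scal
  if (!is.null(key_mask)) S[, !key_mask] <- -1e30
  A <- softmax_rows(S)
  list(O = A %*% V, A = A, scal = scal)
}

# Multi-head self-attention on one sequence block X (L x d) with packed
# head projections.  Returns output and caches.
mha_forward <- function(X, lp, n_heads, key_mask) {
  d <- ncol(X)
  dk <- d %/% n_heads
  Q <- X %*% lp$Wq + rep(lp$bq, each = nrow(X))
  K <- X %*% lp$Wk + rep(lp$bk, each = nrow(X))
  V <- X %*% lp$Wv + rep(lp$bv, each = nrow(X))
  O <- matrix(0, nrow(X), d)
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    at <- sdp_attention(Q[, idx, drop = FALSE], K[, idx, drop = FALSE],
                        V[, idx, drop = FALSE], key_mask)
    O[, idx] <- at$O
    heads[[h]] <- at$A
  }
  out <- O %*% lp$Wo + rep(lp$bo, each = nrow(X))
  list(out = out, Q = Q, K = K, V = V, O = O, heads = heads)
}

# Full encoder forward.
#   ids:  B x L integer matrix of 0-based token ids (PAD-padded)
#   mask: B x L numeric/logical matrix, 1 on real tokens
# Returns final hidden states H ((B*L) x d) and caches for backward.
encoder_forward <- function(params, cfg, ids, mask, dropout_rate = 0) {
  B <- nrow(ids); L <- ncol(ids); d <- cfg$hidden_dim
  ids_flat <- as.integer(t(ids))          # row-major: (b-1)*L + t
  X <- params$tok_emb[ids_flat + 1L, , drop = FALSE] +
    params$pos_emb[rep(seq_len(L), B), , drop = FALSE]
  ln0 <- layernorm_forward(X, params$emb_ln_g, params$emb_ln_b)
  H <- ln0$Y
  drop_masks <- list()
  if (dropout_rate > 0) {
    keep <- 1 - dropout_rate
    dm <- matrix((stats::runif(length(H)) < keep) / keep, nrow(H), ncol(H))
    H <- H * dm
    drop_masks$emb <- dm
  }
  key_masks <- lapply(seq_len(B), function(b) as.logical(mask[b, ]))
  nh <- cfg$num_heads
  dk <- d %/% nh
  scal <- 1 / sqrt(dk)
  BL <- B * L
  layer_caches <- vector("list", cfg$num_layers)
  for (l in seq_len(cfg$num_layers)) {
    lp <- params$layers[[l]]
    # packed projections for the whole stacked batch, one BLAS call each
    Q <- H %*% lp$Wq + rep(lp$bq, each = BL)
    K <- H %*% lp$Wk + rep(lp$bk, each = BL)
    V <- H %*% lp$Wv + rep(lp$bv, each = BL)
    O <- matrix(0, BL, d)
    A_cache <- vector("list", B * nh)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * L + 1L):(b * L)
      km <- key_masks[[b]]
      masked <- !all(km)
      for (h in seq_len(nh)) {
        idx <- ((h - 1L) * dk + 1L):(h * dk)
        S <- tcrossprod(Q[rows, idx, drop = FALSE],
                        K[rows, idx, drop = FALSE]) * scal
        if (masked) S[, !km] <- -1e30
        A <- softmax_rows(S)
        O[rows, idx] <- A %*% V[rows, idx, drop = FALSE]
        A_cache[[(b - 1L) * nh + h]] <- A
      }
    }
    attn_out <- O %*% lp$Wo + rep(lp$bo, each = BL)
    mha_caches <- list(Q = Q, K = K, V = V, O = O, A = A_cache)
    ln1 <- layernorm_forward(H + attn_out, lp$ln1_g, lp$ln1_b)
    H1 <- ln1$Y
    Z <- H1 %*% lp$W1 + rep(lp$b1, each = B * L)
    if (identical(cfg$activation, "relu")) {
      Tn <- NULL
      G <- pmax(Z, 0)
    } else {
      Tn <- tanh(GELU_C * (Z + 0.044715 * Z^3))
      G <- 0.5 * Z * (1 + Tn)
    }
    FF <- G %*% lp$W2 + rep(lp$b2, each = B * L)
    ln2 <- layernorm_forward(H1 + FF, lp$ln2_g, lp$ln2_b)
    layer_caches[[l]] <- list(H_in = H, mha = mha_caches, ln1 = ln1,
                              H1 = H1, Z = Z, Tn = Tn, G = G, ln2 = ln2)
    H <- ln2$Y
  }
  list(H = H, ids_flat = ids_flat, ln0 = ln0, layer_caches = layer_caches,
       key_masks = key_masks, drop_masks = drop_masks, B = B, L = L)
}

# Backward through the encoder given dH at the final hidden states.
# Returns gradients with the same structure as the parameter list
# (mlm head excluded; handled by the caller that produced dH).
encoder_backward <- function(params, cfg, fwd, dH) {
  B <- fwd$B; L <- fwd$L; d <- cfg$hidden_dim
  grads <- list(layers = vector("list", cfg$num_layers))
  for (l in rev(seq_len(cfg$num_layers))) {
    lp <- params$layers[[l]]
    cc <- fwd$layer_caches[[l]]
    lb2 <- layernorm_backward(dH, cc$ln2, lp$ln2_g)
    dFF <- lb2$dX
    dG <- tcrossprod(dFF, lp$W2)
    dZ <- if (identical(cfg$activation, "relu")) {
      dG * (cc$Z > 0)
    } else {
      dG * (0.5 * (1 + cc$Tn) +
              0.5 * cc$Z * (1 - cc$Tn * cc$Tn) * GELU_C *
                (1 + 3 * 0.044715 * cc$Z * cc$Z))
    }
    dH1 <- lb2$dX + tcrossprod(dZ, lp$W1)
    lb1 <- layernorm_backward(dH1, cc$ln1, lp$ln1_g)
    dAttnIn <- lb1$dX   # gradient wrt (H_in + attn_out)
    mh <- cc$mha
    nh <- cfg$num_heads
    dk <- d %/% nh
    scal <- 1 / sqrt(dk)
    dWo <- crossprod(mh$O, dAttnIn)
    dbo <- colSums(dAttnIn)
    dO <- tcrossprod(dAttnIn, lp$Wo)
    dQ <- matrix(0, B * L, d)
    dK <- matrix(0, B * L, d)
    dV <- matrix(0, B * L, d)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * L + 1L):(b * L)
      for (h in seq_len(nh)) {
        idx <- ((h - 1L) * dk + 1L):(h * dk)
        A <- mh$A[[(b - 1L) * nh + h]]
        dOh <- dO[rows, idx, drop = FALSE]
        dA <- tcrossprod(dOh, mh$V[rows, idx, drop = FALSE])
        dV[rows, idx] <- crossprod(A, dOh)
        dS <- A * (dA - rowSums(dA * A))
        dQ[rows, idx] <- dS %*% mh$K[rows, idx, drop = FALSE] * scal
        dK[rows, idx] <- crossprod(dS, mh$Q[rows, idx, drop = FALSE]) * scal
      }
    }
    dH_in <- dAttnIn +
      tcrossprod(dQ, lp$Wq) + tcrossprod(dK, lp$Wk) + tcrossprod(dV, lp$Wv)
    grads$layers[[l]] <- list(
      Wq = crossprod(cc$H_in, dQ), bq = colSums(dQ),
      Wk = crossprod(cc$H_in, dK), bk = colSums(dK),
      Wv = crossprod(cc$H_in, dV), bv = colSums(dV),
      Wo = dWo, bo = dbo,
      ln1_g = lb1$dg, ln1_b = lb1$db,
      W1 = crossprod(cc$H1, dZ), b1 = colSums(dZ),
      W2 = crossprod(cc$G, dFF), b2 = colSums(dFF),
      ln2_g = lb2$dg, ln2_b = lb2$db
    )
    dH <- dH_in
  }
  if (!is.null(fwd$drop_masks$emb)) dH <- dH * fwd$drop_masks$emb
  lb0 <- layernorm_backward(dH, fwd$ln0, params$emb_ln_g)
  dX <- lb0$dX
  # scatter-add into embedding tables
  dtok <- rowsum(dX, group = fwd$ids_flat, reorder = FALSE)
  dTok <- matrix(0, cfg$vocab_size, d)
  dTok[as.integer(rownames(dtok)) + 1L, ] <- dtok
  dpos <- rowsum(dX, group = rep(seq_len(L), B), reorder = FALSE)
  dPos <- matrix(0, cfg$max_len, d)
  dPos[as.integer(rownames(dpos)), ] <- dpos
  grads$tok_emb <- dTok
  grads$pos_emb <- dPos
  grads$emb_ln_g <- lb0$dg
  grads$emb_ln_b <- lb0$db
  grads
}

# Masked-LM loss: softmax cross-entropy over the labeled positions only.
# labels: B x L matrix of original 0-based ids, NA at unlabeled positions.
# Returns loss, accuracy on the batch, dH for encoder_backward, and the
# mlm-head gradients.
mlm_head_loss <- function(params, H, labels_flat) {
  lab_rows <- which(!is.na(labels_flat))
  if (length(lab_rows) == 0L) stop("no labeled positions in batch")
  y <- labels_flat[lab_rows] + 1L
  Hl <- H[lab_rows, , drop = FALSE]
  logits <- Hl %*% params$mlm_W + rep(params$mlm_b, each = length(lab_rows))
  P <- softmax_rows(logits)
  n <- length(lab_rows)
  picked <- P[cbind(seq_len(n), y)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  acc <- mean(max.col(logits, ties.method = "first") == y)
  dlogits <- P
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  dlogits <- dlogits / n
  dH <- matrix(0, nrow(H), ncol(H))
  dH[lab_rows, ] <- tcrossprod(dlogits, params$mlm_W)
  list(loss = loss, accuracy = acc, dH = dH,
       dW = crossprod(Hl, dlogits), db = colSums(dlogits))
}

# ---- backend dispatch ------------------------------------------------------
# The compiled fast path (src/transformer.cpp) mirrors the R reference
# implementation above; options(protpath.backend = "R") forces the
# reference path (used by the equivalence tests).

backend_cpp <- function() !identical(getOption("protpath.backend"), "R")

cfg_as_list <- function(cfg) {
  c(cfg[c("num_layers", "hidden_dim", "num_heads", "ff_dim", "max_len",
          "vocab_size", "dropout")],
    list(relu = identical(cfg$activation, "relu")))
}

as_int_matrix <- function(x) {
  storage.mode(x) <- "integer"
  x
}

# One masked-LM training step: loss, batch accuracy and all gradients.
mlm_training_step <- function(params, cfg, batch) {
  labels_flat <- as.integer(t(batch$mlm_labels))
  if (backend_cpp()) {
    labs <- labels_flat
    labs[is.na(labs)] <- -1L
    res <- .cpp_mlm_step(params, cfg_as_list(cfg),
                         as_int_matrix(batch$input_ids),
                         batch$attention_mask * 1.0, labs)
    list(loss = res$loss, accuracy = res$accuracy, grads = res$grads)
  } else {
    fwd <- encoder_forward(params, cfg, batch$input_ids,
                           batch$attention_mask,
                           dropout_rate = cfg$dropout)
    ho <- mlm_head_loss(params, fwd$H, labels_flat)
    grads <- encoder_backward(params, cfg, fwd, ho$dH)
    grads$mlm_W <- ho$dW
    grads$mlm_b <- ho$db
    list(loss = ho$loss, accuracy = ho$accuracy, grads = grads)
  }
}

# Final hidden states for inference (no dropout).
encoder_hidden_states <- function(params, cfg, ids, mask) {
  if (backend_cpp()) {
    .cpp_encoder_hidden(params, cfg_as_list(cfg), as_int_matrix(ids),
                        mask * 1.0)
  } else {
    encoder_forward(params, cfg, ids, mask, dropout_rate = 0)$H
  }
}

# ---- generic nested-list parameter utilities -------------------------------

map_params <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    keys <- if (is.null(names(a))) seq_along(a) else names(a)
    for (i in seq_along(a)) {
      out[[i]] <- map_params(f, a[[i]],
                             if (is.null(b)) NULL else b[[keys[i]]])
    }
    out
  } else if (is.null(b)) f(a) else f(a, b)
}

# Adam with linear warmup.  State holds first/second moments per parameter.
adam_init <- function(params) {
  list(m = map_params(function(x) x * 0, params),
       v = map_params(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, warmup = 100L, weight_decay = 0) {
  state$t <- state$t + 1L
  lr_t <- lr * min(1, state$t / max(1L, warmup))
  state$m <- map_params(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- map_params(function(v, g) beta2 * v + (1 - beta2) * g * g,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- map_params(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                    state$m, state$v)
  if (weight_decay > 0) {
    upd <- map_params(function(u, p) u + weight_decay * p, upd, params)
  }
  params <- map_params(function(p, u) p - lr_t * u, params, upd)
  list(params = params, state = state)
}
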