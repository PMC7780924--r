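# The encoder has two implementations: a pure-R reference and a compiled
# fast path.  These tests pin the reference to finite-difference gradients
# and the fast path to the reference.

pp <- asNamespace("protpath")

make_batch <- function(cfg, seqs = c("MKVLAWQQ", "ACDEFGH"), seed = 3) {
  docs <- lapply(seqs, tokenize, vocab = test_vocab, max_len = cfg$max_len)
  apply_mlm_masking(docs, test_vocab, max_len = cfg$max_len,
                    mask_rate = 0.3, seed = seed)
}

test_that("scaled dot-product attention obeys its contract", {
  Z <- matrix(0, 3, 4)
  at <- scaled_dot_attention(Z, Z, Z)
  expect_equal(at$output, Z)
  expect_equal(at$weights, matrix(1 / 3, 3, 3))  # softmax of zeros

  # a dominant key captures the output
  K <- rbind(c(50, 0), c(0, 50), c(-50, -50))
  V <- rbind(c(1, 2), c(3, 4), c(5, 6))
  at2 <- scaled_dot_attention(matrix(c(50, 0), 1), K, V)
  expect_equal(drop(at2$output), c(1, 2), tolerance = 1e-6)

  set.seed(2)
  Q <- matrix(rnorm(12), 3); K2 <- matrix(rnorm(20), 5)
  V2 <- matrix(rnorm(15), 5)
  expect_equal(rowSums(scaled_dot_attention(Q, K2, V2)$weights),
               rep(1, 3), tolerance = 1e-6)
  at3 <- scaled_dot_attention(Q, K2, V2, key_mask = c(TRUE, TRUE, FALSE,
                                                      TRUE, FALSE))
  expect_equal(unname(at3$weights[, c(3, 5)]), matrix(0, 3, 2))
  expect_equal(rowSums(at3$weights), rep(1, 3), tolerance = 1e-6)

  expect_error(scaled_dot_attention(matrix(0, 2, 3), matrix(0, 2, 4),
                                    matrix(0, 2, 4)), "width")
})

test_that("multi-head attention reduces to single-head and concatenation", {
  set.seed(5)
  d <- 6
  x <- matrix(rnorm(5 * d), 5, d)
  # h = 1 with explicit projections equals composed single attention
  params <- list(Wq = matrix(rnorm(d * d), d), Wk = matrix(rnorm(d * d), d),
                 Wv = matrix(rnorm(d * d), d), Wo = diag(d))
  out <- multi_head_attention(x, params, n_heads = 1)
  ref <- scaled_dot_attention(x %*% params$Wq, x %*% params$Wk,
                              x %*% params$Wv)$output
  expect_equal(out, ref, tolerance = 1e-12)
  expect_equal(dim(out), dim(x))

  # h = 2 with identity-partition projections equals the concatenation of
  # two independent half-dimension attentions
  I <- diag(d)
  params2 <- list(Wq = I, Wk = I, Wv = I, Wo = I)
  out2 <- multi_head_attention(x, params2, n_heads = 2)
  half1 <- scaled_dot_attention(x[, 1:3], x[, 1:3], x[, 1:3])$output
  half2 <- scaled_dot_attention(x[, 4:6], x[, 4:6], x[, 4:6])$output
  expect_equal(out2, cbind(half1, half2), tolerance = 1e-12)

  bad <- params
  bad$Wo <- diag(d + 1)
  expect_error(multi_head_attention(x, bad, n_heads = 1), "projection")
})

test_that("reference backward pass matches finite differences", {
  withr::local_options(protpath.backend = "R")
  set.seed(7)
  cfg <- unit_cfg()
  params <- pp$init_encoder_params(cfg)
  batch <- make_batch(cfg)
  labels_flat <- as.integer(t(batch$mlm_labels))

  loss_of <- function(p) {
    fwd <- pp$encoder_forward(p, cfg, batch$input_ids,
                              batch$attention_mask, 0)
    pp$mlm_head_loss(p, fwd$H, labels_flat)$loss
  }
  fwd <- pp$encoder_forward(params, cfg, batch$input_ids,
                            batch$attention_mask, 0)
  ho <- pp$mlm_head_loss(params, fwd$H, labels_flat)
  grads <- pp$encoder_backward(params, cfg, fwd, ho$dH)
  grads$mlm_W <- ho$dW
  grads$mlm_b <- ho$db

  eps <- 1e-5
  probe <- function(get, set, gref) {
    vals <- get(params)
    for (i in sample(length(vals), 3)) {
      v <- vals; v[i] <- v[i] + eps; up <- loss_of(set(params, v))
      v <- vals; v[i] <- v[i] - eps; dn <- loss_of(set(params, v))
      num <- (up - dn) / (2 * eps)
      expect_equal(gref[i], num, tolerance = 1e-4)
    }
  }
  probe(function(p) p$tok_emb, function(p, v) {p$tok_emb[] <- v; p},
        grads$tok_emb)
  probe(function(p) p$layers[[1]]$Wq,
        function(p, v) {p$layers[[1]]$Wq[] <- v; p}, grads$layers[[1]]$Wq)
  probe(function(p) p$layers[[1]]$Wo,
        function(p, v) {p$layers[[1]]$Wo[] <- v; p}, grads$layers[[1]]$Wo)
  probe(function(p) p$layers[[1]]$W1,
        function(p, v) {p$layers[[1]]$W1[] <- v; p}, grads$layers[[1]]$W1)
  probe(function(p) p$layers[[1]]$ln1_g,
        function(p, v) {p$layers[[1]]$ln1_g[] <- v; p},
        grads$layers[[1]]$ln1_g)
  probe(function(p) p$mlm_W, function(p, v) {p$mlm_W[] <- v; p},
        grads$mlm_W)
})

test_that("compiled fast path agrees with the reference implementation", {
  for (act in c("relu", "gelu")) {
    set.seed(17)
    cfg <- unit_cfg()
    cfg$activation <- act
    params <- pp$init_encoder_params(cfg)
    batch <- make_batch(cfg, c("MKVLAWQQ", "ACD"))  # includes padding

    r_res <- withr::with_options(list(protpath.backend = "R"),
                                 pp$mlm_training_step(params, cfg, batch))
    c_res <- pp$mlm_training_step(params, cfg, batch)
    expect_equal(c_res$loss, r_res$loss, tolerance = 1e-12)
    expect_equal(c_res$accuracy, r_res$accuracy)
    diffs <- unlist(pp$map_params(function(a, b) max(abs(a - b)),
                                  r_res$grads, c_res$grads))
    expect_lt(max(diffs), 1e-10)

    hR <- withr::with_options(list(protpath.backend = "R"),
      pp$encoder_hidden_states(params, cfg, batch$input_ids,
                               batch$attention_mask))
    hC <- pp$encoder_hidden_states(params, cfg, batch$input_ids,
                                   batch$attention_mask)
    expect_lt(max(abs(hR - hC)), 1e-12)
  }
})

test_that("hidden states and embeddings are invariant to trailing padding", {
  set.seed(21)
  cfg <- unit_cfg()
  params <- pp$init_encoder_params(cfg)
  doc <- tokenize("MKVLA", test_vocab, cfg$max_len)  # 7 tokens
  pad <- vocab_index(test_vocab, "[PAD]")
  pad_to <- function(n) {
    ids <- matrix(pad, 1, n)
    ids[1, seq_along(doc)] <- doc
    mask <- matrix(0, 1, n)
    mask[1, seq_along(doc)] <- 1
    pp$encoder_hidden_states(params, cfg, ids, mask)
  }
  h_short <- pad_to(length(doc))       # no padding at all
  h_long <- pad_to(cfg$max_len)        # padded to the full window
  expect_equal(h_short[seq_along(doc), ], h_long[seq_along(doc), ],
               tolerance = 1e-5)

  # pooled embeddings keep the configured dimension for any input length
  lm <- structure(list(params = params, config = cfg, vocab = test_vocab,
                       log = data.frame()), class = "protein_lm")
  e <- predict(lm, c("MKV", "ACDEFGHIKLMN"))
  expect_equal(dim(e), c(2L, cfg$hidden_dim))
  # mean pooling of a length-1 sequence averages its non-pad positions
  e3 <- predict(lm, "W", pooling = "mean")
  expect_length(e3, cfg$hidden_dim)
})

test_that("training is deterministic and the loss decreases on a grammar", {
  fam <- generate_family(family_spec(n_sequences = 80, length = 20,
                                     seed = 5))
  cfg <- unit_cfg(max_len = 24L)
  corpus <- tokenize_corpus(fam, test_vocab, max_len = cfg$max_len)
  lm1 <- protein_lm(corpus, cfg, steps = 120, batch_size = 8, seed = 9,
                    log_every = 10)
  lm2 <- protein_lm(corpus, cfg, steps = 120, batch_size = 8, seed = 9,
                    log_every = 10)
  expect_identical(lm1$log, lm2$log)  # bit-identical replay
  expect_identical(lm1$params$tok_emb, lm2$params$tok_emb)

  # smoothed masked-LM loss decreases over training
  half <- nrow(lm1$log) %/% 2
  expect_lt(mean(utils::tail(lm1$log$mlm_loss, half)),
            mean(utils::head(lm1$log$mlm_loss, half)))
})
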