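test_that("fusion concatenates in a fixed, documented order", {
  bert <- matrix(1:6 / 10, 2, 3)
  hydro <- matrix(7:10 / 10, 2, 2)
  full <- fuse(bert_emb = bert, hydro = hydro, variant = "full")
  expect_equal(dim(full), c(2L, 5L))
  expect_equal(unname(full[, 1:3]), unname(bert))   # LM block first
  expect_equal(unname(full[, 4:5]), unname(hydro))  # hydropathy second
  expect_equal(attr(full, "provenance"), "full")

  only <- fuse(bert_emb = bert, variant = "bert_only")
  expect_equal(unname(only[, ]), unname(bert))

  eh <- fuse(embed = hydro, hydro = bert, variant = "embed_hydro")
  expect_equal(dim(eh), c(2L, 5L))

  expect_error(fuse(hydro = hydro, variant = "full"), "requires")
  expect_error(fuse(bert_emb = bert, variant = "embed_hydro"), "requires")

  # default dimensions: 768-dim embedding + 256-dim hydropathy = 1024
  expect_equal(ncol(fuse(bert_emb = matrix(0, 1, 768),
                         hydro = matrix(0, 1, 256), variant = "full")),
               1024L)
})

test_that("MLP forward matches hand evaluation", {
  p0 <- list(W1 = matrix(0, 2, 3), b1 = numeric(3), w2 = numeric(3), b2 = 0)
  expect_equal(mlp_forward(c(1, -2), p0), 0.5)  # sigmoid(0)

  p <- list(W1 = matrix(c(1, 0), 2, 1), b1 = 0, w2 = 1, b2 = 0)
  expect_equal(mlp_forward(c(-3, 7), p), 0.5)   # sigmoid(ReLU(-3)) = 0.5
  expect_equal(mlp_forward(c(2, 7), p), 1 / (1 + exp(-2)))

  # monotone in the pre-sigmoid activation
  scores <- vapply(c(0.5, 1, 2, 4), function(w) {
    mlp_forward(c(2, 0), list(W1 = matrix(c(1, 0), 2, 1), b1 = 0,
                              w2 = w, b2 = 0))
  }, numeric(1))
  expect_true(all(diff(scores) > 0))

  expect_error(mlp_forward(c(NaN, 1), p), "NaN")
})

test_that("binary cross-entropy matches the closed form", {
  expect_lt(bce_loss(1, 1), 1e-10)
  expect_equal(bce_loss(0.5, 0), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(0.9, 0), -log(0.1), tolerance = 1e-12)
  expect_error(bce_loss(0.5, 2), "0 or 1")

  grid <- expand.grid(yhat = seq(0.01, 0.99, by = 0.07), y = c(0, 1))
  closed <- -(grid$y * log(grid$yhat) + (1 - grid$y) * log(1 - grid$yhat))
  expect_equal(bce_loss(grid$yhat, grid$y), closed, tolerance = 1e-9)
})

test_that("splits are stratified, disjoint, exhaustive and reproducible", {
  data <- data.frame(id = sprintf("m%03d", 1:100),
                     residues = "MKVLA",
                     label = rep(c(1L, 0L), c(20, 80)),
                     augmented = FALSE)
  s <- split_dataset(data, c(5, 4, 1), seed = 3)
  expect_equal(nrow(s$test), 10L)
  expect_equal(sum(s$test$label), 2L)     # 20% positives, as in the full set
  expect_equal(nrow(s$finetune), 50L)
  expect_equal(nrow(s$train), 40L)

  all_ids <- sort(c(s$finetune$id, s$train$id, s$test$id))
  expect_equal(all_ids, sort(data$id))    # partition: union is everything
  expect_equal(anyDuplicated(all_ids), 0L)

  s2 <- split_dataset(data, c(5, 4, 1), seed = 3)
  expect_identical(lapply(s, `[[`, "id"), lapply(s2, `[[`, "id"))

  one_class <- transform(data, label = 1L)
  expect_error(split_dataset(one_class), "both classes")
  tiny <- data[c(1:2, 21:60), ]
  expect_error(split_dataset(tiny), "at least 3")
})

test_that("augmented records can only land in the training partition", {
  data <- data.frame(id = sprintf("m%03d", 1:60), residues = "MKVLA",
                     label = rep(c(1L, 0L), c(15, 45)), augmented = FALSE)
  aug <- augment_mutation_set(data, "terminator_noise", copies = 2,
                              noise_tokens = 1, seed = 5)
  for (seed in 1:5) {
    s <- split_dataset(aug, c(5, 4, 1), seed = seed)
    expect_false(any(s$test$augmented))
    expect_false(any(s$finetune$augmented))
    expect_true(all(aug$id[aug$augmented] %in% s$train$id))
  }
})

test_that("the classifier learns a separable toy problem end to end", {
  set.seed(40)
  # two Gaussian blobs expressed directly as hydropathy-bearing sequences:
  # class 1 hydrophobic-rich, class 0 hydrophilic-rich
  make_seq <- function(class) {
    pool <- if (class == 1) c("I", "V", "L", "F") else c("R", "K", "D", "E")
    paste(c(sample(pool, 8, TRUE), sample(AMINO_ACIDS, 4, TRUE)),
          collapse = "")
  }
  n <- 60
  data <- data.frame(
    id = sprintf("t%03d", 1:n), residues = NA_character_,
    label = rep(c(1L, 0L), each = n / 2), augmented = FALSE)
  data$residues <- vapply(data$label, make_seq, character(1))

  cfg <- classifier_config(hidden_dim = 16L, epochs = 60L, seed = 2)
  fit <- fusion_classifier(data, encoder = NULL, variant = "embed_hydro",
                           config = cfg, d_hy = 14L)
  expect_s3_class(fit, "fusion_model")
  # learning sanity: later loss below the first epoch's
  expect_lt(fit$history$train_loss[50], fit$history$train_loss[1])
  expect_gte(fit$test_metrics$auroc, 0.9)

  preds <- predict(fit, data)
  expect_true(all(preds$score >= 0 & preds$score <= 1))
  expect_equal(preds$label, as.integer(preds$score >= 0.5))
  expect_equal(preds$id, data$id)                 # order preserved
  expect_identical(predict(fit, data), preds)     # deterministic

  # a score of 0.997 with the default threshold is called pathogenic
  thr_fit <- fit
  expect_equal(as.integer(0.997 >= thr_fit$config$threshold), 1L)

  one_class <- transform(data, label = 0L)
  expect_error(fusion_classifier(one_class, variant = "embed_hydro",
                                 config = cfg, d_hy = 14L), "both classes")
})

test_that("an untrained classifier scores at chance on balanced data", {
  set.seed(41)
  n <- 80
  data <- data.frame(
    id = sprintf("u%03d", 1:n),
    residues = vapply(1:n, function(i)
      paste(sample(AMINO_ACIDS, 12, TRUE), collapse = ""), character(1)),
    label = rep(c(0L, 1L), n / 2), augmented = FALSE)
  cfg <- classifier_config(hidden_dim = 8L, epochs = 0L, seed = 3)
  fit <- fusion_classifier(data, variant = "embed_hydro", config = cfg,
                           d_hy = 12L)
  expect_gt(fit$test_metrics$auroc, 0.15)
  expect_lt(fit$test_metrics$auroc, 0.85)
})

test_that("fine-tune mode adapts the encoder on the fine-tuning split", {
  fam <- generate_family(family_spec(n_sequences = 40, length = 20,
                                     seed = 14))
  cfg <- unit_cfg(max_len = 24L)
  corpus <- tokenize_corpus(fam, test_vocab, max_len = cfg$max_len)
  lm <- protein_lm(corpus, cfg, steps = 30, batch_size = 8, seed = 1)
  muts <- generate_mutation_set(fam, mutation_set_spec(
    n_benign = 45, n_pathogenic = 15, seed = 15))
  ccfg <- classifier_config(hidden_dim = 8L, epochs = 20L,
                            mode = "fine_tune", finetune_steps = 10L,
                            seed = 4)
  fit <- fusion_classifier(muts, encoder = lm, variant = "full",
                           config = ccfg)
  # the fitted model carries an encoder whose weights moved
  expect_false(identical(fit$encoder$params$tok_emb, lm$params$tok_emb))
  expect_true(all(predict(fit, muts[1:4, ])$score >= 0))
  expect_error(fusion_classifier(muts, encoder = NULL, variant = "full",
                                 config = ccfg), "encoder")
})

test_that("training-order permutations leave the test AUROC stable", {
  set.seed(42)
  fam <- generate_family(family_spec(n_sequences = 10, length = 30,
                                     seed = 12))
  muts <- generate_mutation_set(fam, mutation_set_spec(
    n_benign = 60, n_pathogenic = 20, seed = 13))
  cfg <- classifier_config(hidden_dim = 16L, epochs = 80L, seed = 6)
  splits <- split_dataset(muts, c(5, 4, 1), seed = 6)
  base_fit <- fusion_classifier(muts, variant = "embed_hydro",
                                config = cfg, splits = splits, d_hy = 30L)
  for (k in 1:3) {
    perm <- splits
    perm$train <- perm$train[sample(nrow(perm$train)), ]
    fit_k <- fusion_classifier(muts, variant = "embed_hydro", config = cfg,
                               splits = perm, d_hy = 30L)
    expect_lt(abs(fit_k$test_metrics$auroc - base_fit$test_metrics$auroc),
              0.15)
  }
})
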