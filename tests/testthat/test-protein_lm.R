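pp <- asNamespace("protpath")

test_that("masking selects the right number of content positions", {
  v <- test_vocab
  doc <- tokenize(paste(rep("ACDEF", 4), collapse = ""), v, 30)  # 20 AA
  b <- apply_mlm_masking(list(doc), v, max_len = 30, mask_rate = 0.15,
                         seed = 1)
  expect_equal(sum(!is.na(b$mlm_labels)), 3L)  # round(0.15 * 20), min 1

  b0 <- apply_mlm_masking(list(doc), v, max_len = 30, mask_rate = 0.001,
                          seed = 1)
  expect_equal(sum(!is.na(b0$mlm_labels)), 1L)  # min-1 rule

  # special positions are never selected, labels hold original ids
  sel <- which(!is.na(b$mlm_labels[1, ]))
  expect_true(all(doc[sel] >= 5L))
  expect_equal(b$mlm_labels[1, sel], doc[sel])
  # attention mask marks exactly the real tokens
  expect_equal(sum(b$attention_mask), length(doc))
})

test_that("masking is reproducible and validates its input", {
  v <- test_vocab
  docs <- lapply(c("MKVLAWII", "ACDEFGHK"), tokenize, vocab = v,
                 max_len = 16)
  b1 <- apply_mlm_masking(docs, v, 16, seed = 42)
  b2 <- apply_mlm_masking(docs, v, 16, seed = 42)
  expect_identical(b1, b2)

  masked_doc <- c(vocab_index(v, "[CLS]"), vocab_index(v, "[MASK]"),
                  vocab_index(v, "[SEP]"))
  expect_error(apply_mlm_masking(list(masked_doc), v, 16), "MASK")
  empty_doc <- c(vocab_index(v, "[CLS]"), vocab_index(v, "[SEP]"))
  expect_error(apply_mlm_masking(list(empty_doc), v, 16), "eligible")
})

test_that("masking applies the 80/10/10 replacement recipe", {
  v <- test_vocab
  long <- paste(sample(AMINO_ACIDS, 400, replace = TRUE), collapse = "")
  docs <- lapply(seq_len(40), function(i)
    tokenize(substr(long, 1, 58), v, 60))
  b <- apply_mlm_masking(docs, v, 60, mask_rate = 0.15, seed = 8)
  sel <- !is.na(b$mlm_labels)
  replaced <- b$input_ids[sel]
  original <- b$mlm_labels[sel]
  frac_mask <- mean(replaced == pp$special_id(v, "mask"))
  frac_keep <- mean(replaced == original)
  expect_gt(frac_mask, 0.65); expect_lt(frac_mask, 0.92)
  expect_gt(frac_keep, 0.03); expect_lt(frac_keep, 0.22)
})

test_that("masked accuracy counts argmax hits over labeled positions", {
  expect_equal(masked_accuracy(c(3L, 7L), c(3L, 7L)), 1)
  expect_equal(masked_accuracy(c(3L, 7L, 1L, 2L), c(3L, 7L, 1L, 9L)), 0.75)
  expect_error(masked_accuracy(matrix(0, 1, 3), NA_integer_), "labeled")

  # hand-counted 10-position case against the matrix interface
  set.seed(3)
  logits <- matrix(rnorm(10 * 6), 10, 6)
  labels <- sample(0:5, 10, replace = TRUE)
  hand <- sum(vapply(1:10, function(i)
    which.max(logits[i, ]) - 1L == labels[i], logical(1))) / 10
  expect_equal(masked_accuracy(logits, labels), hand)
})

test_that("pretraining validates corpus and batch geometry", {
  cfg <- unit_cfg()
  empty <- structure(list(documents = list(), source_ids = character(),
                          vocab = test_vocab), class = "pp_corpus")
  expect_error(protein_lm(empty, cfg, steps = 5), "empty")
  small <- tokenize_corpus(c("MKV", "ACD"), test_vocab, cfg$max_len)
  expect_error(protein_lm(small, cfg, steps = 5, batch_size = 16),
               "smaller batch")
})

test_that("an untrained encoder predicts masked tokens at chance level", {
  set.seed(31)
  cfg <- unit_cfg(max_len = 24L)
  lm <- structure(list(params = pp$init_encoder_params(cfg), config = cfg,
                       vocab = test_vocab, log = data.frame()),
                  class = "protein_lm")
  fam <- generate_family(family_spec(n_sequences = 60, length = 20,
                                     seed = 6))
  corpus <- tokenize_corpus(fam, test_vocab, max_len = cfg$max_len)
  acc <- evaluate_mlm(lm, corpus, seed = 2)
  expect_lt(acc, 0.25)  # ~1/20 at chance; generous bound
})

test_that("default base profile processes 4096 tokens per iteration", {
  cfg <- encoder_profile("base")
  batch_size <- 16L
  expect_equal(cfg$max_len * batch_size, 4096L)
  expect_equal(cfg$hidden_dim, 768L)
  expect_equal(cfg$num_layers, 12L)
  expect_equal(cfg$num_heads, 12L)
})

test_that("encoder config enforces its shape constraints", {
  expect_error(encoder_config(hidden_dim = 10L, num_heads = 3L),
               "divisible")
  expect_error(encoder_config(mask_rate = 0), "mask_rate")
  cfg <- encoder_config(num_layers = 2L, hidden_dim = 8L, num_heads = 2L)
  expect_s3_class(cfg, "pp_encoder_config")
})

test_that("checkpoints round-trip and training logs are written", {
  fam <- generate_family(family_spec(n_sequences = 40, length = 15,
                                     seed = 3))
  cfg <- unit_cfg(max_len = 18L)
  corpus <- tokenize_corpus(fam, test_vocab, max_len = cfg$max_len)
  lm <- protein_lm(corpus, cfg, steps = 10, batch_size = 8, seed = 4)
  ck <- tempfile(fileext = ".rds")
  save_encoder(lm, ck)
  lm2 <- load_encoder(ck)
  expect_identical(lm2$params, lm$params)
  expect_equal(predict(lm2, "MKVLA"), predict(lm, "MKVLA"))
  expect_error(load_encoder(system.file("extdata", "kyte_doolittle.tsv",
                                        package = "protpath")))

  log_tsv <- tempfile(fileext = ".tsv")
  write_training_log(lm, log_tsv)
  log <- utils::read.delim(log_tsv)
  expect_named(log, c("step", "mlm_loss", "masked_accuracy"))

  expect_error(predict(lm, paste(rep("A", 40), collapse = "")), NA)
  expect_output(print(lm), "language model")
})
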