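# Shared fixtures.  The desk-scale pre-trained language model is expensive
# (~2 min) and is built lazily, once per test run, for the tests that need
# a trained encoder.

`%||%` <- function(a, b) if (is.null(a)) b else a

test_vocab <- build_vocabulary()

# A deliberately small encoder configuration for fast unit tests.
unit_cfg <- function(...) {
  args <- utils::modifyList(
    list(num_layers = 1L, hidden_dim = 16L, num_heads = 2L,
         ff_dim = 32L, max_len = 16L, dropout = 0,
         vocab_size = test_vocab$size, activation = "relu"),
    list(...))
  do.call(encoder_config, args)
}

.fixture_env <- new.env(parent = emptyenv())

# Synthetic conserved-family corpus at the generator's default study
# conditions, split into training and held-out members.
fixture_family <- function() {
  if (is.null(.fixture_env$family)) {
    .fixture_env$family <- generate_family(
      family_spec(n_sequences = 600L, seed = 11L))
  }
  .fixture_env$family
}

# Tiny-profile encoder pre-trained 2000 steps on 500 family sequences.
fixture_lm <- function() {
  if (is.null(.fixture_env$lm)) {
    fam <- fixture_family()
    cfg <- encoder_profile("tiny", vocab_size = test_vocab$size)
    corpus <- tokenize_corpus(fam[1:500, ], test_vocab,
                              max_len = cfg$max_len)
    .fixture_env$lm <- protein_lm(corpus, cfg, steps = 2000L,
                                  batch_size = 16L, seed = 22L)
  }
  .fixture_env$lm
}

fixture_heldout_corpus <- function() {
  fam <- fixture_family()
  cfg <- encoder_profile("tiny", vocab_size = test_vocab$size)
  tokenize_corpus(fam[501:600, ], test_vocab, max_len = cfg$max_len)
}

write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
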