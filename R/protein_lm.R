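# Masked-language-model pre-training of the protein sequence encoder, and
# the user-facing attention primitives.

#' Encoder configuration
#'
#' Architecture and training hyper-parameters of the bidirectional
#' transformer encoder.  The `"base"` profile is the standard
#' 12-layer/768-hidden/12-head configuration with maximum input length
#' 256, giving 256 x 16 = 4096 tokens per iteration at the default batch
#' size; the `"tiny"` profile (2 layers, 64 hidden, 4 heads, length 64)
#' is a desk-scale model that trains in minutes on one CPU.
#'
#' @param num_layers Number of transformer blocks.
#' @param hidden_dim Model width `d_model`; also the embedding dimension.
#' @param num_heads Attention heads; must divide `hidden_dim` (per-head
#'   key/query/value width is `hidden_dim / num_heads`).
#' @param ff_dim Feed-forward inner width (default `4 * hidden_dim`).
#' @param max_len Maximum tokenized sequence length `L`, including the
#'   start/end framing tokens.
#' @param dropout Dropout probability applied during pre-training.
#' @param mask_rate Fraction of eligible positions selected for the
#'   masked-LM objective (canonical recipe: 0.15 with 80/10/10
#'   mask/random/keep replacement).
#' @param vocab_size Vocabulary size (from [build_vocabulary()]).
#' @param pooling Default sequence pooling: `"cls"` (hidden state at the
#'   start token) or `"mean"` (mean over non-pad positions).
#' @param activation Feed-forward activation: `"gelu"` (the reference
#'   architecture's choice, default) or `"relu"` (used by the tiny
#'   profile; transcendental-free, which matters for CPU training).
#' @return An object of class `pp_encoder_config`.
#' @export
encoder_config <- function(num_layers = 12L, hidden_dim = 768L,
                           num_heads = 12L, ff_dim = 4L * hidden_dim,
                           max_len = 256L, dropout = 0.1,
                           mask_rate = 0.15,
                           vocab_size = build_vocabulary()$size,
                           pooling = c("cls", "mean"),
                           activation = c("gelu", "relu")) {
  pooling <- match.arg(pooling)
  activation <- match.arg(activation)
  stopifnot(num_layers >= 1L, hidden_dim >= 1L, num_heads >= 1L,
            max_len >= 3L, mask_rate > 0, mask_rate < 1,
            dropout >= 0, dropout < 1)
  if (hidden_dim %% num_heads != 0L) {
    stop("hidden_dim (", hidden_dim, ") must be divisible by num_heads (",
         num_heads, ")")
  }
  structure(list(num_layers = as.integer(num_layers),
                 hidden_dim = as.integer(hidden_dim),
                 num_heads = as.integer(num_heads),
                 ff_dim = as.integer(ff_dim),
                 max_len = as.integer(max_len),
                 dropout = dropout, mask_rate = mask_rate,
                 vocab_size = as.integer(vocab_size),
                 pooling = pooling, activation = activation),
            class = "pp_encoder_config")
}

#' @rdname encoder_config
#' @param profile `"base"` or `"tiny"`.
#' @param ... Overrides passed to [encoder_config()].
#' @export
encoder_profile <- function(profile = c("base", "tiny"), ...) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
    base = list(num_layers = 12L, hidden_dim = 768L, num_heads = 12L,
                ff_dim = 3072L, max_len = 256L, dropout = 0.1),
    tiny = list(num_layers = 2L, hidden_dim = 64L, num_heads = 4L,
                ff_dim = 256L, max_len = 64L, dropout = 0,
                activation = "relu"))
  do.call(encoder_config, utils::modifyList(defaults, list(...)))
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`, with optionally masked key positions
#' receiving effectively `-Inf` logits so every attention row is a
#' probability distribution over the unmasked keys.
#'
#' @param Q,K,V Numeric matrices; `Q` and `K` share the inner width
#'   `d_k`, `K` and `V` share their number of rows.
#' @param key_mask Optional logical vector over key rows (`TRUE` = keep).
#' @return List with `output` (`nrow(Q) x ncol(V)`) and `weights` (the
#'   attention matrix, rows summing to 1).
#' @export
scaled_dot_attention <- function(Q, K, V, key_mask = NULL) {
  at <- sdp_attention(Q, K, V, key_mask)
  list(output = at$O, weights = at$A)
}

#' Multi-head self-attention
#'
#' Projects the input through packed per-head query/key/value maps, runs
#' scaled dot-product attention per head, concatenates the heads and
#' applies the output projection:
#' `Concat(head_1, ..., head_h) W_O` with
#' `head_i = Attention(x W_Q[i], x W_K[i], x W_V[i])`.
#'
#' @param x Numeric matrix, one row per position, width `d_model`.
#' @param params List with matrices `Wq`, `Wk`, `Wv` (`d_model x d_model`,
#'   heads packed column-wise), `Wo` (`h * d_v x d_model`), and optional
#'   bias vectors `bq`, `bk`, `bv`, `bo`.
#' @param n_heads Number of heads; must divide the projection width.
#' @param key_mask Optional logical vector over positions.
#' @return Numeric matrix of the same shape as `x`.
#' @export
multi_head_attention <- function(x, params, n_heads, key_mask = NULL) {
  d <- ncol(x)
  if (ncol(params$Wq) %% n_heads != 0L) {
    stop("projection width ", ncol(params$Wq),
         " not divisible by n_heads ", n_heads)
  }
  if (nrow(params$Wo) != ncol(params$Wv)) {
    stop("output projection expects ", nrow(params$Wo),
         " inputs but heads produce ", ncol(params$Wv))
  }
  lp <- list(Wq = params$Wq, Wk = params$Wk, Wv = params$Wv, Wo = params$Wo,
             bq = params$bq %||% numeric(ncol(params$Wq)),
             bk = params$bk %||% numeric(ncol(params$Wk)),
             bv = params$bv %||% numeric(ncol(params$Wv)),
             bo = params$bo %||% numeric(ncol(params$Wo)))
  mha_forward(x, lp, n_heads, key_mask)$out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply masked-LM masking to a batch of token sequences
#'
#' Selects `round(mask_rate * n_eligible)` positions (at least one) per
#' sequence among the content tokens (special and padding tokens are
#' never selected).  Each selected position is replaced by `[MASK]` with
#' probability 0.8, by a random amino-acid token with probability 0.1,
#' and kept unchanged with probability 0.1; the original token id is
#' recorded as the prediction label.
#'
#' @param docs List of 0-based token-id vectors (or a `pp_corpus`).
#' @param vocab The `pp_vocabulary` the ids refer to.
#' @param max_len Padded batch width.
#' @param mask_rate Selection probability (default 0.15).
#' @param seed Optional integer seed for reproducible masking.
#' @return An object of class `pp_mlm_batch`: list of `input_ids`,
#'   `attention_mask` and `mlm_labels`, all `B x max_len` matrices;
#'   `mlm_labels` is `NA` at unselected positions.
#' @export
apply_mlm_masking <- function(docs, vocab, max_len, mask_rate = 0.15,
                              seed = NULL) {
  if (inherits(docs, "pp_corpus")) docs <- docs$documents
  if (!is.null(seed)) set.seed(seed)
  B <- length(docs)
  pad <- special_id(vocab, "pad")
  mask_id <- special_id(vocab, "mask")
  n_special <- length(SPECIAL_TOKENS)
  aa_ids <- vocab_index(vocab, AMINO_ACIDS)
  input_ids <- matrix(pad, B, max_len)
  attention_mask <- matrix(0, B, max_len)
  mlm_labels <- matrix(NA_integer_, B, max_len)
  for (b in seq_len(B)) {
    ids <- docs[[b]]
    if (length(ids) > max_len) stop("document ", b, " longer than max_len")
    if (any(ids == mask_id)) stop("document ", b, " already contains [MASK]")
    n <- length(ids)
    input_ids[b, seq_len(n)] <- ids
    attention_mask[b, seq_len(n)] <- 1
    eligible <- which(ids >= n_special)   # content tokens only
    if (length(eligible) == 0L) {
      stop("document ", b, " has no eligible (content) positions to mask")
    }
    n_sel <- max(1L, round(mask_rate * length(eligible)))
    sel <- if (length(eligible) == 1L) eligible else
      sample(eligible, n_sel)
    mlm_labels[b, sel] <- ids[sel]
    u <- stats::runif(length(sel))
    repl <- ids[sel]
    repl[u < 0.8] <- mask_id
    rnd <- u >= 0.8 & u < 0.9
    if (any(rnd)) repl[rnd] <- sample(aa_ids, sum(rnd), replace = TRUE)
    input_ids[b, sel] <- repl
  }
  structure(list(input_ids = input_ids, attention_mask = attention_mask,
                 mlm_labels = mlm_labels),
            class = "pp_mlm_batch")
}

#' Masked-token prediction accuracy
#'
#' Fraction of labeled (masked) positions whose predicted token equals
#' the original token.
#'
#' @param predictions Either a matrix of logits/probabilities with one
#'   row per labeled position (argmax is taken), or a vector of 0-based
#'   predicted token ids.
#' @param labels Vector of 0-based original token ids (`NA` entries are
#'   dropped).
#' @return Accuracy in `[0, 1]`.
#' @export
masked_accuracy <- function(predictions, labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0L) stop("no labeled positions")
  pred_ids <- if (is.matrix(predictions)) {
    max.col(predictions, ties.method = "first") - 1L
  } else {
    as.integer(predictions)
  }
  if (length(pred_ids) != length(labels)) {
    stop("got ", length(pred_ids), " predictions for ", length(labels),
         " labeled positions")
  }
  mean(pred_ids == labels)
}

#' Pre-train the protein language model
#'
#' Trains a bidirectional transformer encoder from scratch with the
#' masked-language-model objective: cross-entropy over the masked
#' positions only.  Optimisation is Adam with linear learning-rate
#' warmup.  Tokens processed per iteration equal
#' `max_len * batch_size` (4096 for the base profile at batch 16).
#'
#' @param corpus A `pp_corpus` from [tokenize_corpus()].
#' @param config A `pp_encoder_config`.
#' @param steps Number of optimizer steps.
#' @param batch_size Sequences per step.
#' @param lr Peak learning rate.
#' @param warmup Linear warmup steps.
#' @param seed Integer seed; the full run is reproducible from it.
#' @param init Optional `protein_lm` object to continue training from
#'   (e.g. domain adaptation of an already pre-trained encoder).
#' @param log_every Record batch loss/accuracy every this many steps.
#' @param verbose Print progress lines.
#' @return An object of class `protein_lm`: list with `params`, `config`,
#'   `vocab`, and `log` (data.frame `step`, `mlm_loss`,
#'   `masked_accuracy`).
#' @export
protein_lm <- function(corpus, config = encoder_profile("tiny"),
                       steps = 1000L, batch_size = 16L, lr = 1e-3,
                       warmup = 100L, seed = 1L, init = NULL,
                       log_every = 50L, verbose = FALSE) {
  stopifnot(inherits(corpus, "pp_corpus"), steps >= 1L)
  n_docs <- length(corpus$documents)
  if (n_docs == 0L) stop("empty corpus")
  if (n_docs < batch_size) {
    stop("corpus has ", n_docs, " documents < batch_size ", batch_size,
         "; use a smaller batch")
  }
  if (max(lengths(corpus$documents)) > config$max_len) {
    stop("corpus contains documents longer than config max_len ",
         config$max_len, "; re-tokenize with this limit")
  }
  set.seed(seed)
  params <- if (is.null(init)) init_encoder_params(config) else init$params
  state <- adam_init(params)
  ord <- sample.int(n_docs)
  pos <- 1L
  log_steps <- integer(0); log_loss <- numeric(0); log_acc <- numeric(0)
  for (step in seq_len(steps)) {
    if (pos + batch_size - 1L > n_docs) {
      ord <- sample.int(n_docs)
      pos <- 1L
    }
    take <- ord[pos:(pos + batch_size - 1L)]
    pos <- pos + batch_size
    batch <- apply_mlm_masking(corpus$documents[take], corpus$vocab,
                               max_len = config$max_len,
                               mask_rate = config$mask_rate)
    head_out <- mlm_training_step(params, config, batch)
    res <- adam_step(params, head_out$grads, state, lr = lr, warmup = warmup)
    params <- res$params
    state <- res$state
    if (step %% log_every == 0L || step == steps || step == 1L) {
      log_steps <- c(log_steps, step)
      log_loss <- c(log_loss, head_out$loss)
      log_acc <- c(log_acc, head_out$accuracy)
      if (verbose) {
        message(sprintf("step %d  mlm_loss %.4f  masked_acc %.3f",
                        step, head_out$loss, head_out$accuracy))
      }
    }
  }
  structure(list(params = params, config = config, vocab = corpus$vocab,
                 log = data.frame(step = log_steps, mlm_loss = log_loss,
                                  masked_accuracy = log_acc),
                 seed = seed, steps = steps, batch_size = batch_size),
            class = "protein_lm")
}

#' @export
print.protein_lm <- function(x, ...) {
  cfg <- x$config
  cat("Protein language model (masked-LM transformer encoder)\n")
  cat(sprintf("  %d layers, %d hidden, %d heads, max length %d, vocab %d\n",
              cfg$num_layers, cfg$hidden_dim, cfg$num_heads, cfg$max_len,
              cfg$vocab_size))
  n <- nrow(x$log)
  if (n > 0) {
    cat(sprintf("  trained %d steps; final batch mlm_loss %.4f, masked accuracy %.3f\n",
                x$steps, x$log$mlm_loss[n], x$log$masked_accuracy[n]))
  }
  invisible(x)
}

# Forward a padded id matrix through a trained model (no dropout).
lm_hidden_states <- function(model, input_ids, attention_mask) {
  encoder_hidden_states(model$params, model$config, input_ids,
                        attention_mask)
}

#' Embed sequences with a trained language model
#'
#' Runs sequences through the encoder and pools the final hidden states
#' into one fixed-dimension vector per sequence: `"cls"` pooling takes
#' the hidden state at the start token, `"mean"` averages over non-pad
#' positions.  The embedding dimension equals the configured hidden
#' width regardless of sequence length.
#'
#' @param object A `protein_lm`.
#' @param newdata Character vector of cleaned residue strings, a
#'   `data.frame` with a `residues` column, or a `pp_corpus`.
#' @param type `"embedding"` (default) or `"mlm"`, which returns
#'   masked-token logits for a `pp_mlm_batch` supplied as `newdata`.
#' @param pooling Override the configured pooling.
#' @param ... Unused.
#' @return For `type = "embedding"`, a numeric matrix with one row per
#'   sequence and `hidden_dim` columns.  For `type = "mlm"`, a list with
#'   `logits` (labeled positions x vocab) and `labels`.
#' @export
predict.protein_lm <- function(object, newdata, type = c("embedding", "mlm"),
                               pooling = NULL, ...) {
  type <- match.arg(type)
  cfg <- object$config
  if (type == "mlm") {
    stopifnot(inherits(newdata, "pp_mlm_batch"))
    H <- lm_hidden_states(object, newdata$input_ids,
                          newdata$attention_mask)
    labels_flat <- as.integer(t(newdata$mlm_labels))
    lab_rows <- which(!is.na(labels_flat))
    logits <- H[lab_rows, , drop = FALSE] %*% object$params$mlm_W +
      rep(object$params$mlm_b, each = length(lab_rows))
    return(list(logits = logits, labels = labels_flat[lab_rows]))
  }
  pooling <- pooling %||% cfg$pooling
  docs <- if (inherits(newdata, "pp_corpus")) {
    newdata$documents
  } else {
    residues <- if (is.data.frame(newdata)) newdata$residues else newdata
    lapply(residues, tokenize, vocab = object$vocab, max_len = cfg$max_len)
  }
  too_long <- lengths(docs) > cfg$max_len
  if (any(too_long)) {
    stop(sum(too_long), " sequence(s) exceed max_len ", cfg$max_len,
         "; truncate upstream (tokenize with this limit)")
  }
  pad <- special_id(object$vocab, "pad")
  B <- length(docs)
  ids <- matrix(pad, B, cfg$max_len)
  am <- matrix(0, B, cfg$max_len)
  for (b in seq_len(B)) {
    n <- length(docs[[b]])
    ids[b, seq_len(n)] <- docs[[b]]
    am[b, seq_len(n)] <- 1
  }
  Hall <- lm_hidden_states(object, ids, am)
  out <- matrix(0, B, cfg$hidden_dim)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * cfg$max_len + 1L):(b * cfg$max_len)
    H <- Hall[rows, , drop = FALSE]
    out[b, ] <- if (pooling == "cls") H[1L, ] else
      colMeans(H[am[b, ] == 1, , drop = FALSE])
  }
  out
}

#' Masked-token accuracy of a model on held-out sequences
#'
#' Applies the masking procedure to the given corpus with a fixed seed
#' and scores the model's masked-token predictions.
#'
#' @param model A `protein_lm`.
#' @param corpus A `pp_corpus` of held-out sequences.
#' @param seed Seed for the masking draw.
#' @param batch_size Sequences per forward batch.
#' @return Masked-token accuracy in `[0, 1]`.
#' @export
evaluate_mlm <- function(model, corpus, seed = 1L, batch_size = 32L) {
  stopifnot(inherits(corpus, "pp_corpus"))
  set.seed(seed)
  docs <- corpus$documents
  n <- length(docs)
  correct <- 0L; total <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    batch <- apply_mlm_masking(docs[idx], corpus$vocab,
                               max_len = model$config$max_len,
                               mask_rate = model$config$mask_rate)
    pred <- predict(model, batch, type = "mlm")
    hit <- max.col(pred$logits, ties.method = "first") - 1L == pred$labels
    correct <- correct + sum(hit)
    total <- total + length(hit)
  }
  correct / total
}

#' Save / load an encoder checkpoint
#'
#' Single-file checkpoint with a versioned header recording the format,
#' package version, and configuration.
#'
#' @param model A `protein_lm`.
#' @param path Destination file.
#' @export
save_encoder <- function(model, path) {
  stopifnot(inherits(model, "protein_lm"))
  payload <- list(format = "protpath-encoder", format_version = 1L,
                  package_version = as.character(utils::packageVersion("protpath")),
                  model = unclass(model))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "protpath-encoder")) {
    stop("not a protpath encoder checkpoint: ", path)
  }
  structure(payload$model, class = "protein_lm")
}

#' Write the training log as TSV
#'
#' @param model A `protein_lm`.
#' @param path Destination TSV (columns step, mlm_loss, masked_accuracy).
#' @export
write_training_log <- function(model, path) {
  utils::write.table(model$log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
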