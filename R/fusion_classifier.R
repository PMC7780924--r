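# Fusion of language-model embeddings with hydropathy encodings, and the
# one-hidden-layer MLP pathogenicity classifier.

#' Classifier configuration
#'
#' Training hyper-parameters of the fusion MLP: Adam with learning rate
#' 0.001, weight decay 0.005 (applied as an L2 term), 300 epochs.
#'
#' @param hidden_dim Width of the single ReLU hidden layer.
#' @param epochs Training epochs (full-batch).
#' @param learning_rate Adam learning rate.
#' @param weight_decay L2 penalty coefficient.
#' @param threshold Decision threshold on the predicted probability.
#' @param mode `"feature_based"` (encoder frozen) or `"fine_tune"` (the
#'   encoder is first adapted to the mutation sequences by continued
#'   masked-LM training on the fine-tuning split, then used for feature
#'   extraction).
#' @param finetune_steps Masked-LM adaptation steps in `"fine_tune"` mode.
#' @param seed Integer seed covering the split, initialisation and
#'   training.
#' @return An object of class `pp_classifier_config`.
#' @export
classifier_config <- function(hidden_dim = 512L, epochs = 300L,
                              learning_rate = 0.001, weight_decay = 0.005,
                              threshold = 0.5,
                              mode = c("feature_based", "fine_tune"),
                              finetune_steps = 200L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(hidden_dim >= 1L, epochs >= 0L, learning_rate > 0,
            weight_decay >= 0, threshold > 0, threshold < 1)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay, threshold = threshold,
                 mode = mode, finetune_steps = as.integer(finetune_steps),
                 seed = as.integer(seed)),
            class = "pp_classifier_config")
}

#' Concatenate sequence representations
#'
#' Deterministic fusion of per-sequence representations: the language
#' model embedding always comes first, the hydropathy vector second.
#' The `"bert_only"` variant passes the embedding through unchanged; the
#' `"embed_hydro"` variant uses a plain (non-pre-trained) embedding-layer
#' representation in place of the language model.
#'
#' @param bert_emb Language-model embedding (numeric vector or matrix,
#'   rows = sequences).
#' @param hydro Hydropathy vector/matrix.
#' @param embed Embedding-layer representation (for `"embed_hydro"`).
#' @param variant `"full"`, `"bert_only"`, or `"embed_hydro"`.
#' @return Fused numeric vector/matrix with attribute `provenance`.
#' @export
fuse <- function(bert_emb = NULL, hydro = NULL, embed = NULL,
                 variant = c("full", "bert_only", "embed_hydro")) {
  variant <- match.arg(variant)
  need <- function(x, what) {
    if (is.null(x)) stop("variant '", variant, "' requires ", what)
    if (is.vector(x)) matrix(x, nrow = 1) else x
  }
  out <- switch(variant,
    full = cbind(need(bert_emb, "the language-model embedding"),
                 need(hydro, "the hydropathy vector")),
    bert_only = need(bert_emb, "the language-model embedding"),
    embed_hydro = cbind(need(embed, "an embedding-layer representation"),
                        need(hydro, "the hydropathy vector")))
  attr(out, "provenance") <- variant
  out
}

#' MLP forward pass
#'
#' `h = ReLU(W1 x + b1)`, `yhat = sigmoid(w2 . h + b2)`.
#'
#' @param x Feature vector or matrix (rows = samples).
#' @param params List with `W1` (`p x hidden`), `b1`, `w2` (`hidden`),
#'   `b2` (scalar).
#' @return Predicted probabilities in `(0, 1)`.
#' @export
mlp_forward <- function(x, params) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (anyNA(x) || any(is.nan(x))) stop("NaN/NA in classifier input")
  H <- pmax(x %*% params$W1 + rep(params$b1, each = nrow(x)), 0)
  z <- drop(H %*% params$w2) + params$b2
  1 / (1 + exp(-z))
}

#' Binary cross-entropy loss
#'
#' `-(y log yhat + (1 - y) log(1 - yhat))`, with `yhat` clipped to
#' `[eps, 1 - eps]` for numerical safety.
#'
#' @param yhat Predicted probabilities.
#' @param y True labels in `{0, 1}`.
#' @param eps Clipping bound.
#' @return Non-negative loss, elementwise (vectorized).
#' @export
bce_loss <- function(yhat, y, eps = 1e-12) {
  if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1")
  yhat <- pmin(pmax(yhat, eps), 1 - eps)
  -(y * log(yhat) + (1 - y) * log(1 - yhat))
}

#' Split a labeled mutation set into fine-tuning / training / test
#'
#' The test partition is stratified so both classes appear in the same
#' proportion as in the full (non-augmented) set; the remainder is split
#' between the fine-tuning and training partitions.  Partition sizes
#' follow largest-remainder rounding with test-first tie-breaking.
#' Augmented records (rows with `augmented = TRUE`) are assigned to the
#' training partition only, so noise sequences can never contaminate the
#' test set.
#'
#' @param data Labeled `data.frame` (`id`, `residues`, `label`, optional
#'   `augmented`).
#' @param ratio Numeric triple fine-tune : train : test, default `5:4:1`.
#' @param seed Integer seed; the same seed reproduces the partition.
#' @return List of three `data.frame`s: `finetune`, `train`, `test`.
#' @export
split_dataset <- function(data, ratio = c(5, 4, 1), seed = 1L) {
  stopifnot(length(ratio) == 3L, all(ratio >= 0), sum(ratio) > 0,
            all(c("label") %in% names(data)))
  if (is.null(data$augmented)) data$augmented <- FALSE
  real <- which(!data$augmented)
  labs <- data$label[real]
  if (length(unique(labs)) < 2L) stop("both classes must be present")
  counts <- table(labs)
  if (any(counts < 3L)) {
    stop("each class needs at least 3 non-augmented members")
  }
  set.seed(seed)
  part <- character(nrow(data))
  part[data$augmented] <- "train"
  # priority for remainder allocation and tie-breaks: test, then finetune
  parts <- c("finetune", "train", "test")
  priority <- c(finetune = 2L, train = 3L, test = 1L)
  for (cl in names(counts)) {
    idx <- real[labs == cl]
    idx <- idx[sample.int(length(idx))]
    q <- length(idx) * ratio / sum(ratio)
    base <- floor(q)
    rem <- q - base
    leftover <- length(idx) - sum(base)
    if (leftover > 0) {
      give <- order(-rem, priority[parts])[seq_len(leftover)]
      base[give] <- base[give] + 1L
    }
    # allocate in priority order: test first, then finetune, then train
    alloc_order <- order(priority[parts])
    offset <- 0L
    for (k in alloc_order) {
      n_k <- base[k]
      if (n_k > 0) {
        part[idx[(offset + 1L):(offset + n_k)]] <- parts[k]
        offset <- offset + n_k
      }
    }
  }
  lapply(stats::setNames(parts, parts),
         function(p) data[part == p, , drop = FALSE])
}

# Amino-acid composition representation: proportion of each content token
# (20 amino acids + terminator) in the sequence.  This is exactly what a
# non-pre-trained embedding layer pooled by mean reduces to, up to the
# (learned) linear map that the classifier's first layer provides.
composition_features <- function(residues) {
  toks <- c(AMINO_ACIDS, TERMINATOR)
  t(vapply(strsplit(residues, "", fixed = TRUE), function(ch) {
    tab <- table(factor(ch, levels = toks))
    as.numeric(tab) / length(ch)
  }, numeric(length(toks))))
}

# Per-variant feature matrix for a set of sequences.
fusion_features <- function(residues, encoder = NULL,
                            variant = "full", d_hy = NULL,
                            scale = hydropathy_scale()) {
  d_hy <- d_hy %||% if (!is.null(encoder)) encoder$config$max_len else 256L
  hydro <- if (variant != "bert_only") {
    t(vapply(residues, hydropathy_encode, numeric(d_hy),
             max_len = d_hy, scale = scale, USE.NAMES = FALSE))
  }
  bert <- if (variant %in% c("full", "bert_only")) {
    if (is.null(encoder)) stop("variant '", variant, "' needs an encoder")
    predict(encoder, residues)
  }
  embed <- if (variant == "embed_hydro") composition_features(residues)
  fuse(bert_emb = bert, hydro = hydro, embed = embed, variant = variant)
}

mlp_init <- function(p, hidden) {
  list(W1 = matrix(stats::rnorm(p * hidden, sd = sqrt(2 / p)), p, hidden),
       b1 = numeric(hidden),
       w2 = stats::rnorm(hidden, sd = sqrt(1 / hidden)),
       b2 = 0)
}

mlp_grads <- function(X, y, params, weight_decay) {
  n <- nrow(X)
  A <- X %*% params$W1 + rep(params$b1, each = n)
  H <- pmax(A, 0)
  z <- drop(H %*% params$w2) + params$b2
  yhat <- 1 / (1 + exp(-z))
  loss <- mean(bce_loss(yhat, y))
  dz <- (yhat - y) / n
  dH <- outer(dz, params$w2)
  dH[A <= 0] <- 0
  g <- list(W1 = crossprod(X, dH) + weight_decay * params$W1,
            b1 = colSums(dH),
            w2 = drop(crossprod(H, dz)) + weight_decay * params$w2,
            b2 = sum(dz))
  list(loss = loss, grads = g, yhat = yhat)
}

#' Fit the fusion pathogenicity classifier
#'
#' The main model-fitting entry point.  Splits the labeled mutation set
#' into fine-tuning / training / test partitions, represents each
#' sequence by the configured variant (`"full"` = language-model
#' embedding + hydropathy vector, `"bert_only"` = embedding alone,
#' `"embed_hydro"` = plain embedding-layer representation + hydropathy),
#' and trains a one-hidden-layer ReLU MLP with a sigmoid output and
#' binary cross-entropy loss.
#'
#' @param data Labeled mutation `data.frame` (`id`, `residues`, `label`,
#'   optional `augmented`), e.g. from [generate_mutation_set()] or read
#'   from FASTA + label TSV.
#' @param encoder A trained [protein_lm()] (required unless
#'   `variant = "embed_hydro"`).
#' @param variant Representation variant; see [fuse()].
#' @param config A [classifier_config()].
#' @param ratio Split ratio fine-tune : train : test.
#' @param splits Optional pre-computed result of [split_dataset()];
#'   overrides `ratio`.
#' @param d_hy Hydropathy vector length; defaults to the encoder's
#'   maximum sequence length so both representations cover the same
#'   window.
#' @param scale Hydropathy scale.
#' @return An object of class `fusion_model` with elements `params`
#'   (MLP weights), `encoder`, `variant`, `config`, `splits`, `history`
#'   (per-epoch training loss and test AUROC) and `test_metrics`.
#' @seealso [predict.fusion_model()], [metrics_report()]
#' @export
fusion_classifier <- function(data, encoder = NULL, variant = c("full",
                              "bert_only", "embed_hydro"),
                              config = classifier_config(),
                              ratio = c(5, 4, 1), splits = NULL,
                              d_hy = NULL, scale = hydropathy_scale()) {
  variant <- match.arg(variant)
  stopifnot(inherits(config, "pp_classifier_config"))
  if (is.null(splits)) splits <- split_dataset(data, ratio, seed = config$seed)
  if (length(unique(splits$train$label)) < 2L) {
    stop("training partition has a single class; augment or re-split")
  }
  if (config$mode == "fine_tune") {
    if (is.null(encoder)) stop("fine_tune mode requires an encoder")
    ft_corpus <- tokenize_corpus(splits$finetune, encoder$vocab,
                                 max_len = encoder$config$max_len)
    encoder <- protein_lm(ft_corpus, config = encoder$config,
                          steps = config$finetune_steps,
                          batch_size = min(16L, nrow(splits$finetune)),
                          seed = config$seed, init = encoder)
  }
  d_hy <- d_hy %||% if (!is.null(encoder)) encoder$config$max_len else 256L
  feat <- function(df) fusion_features(df$residues, encoder, variant,
                                       d_hy = d_hy, scale = scale)
  X_train <- feat(splits$train)
  y_train <- splits$train$label
  X_test <- feat(splits$test)
  y_test <- splits$test$label
  set.seed(config$seed)
  params <- mlp_init(ncol(X_train), config$hidden_dim)
  state <- adam_init(params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        test_auroc = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    gr <- mlp_grads(X_train, y_train, params, config$weight_decay)
    res <- adam_step(params, gr$grads, state, lr = config$learning_rate,
                     warmup = 0L)
    params <- res$params
    state <- res$state
    test_auroc <- if (length(unique(y_test)) == 2L) {
      roc_curve(y_test, mlp_forward(X_test, params))$auroc
    } else NA_real_
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = gr$loss,
                                         test_auroc = test_auroc))
  }
  scores <- mlp_forward(X_test, params)
  test_metrics <- if (length(unique(y_test)) == 2L) {
    metrics_report(y_test, scores, config$threshold)
  } else NULL
  structure(list(params = params, encoder = encoder, variant = variant,
                 config = config, d_hy = d_hy, scale = scale,
                 splits = splits, history = history,
                 test_metrics = test_metrics),
            class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat("Fusion pathogenicity classifier (variant:", x$variant, ")\n")
  cat(sprintf("  features: %d, hidden: %d, epochs: %d, mode: %s\n",
              nrow(x$params$W1), x$config$hidden_dim, x$config$epochs,
              x$config$mode))
  if (!is.null(x$test_metrics)) {
    with(x$test_metrics,
         cat(sprintf("  held-out test: accuracy %.3f, AUROC %.3f, AUPR %.3f, F1 %.3f\n",
                     accuracy, auroc, aupr, f1)))
  }
  invisible(x)
}

#' @export
summary.fusion_model <- function(object, ...) {
  cat("Held-out test metrics (", nrow(object$splits$test), "samples ):\n")
  print(object$test_metrics, row.names = FALSE)
  invisible(object$test_metrics)
}

#' @export
coef.fusion_model <- function(object, ...) object$params

#' Predict pathogenicity of mutation sequences
#'
#' @param object A `fusion_model`.
#' @param newdata `data.frame` with `id` and `residues` columns, or a
#'   character vector of residue strings.
#' @param ... Unused.
#' @return A `data.frame` with `id`, `score` (probability in `[0, 1]`)
#'   and `label` (1 iff `score >= threshold`), input order preserved.
#' @export
predict.fusion_model <- function(object, newdata, ...) {
  if (is.character(newdata)) {
    newdata <- data.frame(id = paste0("seq", seq_along(newdata)),
                          residues = newdata, stringsAsFactors = FALSE)
  }
  X <- fusion_features(newdata$residues, object$encoder, object$variant,
                       d_hy = object$d_hy, scale = object$scale)
  score <- mlp_forward(X, object$params)
  data.frame(id = newdata$id, score = score,
             label = as.integer(score >= object$config$threshold),
             stringsAsFactors = FALSE)
}

#' @export
residuals.fusion_model <- function(object, ...) {
  pred <- predict(object, object$splits$test)
  object$splits$test$label - pred$score
}

#' Plot the held-out ROC curve of a fitted fusion model
#'
#' @param x A `fusion_model`.
#' @param ... Passed to [plot()].
#' @export
plot.fusion_model <- function(x, ...) {
  pred <- predict(x, x$splits$test)
  rc <- roc_curve(x$splits$test$label, pred$score)
  plot(rc$points$fpr, rc$points$tpr, type = "l",
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("ROC (AUROC = %.3f)", rc$auroc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(rc)
}

#' Write predictions as TSV (id, score, label)
#'
#' @param predictions Result of [predict.fusion_model()].
#' @param path Destination file.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a label table TSV (id, label)
#'
#' @param path TSV with columns `id` and `label` in `{0, 1}`.
#' @return A `data.frame`.
#' @export
read_labels <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "label") %in% names(tab)))
  if (!all(tab$label %in% c(0, 1))) stop("labels must be 0 or 1")
  tab
}
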