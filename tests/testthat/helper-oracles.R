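# Independent brute-force oracles used to verify the package's metric
# computations.  These are deliberately naive implementations that share
# no code with the package internals.

# AUROC as the Mann-Whitney concordance probability: over all
# positive/negative pairs, count concordant pairs (ties = 1/2).
concordance_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Average precision by exhaustive threshold enumeration: walk thresholds
# at every unique score (descending) and accumulate precision times
# recall increment.
enumerate_ap <- function(labels, scores) {
  n_pos <- sum(labels == 1)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  ap <- 0
  for (t in thresholds) {
    called <- scores >= t
    tp <- sum(labels == 1 & called)
    precision <- tp / sum(called)
    recall <- tp / n_pos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Random labeled score sets, some with ties, for property-style sweeps.
random_scored_set <- function(n, tie_prob = 0.3) {
  scores <- if (runif(1) < tie_prob) {
    sample(seq(0, 1, by = 0.25), n, replace = TRUE)
  } else {
    round(runif(n), 3)
  }
  labels <- sample(c(0L, 1L), n, replace = TRUE)
  # ensure both classes present
  if (all(labels == 0L)) labels[1] <- 1L
  if (all(labels == 1L)) labels[1] <- 0L
  list(labels = labels, scores = scores)
}
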