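# Class-imbalance mitigation: terminator-noise copies of minority-class
# sequences, and truncated wild-type negatives for sets that lack benign
# examples.

#' Terminator-noise augmentation
#'
#' Produces noisy copies of a sequence by inserting terminator symbols
#' (`*`) at uniformly random positions (any of the `len + 1` insertion
#' slots, interior or flanking).  Copies inherit the source label and are
#' id-suffixed to mark their provenance, so downstream splitting can keep
#' them out of the test partition.
#'
#' @param residues Residue string to augment.
#' @param copies Number of noisy copies (0 gives an empty result).
#' @param noise_tokens Terminators inserted per copy; must be positive
#'   and smaller than the sequence length.
#' @param id Identifier of the source sequence, used as prefix.
#' @return Character vector of `copies` augmented residue strings, named
#'   `<id>_noise<k>`.
#' @export
#' @examples
#' set.seed(1); terminator_noise("MKV", copies = 2, noise_tokens = 1)
terminator_noise <- function(residues, copies = 1L, noise_tokens = 1L,
                             id = "seq") {
  stopifnot(copies >= 0L, noise_tokens >= 1L)
  n <- nchar(residues)
  if (noise_tokens >= n) {
    stop("noise_tokens (", noise_tokens, ") must be smaller than the ",
         "sequence length (", n, ")")
  }
  if (copies == 0L) return(stats::setNames(character(0), character(0)))
  out <- vapply(seq_len(copies), function(k) {
    chars <- strsplit(residues, "", fixed = TRUE)[[1]]
    for (j in seq_len(noise_tokens)) {
      slot <- sample.int(length(chars) + 1L, 1L)
      chars <- append(chars, TERMINATOR, after = slot - 1L)
    }
    paste(chars, collapse = "")
  }, character(1))
  stats::setNames(out, sprintf("%s_noise%d", id, seq_len(copies)))
}

#' Truncated wild-type negative sampling
#'
#' Draws contiguous subsequences of a fixed length from a wild-type
#' protein, labeled benign (0).  This supplies negative examples for
#' datasets that are almost entirely pathogenic.
#'
#' @param wildtype Wild-type residue string.
#' @param target_length Length of each truncated sequence.
#' @param n Number of truncations to draw.
#' @return Character vector of `n` substrings of length `target_length`,
#'   named `wt_trunc<k>`.
#' @export
truncated_wildtype <- function(wildtype, target_length, n = 1L) {
  len <- nchar(wildtype)
  stopifnot(n >= 1L, target_length >= 1L)
  if (target_length > len) {
    stop("target_length (", target_length, ") exceeds wild-type length (",
         len, ")")
  }
  starts <- sample.int(len - target_length + 1L, n, replace = TRUE)
  out <- substring(wildtype, starts, starts + target_length - 1L)
  stats::setNames(out, sprintf("wt_trunc%d", seq_len(n)))
}

#' Augment a labeled mutation set
#'
#' Applies an augmentation policy to a labeled mutation `data.frame`
#' (columns `id`, `residues`, `label`, `augmented`).  By default the
#' minority class is augmented.  Augmented rows are flagged
#' `augmented = TRUE`; [split_dataset()] assigns them to the training
#' partition only.
#'
#' @param data Labeled mutation `data.frame`.
#' @param policy `"terminator_noise"` or `"truncated_wildtype"`.
#' @param copies Noisy copies per minority sequence (terminator noise).
#' @param noise_tokens Terminators inserted per copy.
#' @param target_class Class label to augment; default the minority class.
#' @param wildtype,target_length,n For `"truncated_wildtype"`: the
#'   wild-type string, truncation length, and number of negatives.
#' @param seed Integer seed.
#' @return The input `data.frame` with augmented rows appended.
#' @export
augment_mutation_set <- function(data, policy = c("terminator_noise",
                                                  "truncated_wildtype"),
                                 copies = 1L, noise_tokens = 1L,
                                 target_class = NULL,
                                 wildtype = attr(data, "wildtype"),
                                 target_length = NULL, n = NULL,
                                 seed = 1L) {
  policy <- match.arg(policy)
  stopifnot(all(c("id", "residues", "label") %in% names(data)))
  if (is.null(data$augmented)) data$augmented <- FALSE
  set.seed(seed)
  if (policy == "terminator_noise") {
    counts <- table(factor(data$label[!data$augmented], levels = c(0, 1)))
    target_class <- target_class %||%
      as.integer(names(counts)[which.min(counts)])
    src <- data[data$label == target_class & !data$augmented, , drop = FALSE]
    new_rows <- do.call(rbind, lapply(seq_len(nrow(src)), function(i) {
      aug <- terminator_noise(src$residues[i], copies = copies,
                              noise_tokens = noise_tokens, id = src$id[i])
      if (length(aug) == 0L) return(NULL)
      data.frame(id = names(aug), residues = unname(aug),
                 label = src$label[i], augmented = TRUE,
                 stringsAsFactors = FALSE)
    }))
  } else {
    if (is.null(wildtype)) stop("truncated_wildtype policy needs a wildtype")
    target_length <- target_length %||% nchar(data$residues[1])
    n <- n %||% max(1L, sum(data$label == 1) - sum(data$label == 0))
    aug <- truncated_wildtype(wildtype, target_length, n)
    new_rows <- data.frame(id = names(aug), residues = unname(aug),
                           label = 0L, augmented = TRUE,
                           stringsAsFactors = FALSE)
  }
  out <- rbind(data[, c("id", "residues", "label", "augmented")],
               new_rows)
  rownames(out) <- NULL
  for (a in c("wildtype", "motif_positions", "spec")) {
    attr(out, a) <- attr(data, a)
  }
  out
}
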