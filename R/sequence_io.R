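# FASTA ingestion, residue cleaning, amino-acid tokenization and the
# pre-training corpus format.

#' Canonical amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes in alphabetical order, the
#' terminator symbol `"*"`, and the unknown-residue placeholder `"?"` used
#' by [clean_sequence()] for any non-canonical character.
#'
#' @format Character vectors.
#' @name alphabet
NULL

#' @rdname alphabet
#' @export
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname alphabet
#' @export
TERMINATOR <- "*"

#' @rdname alphabet
#' @export
UNKNOWN_RESIDUE <- "?"

# Special tokens occupy the lowest vocabulary indices, in this fixed order.
SPECIAL_TOKENS <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")

#' Read protein sequences from a FASTA file
#'
#' Reads a (possibly alignment-derived) FASTA file and returns cleaned
#' protein sequences.  Residues are uppercased; whitespace and the
#' alignment gap characters `-` and `.` are stripped (gaps are artifacts
#' of the alignment, not residues); any remaining non-canonical character
#' is replaced by the unknown placeholder.  Records whose sequence is
#' empty after cleaning are skipped with a warning rather than aborting
#' the whole import, as real protein-family dumps occasionally contain
#' such records.
#'
#' @param path Path to a FASTA file.
#' @param clean If `TRUE` (default) apply [clean_sequence()] to each record.
#' @param keyword Optional case-insensitive substring filter applied to the
#'   FASTA headers (e.g. `"BRCA1"`); records whose header does not contain
#'   the keyword are dropped.
#' @return A `data.frame` with columns `id` (full FASTA header) and
#'   `residues` (cleaned residue string), one row per retained record, in
#'   file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "MKV", ">s2", "acd-e"), fa)
#' read_fasta(fa)
read_fasta <- function(path, clean = TRUE, keyword = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(!grepl("^[[:space:]]*$", lines))
  if (length(nonblank) == 0L) {
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(), residues = character(),
                      stringsAsFactors = FALSE))
  }
  first <- nonblank[1L]
  if (!startsWith(lines[first], ">")) {
    stop("malformed FASTA: sequence data before any header at line ", first)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  seqs <- as.character(set)
  if (!is.null(keyword)) {
    keep <- grepl(keyword, ids, ignore.case = TRUE, fixed = FALSE)
    ids <- ids[keep]
    seqs <- seqs[keep]
  }
  if (clean) {
    cleaned <- vapply(seqs, function(s) {
      stripped <- gsub("[-.[:space:]]", "", s)
      if (nchar(stripped) == 0L) "" else clean_sequence(s)$residues
    }, character(1), USE.NAMES = FALSE)
    empty <- cleaned == ""
    if (any(empty)) {
      warning(sum(empty), " FASTA record(s) with empty sequence skipped: ",
              paste(utils::head(ids[empty], 5L), collapse = ", "))
      ids <- ids[!empty]
      cleaned <- cleaned[!empty]
    }
    seqs <- cleaned
  }
  data.frame(id = unname(ids), residues = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Canonicalize a raw residue string
#'
#' Uppercases, removes whitespace and alignment gaps (`-`, `.`), and
#' replaces every character that is neither one of the 20 canonical codes
#' nor the terminator `*` with the unknown placeholder `?`.
#'
#' @param raw A character scalar.
#' @return A list with `residues` (the cleaned string) and `n_replaced`
#'   (how many characters became the unknown placeholder).
#' @export
#' @examples
#' clean_sequence("mkXv")  # "MK?V", 1 replacement
clean_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  s <- toupper(gsub("[-.[:space:]]", "", raw))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) stop("empty sequence after cleaning")
  bad <- !(chars %in% c(AMINO_ACIDS, TERMINATOR))
  chars[bad] <- UNKNOWN_RESIDUE
  list(residues = paste(chars, collapse = ""), n_replaced = sum(bad))
}

#' Build the amino-acid vocabulary
#'
#' Deterministic vocabulary over the 20 amino-acid tokens (alphabetical by
#' one-letter code), optionally the terminator symbol, and the five
#' special tokens `[PAD]`, `[UNK]`, `[CLS]`, `[SEP]`, `[MASK]` at indices
#' 0--4.  Token indices are 0-based and form a bijection onto
#' `0..size-1`; content tokens follow the specials, the terminator last.
#'
#' @param include_terminator Include the terminator symbol `*`? Default
#'   `TRUE`: real mutation data contains premature stop codons and the
#'   terminator-noise augmentation inserts them deliberately.
#' @return An object of class `pp_vocabulary`: a list with `tokens`
#'   (character vector, position `i` holds the token with index `i - 1`)
#'   and `size`.
#' @export
build_vocabulary <- function(include_terminator = TRUE) {
  tokens <- c(SPECIAL_TOKENS, AMINO_ACIDS,
              if (include_terminator) TERMINATOR)
  structure(list(tokens = tokens, size = length(tokens)),
            class = "pp_vocabulary")
}

#' @export
print.pp_vocabulary <- function(x, ...) {
  cat("Amino-acid vocabulary:", x$size, "tokens\n")
  cat("  specials:", paste(x$tokens[seq_along(SPECIAL_TOKENS)],
                           collapse = " "), "\n")
  cat("  content: ", paste(x$tokens[-seq_along(SPECIAL_TOKENS)],
                           collapse = " "), "\n")
  invisible(x)
}

#' Token index lookup
#'
#' @param vocab A `pp_vocabulary`.
#' @param tokens Character vector of tokens.
#' @return Integer vector of 0-based indices; `NA` for unknown tokens.
#' @export
vocab_index <- function(vocab, tokens) {
  match(tokens, vocab$tokens) - 1L
}

# 0-based ids of the five special tokens, by role.
special_id <- function(vocab, which) {
  token <- c(pad = "[PAD]", unk = "[UNK]", cls = "[CLS]",
             sep = "[SEP]", mask = "[MASK]")[[which]]
  vocab_index(vocab, token)
}

#' Tokenize a cleaned residue string
#'
#' Maps each residue to its vocabulary index, frames the sequence with the
#' `[CLS]` start and `[SEP]` end tokens, and truncates at the tail to
#' `max_len`, always retaining `[CLS]` and re-appending `[SEP]`.  The
#' unknown placeholder maps to `[UNK]`.
#'
#' @param residues Cleaned residue string (see [clean_sequence()]).
#' @param vocab A `pp_vocabulary`.
#' @param max_len Maximum token count, at least 3.
#' @return Integer vector of 0-based token indices, length `<= max_len`.
#' @export
#' @examples
#' v <- build_vocabulary()
#' tokenize("MKV", v, max_len = 10)
tokenize <- function(residues, vocab, max_len) {
  stopifnot(inherits(vocab, "pp_vocabulary"), max_len >= 3L)
  if (!is.character(residues) || length(residues) != 1L ||
      nchar(residues) == 0L) {
    stop("tokenize: residues must be a non-empty string")
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  ids <- vocab_index(vocab, chars)
  ids[chars == UNKNOWN_RESIDUE] <- special_id(vocab, "unk")
  if (anyNA(ids)) {
    stop("tokenize: residue(s) not in vocabulary: ",
         paste(unique(chars[is.na(ids)]), collapse = ", "),
         " (clean the sequence first)")
  }
  out <- c(special_id(vocab, "cls"), ids, special_id(vocab, "sep"))
  if (length(out) > max_len) {
    out <- c(out[seq_len(max_len - 1L)], special_id(vocab, "sep"))
  }
  out
}

#' Tokenize many sequences into a corpus
#'
#' @param seqs A `data.frame` with columns `id` and `residues` (as from
#'   [read_fasta()]), or a character vector of residue strings.
#' @param vocab A `pp_vocabulary`.
#' @param max_len Maximum token count per document.
#' @return An object of class `pp_corpus`: list with `documents` (list of
#'   0-based integer index vectors), `source_ids`, and `vocab`.
#' @export
tokenize_corpus <- function(seqs, vocab, max_len) {
  if (is.character(seqs)) {
    seqs <- data.frame(id = paste0("seq", seq_along(seqs)), residues = seqs,
                       stringsAsFactors = FALSE)
  }
  docs <- lapply(seqs$residues, tokenize, vocab = vocab, max_len = max_len)
  structure(list(documents = docs, source_ids = seqs$id, vocab = vocab),
            class = "pp_corpus")
}

#' @export
print.pp_corpus <- function(x, ...) {
  lens <- lengths(x$documents)
  cat("Tokenized corpus:", length(x$documents), "documents,",
      "token lengths", min(lens), "-", max(lens), "\n")
  invisible(x)
}

#' Write / read the pre-training corpus file
#'
#' The corpus file is plain text: one sequence per line with residues
#' separated by single spaces, and a blank line after each sequence so
#' every sequence forms its own paragraph.
#'
#' @param seqs A `data.frame` with a `residues` column, or a character
#'   vector of residue strings.
#' @param path Output file path.
#' @return `write_corpus` returns `path` invisibly; `read_corpus` returns
#'   the character vector of residue strings.
#' @export
write_corpus <- function(seqs, path) {
  residues <- if (is.data.frame(seqs)) seqs$residues else seqs
  if (length(residues) == 0L) stop("write_corpus: no sequences")
  spaced <- vapply(strsplit(residues, "", fixed = TRUE),
                   paste, character(1), collapse = " ")
  con <- file(path, open = "wb")  # binary: bit-exact newlines on all platforms
  on.exit(close(con))
  writeLines(as.vector(rbind(spaced, "")), con, sep = "\n")
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[lines != ""]
  vapply(strsplit(lines, " ", fixed = TRUE),
         paste, character(1), collapse = "")
}

#' Write / read a vocabulary file (one token per line, index = line order)
#'
#' @param vocab A `pp_vocabulary`.
#' @param path File path.
#' @export
write_vocabulary <- function(vocab, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(vocab$tokens, con, sep = "\n")
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  tokens <- readLines(path, warn = FALSE)
  structure(list(tokens = tokens, size = length(tokens)),
            class = "pp_vocabulary")
}
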