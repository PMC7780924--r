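# Per-residue hydropathy encoding (Kyte-Doolittle scale).

#' Load a hydropathy scale
#'
#' Scales ship as two-column TSV files (`code`, `value`) under
#' `inst/extdata/` so alternative physicochemical scales can be dropped
#' in.  The default is the Kyte-Doolittle hydropathy scale: positive
#' values are hydrophobic (max Ile = 4.5), negative hydrophilic
#' (min Arg = -4.5).
#'
#' @param name Scale name (file stem) or a path to a TSV file.
#' @return Named numeric vector of length 20, names are one-letter codes.
#' @export
#' @examples
#' sc <- hydropathy_scale()
#' sc[["I"]]  # 4.5
hydropathy_scale <- function(name = "kyte_doolittle") {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0(name, ".tsv"), package = "protpath",
                mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("code", "value") %in% names(tab)))
  if (nrow(tab) != 20L || anyDuplicated(tab$code) ||
      !all(tab$code %in% AMINO_ACIDS)) {
    stop("hydropathy scale must assign exactly one value to each of the ",
         "20 canonical amino acids")
  }
  stats::setNames(as.numeric(tab$value), tab$code)
}

#' Hydropathy value of single residues
#'
#' Canonical residues map to their scale value; the terminator `*` and
#' the unknown placeholder `?` map to 0, the scale's neutral midpoint.
#'
#' @param codes Character vector of single residue characters.
#' @param scale Named numeric vector as from [hydropathy_scale()].
#' @return Numeric vector of hydropathy values.
#' @export
hydropathy_lookup <- function(codes, scale = hydropathy_scale()) {
  ok <- codes %in% c(names(scale), TERMINATOR, UNKNOWN_RESIDUE)
  if (!all(ok)) {
    stop("hydropathy_lookup: not a residue code: ",
         paste(unique(codes[!ok]), collapse = ", "))
  }
  out <- unname(scale[codes])
  out[is.na(out)] <- 0
  out
}

#' Encode a sequence as a fixed-length hydropathy vector
#'
#' Each residue is replaced by its hydropathy value; the vector is
#' zero-padded at the end to length `max_len` (and truncated at the tail
#' if the sequence is longer, consistent with how the language model
#' truncates its input).  `max_len` should equal the language model's
#' maximum sequence length so both representations cover the same window.
#'
#' @param residues Cleaned residue string.
#' @param max_len Output vector length (default 256).
#' @param scale Named numeric vector as from [hydropathy_scale()].
#' @param normalize If `TRUE`, min-max scale values to `[0, 1]` before
#'   padding.  Off by default: the classifier receives raw scale values.
#' @return Numeric vector of length `max_len` with attribute
#'   `true_length`, the number of non-padding positions.
#' @export
#' @examples
#' hydropathy_encode("IR", max_len = 4)  # 4.5 -4.5 0 0
hydropathy_encode <- function(residues, max_len = 256L,
                              scale = hydropathy_scale(),
                              normalize = FALSE) {
  stopifnot(max_len >= 1L)
  if (!is.character(residues) || length(residues) != 1L ||
      nchar(residues) == 0L) {
    stop("hydropathy_encode: empty sequence")
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  vals <- hydropathy_lookup(chars, scale)
  if (normalize) {
    rng <- range(scale)
    vals <- (vals - rng[1]) / (rng[2] - rng[1])
  }
  n <- min(length(vals), max_len)
  out <- numeric(max_len)
  out[seq_len(n)] <- vals[seq_len(n)]
  attr(out, "true_length") <- n
  out
}
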