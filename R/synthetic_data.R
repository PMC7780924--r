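# Synthetic protein-family and labeled-mutation generators.
#
# The family generator emulates a conserved protein domain family, the
# kind of corpus a masked-LM is pre-trained on: most columns are strongly
# conserved (a consensus residue with a small substitution rate), the
# remainder weakly conserved (a dominant residue with more variability),
# as in a deep seed alignment of a functionally constrained domain.  The
# mutation generator plants a recoverable pathogenicity signal jointly in
# position (conserved columns) and physicochemistry (hydropathy sign
# flips), so that sequence-context and hydropathy representations each
# capture part of the signal and their fusion captures more.

#' Specification of a synthetic protein family
#'
#' @param n_sequences Number of family members to draw.
#' @param length Residue length of every member.  The default 62 leaves
#'   room for the two framing tokens within a 64-token encoder window.
#' @param motif_positions 1-based positions of strongly conserved
#'   (motif) columns.  Default: all positions except seven evenly spaced
#'   weakly conserved columns.
#' @param motif_residues Consensus residue per motif position; default
#'   drawn once from the seed.
#' @param background_distribution Probabilities over the 20 amino acids
#'   for non-motif columns.  Default concentrates mass 0.85 on a single
#'   dominant residue (weak conservation); must sum to 1.
#' @param substitution_noise Per-position probability that a motif
#'   column deviates from its consensus residue (default 0.01).
#' @param seed Integer seed; generation is byte-reproducible from it.
#' @return An object of class `pp_family_spec`.
#' @export
family_spec <- function(n_sequences = 500L, length = 62L,
                        motif_positions = setdiff(seq_len(length),
                                                  seq(7L, length, by = 8L)),
                        motif_residues = NULL,
                        background_distribution = NULL,
                        substitution_noise = 0.01, seed = 1L) {
  stopifnot(n_sequences >= 1L, length >= 1L,
            substitution_noise >= 0, substitution_noise < 1)
  if (any(motif_positions < 1L) || any(motif_positions > length)) {
    stop("motif positions must lie in [1, length]")
  }
  if (is.null(background_distribution)) {
    background_distribution <- stats::setNames(rep(0.15 / 19, 20),
                                               AMINO_ACIDS)
    background_distribution[["S"]] <- 0.85
  }
  if (abs(sum(background_distribution) - 1) > 1e-8) {
    stop("background_distribution must sum to 1")
  }
  if (is.null(motif_residues)) {
    old <- .Random.seed_save()
    set.seed(seed)
    motif_residues <- sample(AMINO_ACIDS, length(motif_positions),
                             replace = TRUE)
    .Random.seed_restore(old)
  }
  stopifnot(length(motif_residues) == length(motif_positions))
  structure(list(n_sequences = as.integer(n_sequences),
                 length = as.integer(length),
                 motif_positions = as.integer(motif_positions),
                 motif_residues = motif_residues,
                 background_distribution = background_distribution,
                 substitution_noise = substitution_noise,
                 seed = as.integer(seed)),
            class = "pp_family_spec")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic protein family
#'
#' Draws family members column-by-column: motif columns carry the
#' consensus residue, replaced with probability `substitution_noise` by a
#' uniformly random different residue; non-motif columns draw from the
#' background distribution independently per sequence.
#'
#' @param spec A `pp_family_spec`.
#' @return A `data.frame` with columns `id` and `residues`, plus
#'   attributes `wildtype` (the family consensus string), `motif_positions`
#'   and `spec`.
#' @export
generate_family <- function(spec = family_spec()) {
  stopifnot(inherits(spec, "pp_family_spec"))
  set.seed(spec$seed)
  L <- spec$length
  n <- spec$n_sequences
  bg <- spec$background_distribution
  consensus <- character(L)
  is_motif <- seq_len(L) %in% spec$motif_positions
  consensus[spec$motif_positions] <- spec$motif_residues
  consensus[!is_motif] <- names(bg)[which.max(bg)]
  seqs <- character(n)
  for (i in seq_len(n)) {
    chars <- consensus
    # weakly conserved columns: draw from the background distribution
    nbg <- sum(!is_motif)
    if (nbg > 0) {
      chars[!is_motif] <- sample(names(bg), nbg, replace = TRUE, prob = bg)
    }
    # strongly conserved columns: rare substitutions
    flip <- spec$motif_positions[
      stats::runif(length(spec$motif_positions)) < spec$substitution_noise]
    for (p in flip) {
      chars[p] <- sample(setdiff(AMINO_ACIDS, chars[p]), 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  out <- data.frame(id = sprintf("fam%04d", seq_len(n)), residues = seqs,
                    stringsAsFactors = FALSE)
  attr(out, "wildtype") <- paste(consensus, collapse = "")
  attr(out, "motif_positions") <- spec$motif_positions
  attr(out, "spec") <- spec
  out
}

#' Specification of a labeled mutation set
#'
#' Default class sizes (86 pathogenic / 314 benign) mirror the roughly
#' 1:3.65 imbalance of curated missense SNV sets at desk scale.
#'
#' @param n_benign,n_pathogenic Class sizes (each at least 1).
#' @param signal Pathogenicity mechanism: `"hydropathy_flip"` (pathogenic
#'   mutations flip the hydropathy sign at conserved positions),
#'   `"motif_disruption"` (any substitution at conserved positions), or
#'   `"mixed"`.
#' @param effect_size Minimum absolute hydropathy change of a pathogenic
#'   substitution (dimensionless scale units).  `0` generates an
#'   uninformative null set: both classes receive uniformly random
#'   substitutions, so labels carry no signal.
#' @param seed Integer seed.
#' @return An object of class `pp_mutation_spec`.
#' @export
mutation_set_spec <- function(n_benign = 314L, n_pathogenic = 86L,
                              signal = c("hydropathy_flip",
                                         "motif_disruption", "mixed"),
                              effect_size = 4, seed = 1L) {
  signal <- match.arg(signal)
  stopifnot(n_benign >= 1L, n_pathogenic >= 1L, effect_size >= 0)
  structure(list(n_benign = as.integer(n_benign),
                 n_pathogenic = as.integer(n_pathogenic),
                 signal = signal, effect_size = effect_size,
                 seed = as.integer(seed)),
            class = "pp_mutation_spec")
}

#' Generate a labeled mutation set from a wild-type sequence
#'
#' Every record is the wild-type with exactly one substitution.  Under
#' the `"hydropathy_flip"` signal, benign records substitute at
#' non-conserved positions with a residue of the same hydropathy sign;
#' pathogenic records substitute at conserved (motif) positions with a
#' residue of opposite hydropathy sign changing the value by at least
#' `effect_size`.  With `effect_size = 0` both classes get uniformly
#' random substitutions at random positions (a null set).
#'
#' @param wildtype Wild-type residue string, or the `data.frame` returned
#'   by [generate_family()] (its consensus and motif positions are used).
#' @param spec A `pp_mutation_spec`.
#' @param motif_positions 1-based conserved positions; defaults to the
#'   `motif_positions` attribute of `wildtype`.
#' @param scale Hydropathy scale (see [hydropathy_scale()]).
#' @return A `data.frame` with columns `id`, `residues`, `label`
#'   (benign 0 / pathogenic 1) and `augmented` (`FALSE`), with the
#'   wild-type and spec kept as attributes.
#' @export
generate_mutation_set <- function(wildtype, spec = mutation_set_spec(),
                                  motif_positions = NULL,
                                  scale = hydropathy_scale()) {
  stopifnot(inherits(spec, "pp_mutation_spec"))
  if (is.data.frame(wildtype)) {
    motif_positions <- motif_positions %||% attr(wildtype, "motif_positions")
    wildtype <- attr(wildtype, "wildtype")
  }
  chars <- strsplit(wildtype, "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (L < 10L) stop("wild-type must have at least 10 residues")
  if (spec$effect_size > diff(range(scale)) ) {
    stop("effect_size ", spec$effect_size,
         " unreachable: the scale spans only ", diff(range(scale)))
  }
  set.seed(spec$seed)
  null_mode <- spec$effect_size == 0
  if (!null_mode && is.null(motif_positions)) {
    stop("motif_positions required for a planted-signal mutation set")
  }
  non_motif <- setdiff(seq_len(L), motif_positions)
  draw_random <- function() {
    p <- sample.int(L, 1L)
    list(pos = p, res = sample(setdiff(AMINO_ACIDS, chars[p]), 1L))
  }
  draw_benign <- function() {
    # same hydropathy sign, outside the conserved motif
    repeat {
      p <- if (length(non_motif)) sample(non_motif, 1L) else sample.int(L, 1L)
      v <- hydropathy_lookup(chars[p], scale)
      cand <- names(scale)[sign(scale) == sign(v) & names(scale) != chars[p]]
      if (length(cand)) return(list(pos = p, res = sample(cand, 1L)))
    }
  }
  draw_pathogenic <- function() {
    repeat {
      p <- sample(motif_positions, 1L)
      v <- hydropathy_lookup(chars[p], scale)
      cand <- names(scale)[sign(scale) == -sign(v) &
                             abs(scale - v) >= spec$effect_size]
      if (spec$signal == "motif_disruption") {
        cand <- setdiff(names(scale), chars[p])
      } else if (spec$signal == "mixed" && stats::runif(1) < 0.5) {
        cand <- setdiff(names(scale), chars[p])
      }
      if (length(cand)) return(list(pos = p, res = sample(cand, 1L)))
    }
  }
  n_total <- spec$n_benign + spec$n_pathogenic
  labels <- c(rep(0L, spec$n_benign), rep(1L, spec$n_pathogenic))
  residues <- character(n_total)
  for (i in seq_len(n_total)) {
    mut <- if (null_mode) draw_random() else
      if (labels[i] == 1L) draw_pathogenic() else draw_benign()
    m <- chars
    m[mut$pos] <- mut$res
    residues[i] <- paste(m, collapse = "")
  }
  out <- data.frame(
    id = sprintf("mut%04d_%s", seq_len(n_total),
                 ifelse(labels == 1L, "path", "ben")),
    residues = residues, label = labels, augmented = FALSE,
    stringsAsFactors = FALSE)
  attr(out, "wildtype") <- wildtype
  attr(out, "motif_positions") <- motif_positions
  attr(out, "spec") <- spec
  out
}
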