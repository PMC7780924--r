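# Configuration loading, seed management and the staged pipeline runner
# behind the command-line interface.

PIPELINE_STAGES <- c("simulate", "build_corpus", "pretrain", "encode",
                     "augment", "train", "predict", "evaluate")

#' Derive a per-stage seed from the global seed
#'
#' One global seed fans out deterministically to one sub-seed per
#' pipeline stage, so a stage can be rerun in isolation and still agree
#' with a full pipeline run.  The derivation is
#' `(seed * 1103 + 7919 * stage_index) mod (2^31 - 1)`, kept within the
#' exactly-representable double range.
#'
#' @param seed Global integer seed.
#' @param stage Stage name: one of simulate, build_corpus, pretrain,
#'   encode, augment, train, predict, evaluate.
#' @return Integer sub-seed.
#' @export
derive_seed <- function(seed, stage) {
  idx <- match(stage, PIPELINE_STAGES)
  if (is.na(idx)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 1103 + 7919 * idx) %% 2147483647)
}

#' Load and validate a run configuration
#'
#' YAML configuration with optional sections `encoder` (arguments of
#' [encoder_config()] or `profile`), `classifier` ([classifier_config()]
#' arguments), `family` ([family_spec()]), `mutations`
#' ([mutation_set_spec()]), `augmentation`, and global keys `seed`,
#' `out_dir`, `max_len`.  Validation errors are reported before any
#' computation.
#'
#' @param path YAML file path.
#' @return A list of validated sub-configurations, class `pp_run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  seed <- as.integer(raw$seed %||% 1L)
  enc <- raw$encoder %||% list()
  encoder <- if (!is.null(enc$profile)) {
    do.call(encoder_profile, enc)
  } else if (length(enc)) {
    do.call(encoder_config, enc)
  } else {
    encoder_profile("base")
  }
  classifier <- do.call(classifier_config, raw$classifier %||% list())
  family <- do.call(family_spec, raw$family %||% list())
  mutations <- do.call(mutation_set_spec, raw$mutations %||% list())
  structure(list(seed = seed, out_dir = raw$out_dir %||% ".",
                 encoder = encoder, classifier = classifier,
                 family = family, mutations = mutations,
                 augmentation = raw$augmentation %||% list(),
                 pretrain = raw$pretrain %||% list(),
                 raw = raw),
            class = "pp_run_config")
}

#' Write a stage manifest
#'
#' Records the configuration snapshot, the MD5 checksums of the input
#' files, the derived seed and the package version, so any stage can be
#' replayed exactly from its manifest.
#'
#' @param stage Stage name.
#' @param cfg The run configuration (`pp_run_config`).
#' @param inputs Character vector of input file paths.
#' @param outputs Character vector of files the stage wrote.
#' @param path Manifest destination (YAML).
#' @export
write_manifest <- function(stage, cfg, inputs, outputs, path) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("protpath")),
    global_seed = cfg$seed,
    stage_seed = derive_seed(cfg$seed, stage),
    config = cfg$raw,
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = as.character(outputs),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  yaml::write_yaml(manifest, path)
  invisible(path)
}
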