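#' Run the full synthetic-corpus pipeline from one configuration
#'
#' Orchestrates the end-to-end study on a synthetic corpus: generate ->
#' prepare (vocabulary, encoding, train/test split, partitioning) -> train
#' replicate models -> extract representations -> evaluate (balanced
#' accuracy, category structure, reliability) -> write report artifacts.
#' Every stage draws its seeds deterministically from `config$seed`, so a
#' rerun of the same configuration reproduces identical artifacts
#' (single-threaded).
#'
#' The configuration is a YAML file (or equivalent list) with blocks:
#' \describe{
#'   \item{generator}{arguments of [generator_config()]}
#'   \item{prep}{`vocab_size`, `n_partitions`, `test_fraction`}
#'   \item{models}{`architectures` (subset of srn/lstm/skipgram),
#'     `n_hidden`, `replicates`}
#'   \item{training}{arguments of [training_config()]}
#'   \item{seed}{master integer seed}
#' }
#'
#' @param config Path to a YAML config file, or the config as a list.
#' @param out_dir Output directory for artifacts (TSV/JSON).
#' @param resume Reuse existing artifact files when present.
#' @return The run manifest (list), invisibly written to
#'   `manifest.json`: config snapshot, seeds, package version, artifact
#'   checksums.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(cfg))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (resume && file.exists(manifest_path)) {
    return(invisible(jsonlite::read_json(manifest_path)))
  }
  seed <- as.integer(cfg$seed %||% 1L)

  gen_cfg <- do.call(generator_config,
                     c(cfg$generator %||% list(), list(seed = seed)))
  lexicon <- generate_lexicon(gen_cfg)
  gen <- generate_corpus(lexicon, gen_cfg)
  write_corpus_dir(gen$corpus, file.path(out_dir, "corpus"))
  utils::write.table(gen$probes, file.path(out_dir, "probes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  prep <- cfg$prep %||% list()
  vocab_size <- prep$vocab_size %||% 4096L
  n_partitions <- prep$n_partitions %||% 8L
  test_fraction <- prep$test_fraction %||% 0.1
  split <- split_train_test(gen$corpus, test_fraction, seed = seed + 1L)
  vocab <- build_vocabulary(split$train, size_limit = vocab_size)
  write_vocabulary_json(vocab, file.path(out_dir, "vocabulary.json"))
  train_ids <- encode_tokens(corpus_tokens(split$train), vocab)
  test_ids <- encode_tokens(corpus_tokens(split$test), vocab)
  parts <- partition_corpus(train_ids, n_partitions)

  models_cfg <- cfg$models %||% list()
  archs <- models_cfg$architectures %||% c("srn", "lstm", "skipgram")
  n_hidden <- models_cfg$n_hidden %||% 64L
  replicates <- models_cfg$replicates %||% 1L
  tr_cfg <- do.call(training_config,
                    cfg$training %||% list(local_iterations = 2L))

  probe_words <- intersect(gen$probes$word, vocab$words)
  probes <- gen$probes[gen$probes$word %in% probe_words, ]
  fits <- list()
  sims <- list()
  ba_rows <- list()
  for (arch in archs) {
    for (rep_i in seq_len(replicates)) {
      tag <- sprintf("%s_%d", arch, rep_i)
      w0 <- init_weights(arch, n_vocab = length(vocab$words),
                         n_hidden = n_hidden,
                         seed = seed + 100L * match(arch, archs) + rep_i)
      fit <- train_model(w0, parts, tr_cfg, seed = seed + rep_i)
      reps <- if (arch == "skipgram") {
        skipgram_reps(fit$weights, vocab,
                      counts = tabulate(train_ids, length(vocab$words)))
      } else {
        extract_contextual_reps(fit$weights, train_ids, vocab)
      }
      S <- similarity_matrix(reps, rows = probes$word)
      ba <- balanced_accuracy_sweep(S, probes)
      utils::write.table(
        ba$per_probe, file.path(out_dir, sprintf("balanced_accuracy_%s.tsv", tag)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      write_similarity_tsv(S, file.path(out_dir, sprintf("similarity_%s.tsv", tag)))
      fits[[tag]] <- fit
      sims[[tag]] <- S
      ba_rows[[tag]] <- data.frame(
        model = tag, arch = arch, replicate = rep_i,
        best_threshold = ba$best_threshold,
        mean_balanced_accuracy = ba$mean_balanced_accuracy)
      if (arch != "skipgram") {
        utils::write.table(
          fit$log, file.path(out_dir, sprintf("training_log_%s.tsv", tag)),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  ba_summary <- do.call(rbind, ba_rows)
  utils::write.table(ba_summary, file.path(out_dir, "balanced_accuracy_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  rel <- reliability_table(sims, vapply(strsplit(names(sims), "_"), `[[`, "", 1))
  utils::write.table(rel, file.path(out_dir, "reliability.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("cdslm")),
    seed = seed, config = cfg,
    artifacts = artifact_checksums(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_similarity_tsv <- function(S, path) {
  df <- data.frame(word = rownames(S), unclass(S), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Pairwise model reliability, labelled within- vs cross-architecture.
reliability_table <- function(sims, arch_of) {
  tags <- names(sims)
  rows <- list()
  if (length(tags) >= 2L) {
    for (i in seq_len(length(tags) - 1L)) {
      for (j in seq(i + 1L, length(tags))) {
        rows[[length(rows) + 1L]] <- data.frame(
          model_a = tags[i], model_b = tags[j],
          comparison = if (arch_of[i] == arch_of[j]) "within" else "cross",
          reliability = model_reliability(sims[[i]], sims[[j]]))
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(model_a = character(0), model_b = character(0),
               comparison = character(0), reliability = numeric(0))
}

artifact_checksums <- function(out_dir) {
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  stats::setNames(as.list(unname(sums)), files)
}
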