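# Shared fixtures and independent oracles used across test files.

# A small hand-built corpus of tokenized utterances.
toy_corpus <- function() {
  cds_corpus(list(
    cds_document("d2", 12, list(c("you", "want", "the", "ball", "?"),
                                c("the", "dog", "runs", "."))),
    cds_document("d1", 6, list(c("hi", "baby", "!"),
                               c("look", "at", "the", "dog", ".")))
  ))
}

# Initialized weights perturbed away from their (tiny) init values so
# gradient magnitudes are well away from zero.
rand_weights <- function(arch, n_vocab, n_hidden, seed = 42, sd = 0.3) {
  w <- init_weights(arch, n_vocab = n_vocab, n_hidden = n_hidden, seed = seed)
  set.seed(seed + 1)
  for (k in names(unclass(w))) {
    pert <- rnorm(length(w[[k]]), sd = sd)
    w[[k]] <- if (is.matrix(w[[k]])) w[[k]] + matrix(pert, nrow(w[[k]]))
              else w[[k]] + pert
  }
  w
}

# Central finite-difference gradient of a scalar function of the weights,
# for one weight entry.
fd_grad_entry <- function(loss_fn, w, k, idx, eps = 1e-5) {
  wp <- w; wp[[k]][idx] <- wp[[k]][idx] + eps
  wm <- w; wm[[k]][idx] <- wm[[k]][idx] - eps
  (loss_fn(wp) - loss_fn(wm)) / (2 * eps)
}

# Compare an analytic gradient list against central finite differences on
# every entry (or a sample of entries); returns the max relative error.
max_fd_rel_error <- function(loss_fn, w, grads, eps = 1e-5, sample_n = Inf) {
  max_rel <- 0
  for (k in names(unclass(w))) {
    idxs <- seq_along(w[[k]])
    if (length(idxs) > sample_n) {
      idxs <- sample(idxs, sample_n)
    }
    for (idx in idxs) {
      fd <- fd_grad_entry(loss_fn, w, k, idx, eps)
      an <- grads[[k]][idx]
      if (abs(fd) > 1e-10 || abs(an) > 1e-10) {
        max_rel <- max(max_rel, abs(fd - an) / max(abs(fd), abs(an)))
      }
    }
  }
  max_rel
}

# Exhaustive signal-detection sweep: the brute-force oracle for
# balanced_accuracy_sweep. Loops explicitly over probes, partners and
# thresholds.
brute_force_sweep <- function(S, probe_map, grid) {
  words <- names(probe_map)
  words <- words[vapply(words, function(w)
    sum(probe_map == probe_map[[w]]) > 1L &&
      any(probe_map != probe_map[[w]]), logical(1))]
  ba_by_thr <- numeric(length(grid))
  per_probe_by_thr <- matrix(NA_real_, length(words), length(grid))
  for (gi in seq_along(grid)) {
    r <- grid[gi]
    for (wi in seq_along(words)) {
      w <- words[wi]
      hits <- misses <- fa <- cr <- 0L
      for (x in words) {
        if (x == w) next
        s <- S[w, x]
        same <- probe_map[[x]] == probe_map[[w]]
        if (same && s > r) hits <- hits + 1L
        else if (same) misses <- misses + 1L
        else if (s > r) fa <- fa + 1L
        else cr <- cr + 1L
      }
      sens <- hits / (hits + misses)
      spec <- cr / (cr + fa)
      per_probe_by_thr[wi, gi] <- (sens + spec) / 2
    }
    ba_by_thr[gi] <- mean(per_probe_by_thr[, gi])
  }
  best <- which.max(ba_by_thr)
  list(best_threshold = grid[best], mean_balanced_accuracy = ba_by_thr[best],
       per_probe = per_probe_by_thr[, best])
}

# Representations object built directly from a plain matrix.
reps_from_matrix <- function(M) {
  structure(list(matrix = M, counts = rep(1L, nrow(M)), source = "manual"),
            class = "cds_reps")
}

# A quick synthetic corpus at reduced size for training smoke tests.
small_study <- function(seed = 7, n_categories = 2, words_per_category = 6,
                        tokens_per_document = 1500, n_documents = 4) {
  cfg <- generator_config(
    n_categories = n_categories, words_per_category = words_per_category,
    n_context_frames_per_category = 4, frame_overlap = 0,
    n_documents = n_documents, tokens_per_document = tokens_per_document,
    seed = seed)
  lex <- generate_lexicon(cfg)
  gen <- generate_corpus(lex, cfg)
  vocab <- build_vocabulary(gen$corpus, size_limit = 4096)
  ids <- encode_tokens(corpus_tokens(gen$corpus), vocab)
  list(cfg = cfg, lexicon = lex, corpus = gen$corpus, probes = gen$probes,
       vocab = vocab, ids = ids)
}

# Mean within-category minus between-category probe similarity.
category_contrast <- function(S, probes) {
  pm <- setNames(probes$category, probes$word)
  same <- outer(pm[rownames(S)], pm[colnames(S)], "==")
  diag(same) <- NA
  mean(S[which(same)]) - mean(S[which(!same)])
}
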