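#' Configuration for the synthetic child-directed-speech generator
#'
#' The generator emulates the corpus properties the models are sensitive to
#' without any linguistic realism beyond them: Zipfian unigram frequencies
#' over the planted target words, utterance-boundary punctuation tokens,
#' age-ordered documents, category-specific lexical context frames (so that
#' semantic categories are realized purely distributionally), and injectable
#' polysemy. Planted target words never occur as context words, so the
#' planted structure is recoverable from co-occurrence counts alone.
#'
#' @param n_categories Number of planted semantic categories.
#' @param words_per_category Target words per category.
#' @param n_context_frames_per_category Utterance templates per category.
#' @param frame_overlap Probability in `[0,1]` that a category's frame slot
#'   is filled from a pool shared by all categories (0 = fully disjoint
#'   contexts, 1 = one common frame pool).
#' @param zipf_exponent Exponent of the rank-frequency power law used to
#'   sample target words (1 = classic Zipf).
#' @param n_documents Number of documents; synthetic ages are the document
#'   indices, so documents are age-ordered by construction.
#' @param tokens_per_document Approximate tokens per document (documents end
#'   at the first utterance boundary at or after this count).
#' @param polysemy_rate Fraction in `[0,1]` of target words that are also
#'   assigned frames from a second category.
#' @param age_drift Degree in `[0,1]` to which the within-category frame
#'   mixture changes linearly from the first to the last document.
#' @param seed Integer seed; the generator is deterministic given the config.
#' @return An object of class `cds_generator_config`.
#' @export
generator_config <- function(n_categories = 10L, words_per_category = 8L,
                             n_context_frames_per_category = 6L,
                             frame_overlap = 0, zipf_exponent = 1,
                             n_documents = 20L, tokens_per_document = 10000L,
                             polysemy_rate = 0, age_drift = 0, seed = 1L) {
  stopifnot_scalar_count(n_categories, "n_categories")
  if (words_per_category < 1) {
    stop("`words_per_category` must be >= 1", call. = FALSE)
  }
  stopifnot_scalar_count(n_context_frames_per_category,
                         "n_context_frames_per_category")
  stopifnot_scalar_count(n_documents, "n_documents")
  stopifnot_scalar_count(tokens_per_document, "tokens_per_document")
  for (p in c(frame_overlap, polysemy_rate, age_drift)) {
    if (!is.numeric(p) || p < 0 || p > 1) {
      stop("probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!is.numeric(zipf_exponent) || zipf_exponent <= 0) {
    stop("`zipf_exponent` must be positive", call. = FALSE)
  }
  structure(
    list(n_categories = as.integer(n_categories),
         words_per_category = as.integer(words_per_category),
         n_context_frames_per_category = as.integer(n_context_frames_per_category),
         frame_overlap = frame_overlap, zipf_exponent = zipf_exponent,
         n_documents = as.integer(n_documents),
         tokens_per_document = as.integer(tokens_per_document),
         polysemy_rate = polysemy_rate, age_drift = age_drift,
         seed = as.integer(seed)),
    class = "cds_generator_config"
  )
}

# One frame: tokens before the target slot, tokens after it, terminal
# punctuation. Utterance = c(before, target, after, punct).
make_frame <- function(context_words, punct) {
  n_before <- sample(1:2, 1L)
  n_after <- sample(0:1, 1L)
  picks <- sample(context_words, n_before + n_after)
  list(before = picks[seq_len(n_before)],
       after = if (n_after > 0) picks[n_before + seq_len(n_after)] else character(0),
       punct = punct)
}

#' Generate a planted lexicon
#'
#' Builds target words grouped into categories, a set of context frames per
#' category (with `frame_overlap`-controlled sharing from a common pool),
#' and marks a `polysemy_rate` fraction of target words as polysemous by
#' assigning them a second category whose frames they may also occur in.
#' Target words and frame words are disjoint by construction.
#'
#' @param config A [generator_config()].
#' @return An object of class `cds_lexicon`: `target_words` (named character
#'   vector, word -> category), `frames` (category -> list of frames),
#'   `polysemous_words` (named character vector, word -> second category),
#'   `categories`.
#' @export
generate_lexicon <- function(config) {
  stopifnot(inherits(config, "cds_generator_config"))
  with_local_seed(config$seed, {
    K <- config$n_categories
    W <- config$words_per_category
    Fn <- config$n_context_frames_per_category
    categories <- sprintf("cat%02d", seq_len(K))
    words <- unlist(lapply(seq_len(K), function(k) sprintf("w%02d%02d", k, seq_len(W))))
    target_words <- stats::setNames(rep(categories, each = W), words)

    puncts <- c(".", "!", "?")
    shared_pool <- sprintf("sh%03d", seq_len(3L * Fn))
    shared_frames <- lapply(seq_len(Fn), function(j) {
      make_frame(shared_pool, sample(puncts, 1L))
    })
    frames <- stats::setNames(vector("list", K), categories)
    for (k in seq_len(K)) {
      own_pool <- sprintf("c%02d%02d", k, seq_len(3L * Fn))
      frames[[k]] <- lapply(seq_len(Fn), function(j) {
        if (stats::runif(1) < config$frame_overlap) {
          shared_frames[[j]]
        } else {
          make_frame(own_pool, sample(puncts, 1L))
        }
      })
    }
    n_poly <- floor(config$polysemy_rate * length(words))
    polysemous_words <- character(0)
    if (n_poly > 0) {
      poly <- sample(words, n_poly)
      second <- vapply(poly, function(w) {
        sample(setdiff(categories, target_words[[w]]), 1L)
      }, character(1))
      polysemous_words <- second
    }
    structure(
      list(target_words = target_words, frames = frames,
           polysemous_words = polysemous_words, categories = categories),
      class = "cds_lexicon"
    )
  })
}

# Sample a frame index for the given category under the document's
# age-interpolated mixture.
sample_frame_idx <- function(mix0, mix1, t, drift, n_frames) {
  mix <- (1 - t * drift) * mix0 + (t * drift) * mix1
  sample.int(n_frames, 1L, prob = mix)
}

render_utterance <- function(frame, word) {
  c(frame$before, word, frame$after, frame$punct)
}

#' Generate an age-ordered synthetic corpus with planted categories
#'
#' Emits `n_documents` documents with monotone synthetic ages (the document
#' index, in months). Each utterance embeds one target word — drawn with
#' Zipfian rank-frequency probabilities — into a frame of its category (or,
#' for polysemous words, of either of its two categories with equal
#' probability). Frame mixtures drift linearly with document age at rate
#' `age_drift`. Every utterance ends in a punctuation token.
#'
#' @param lexicon A [generate_lexicon()] result.
#' @param config The same [generator_config()].
#' @return List with `corpus` (a `cds_corpus`), `probes` (data.frame with
#'   columns `word`, `category`: the ground-truth probe file), and
#'   `zipf_ranks` (named integer vector of the rank assigned to each target
#'   word).
#' @export
generate_corpus <- function(lexicon, config) {
  stopifnot(inherits(lexicon, "cds_lexicon"),
            inherits(config, "cds_generator_config"))
  with_local_seed(config$seed + 1L, {
    words <- names(lexicon$target_words)
    n_words <- length(words)
    # Shuffle the rank assignment so frequency is not confounded with category.
    ranks <- stats::setNames(sample.int(n_words), words)
    probs <- (1 / as.numeric(ranks))^config$zipf_exponent
    probs <- probs / sum(probs)
    n_frames <- config$n_context_frames_per_category
    # Two endpoint frame mixtures per category; age drift interpolates.
    mix0 <- lapply(lexicon$categories, function(k) {
      m <- stats::rgamma(n_frames, 2); m / sum(m)
    })
    mix1 <- lapply(lexicon$categories, function(k) {
      m <- stats::rgamma(n_frames, 2); m / sum(m)
    })
    names(mix0) <- names(mix1) <- lexicon$categories
    docs <- vector("list", config$n_documents)
    denom <- max(1L, config$n_documents - 1L)
    for (d in seq_len(config$n_documents)) {
      t_age <- (d - 1) / denom
      utts <- list()
      n_tok <- 0L
      while (n_tok < config$tokens_per_document) {
        w <- words[sample.int(n_words, 1L, prob = probs)]
        cat_w <- lexicon$target_words[[w]]
        if (w %in% names(lexicon$polysemous_words) && stats::runif(1) < 0.5) {
          cat_w <- lexicon$polysemous_words[[w]]
        }
        fi <- sample_frame_idx(mix0[[cat_w]], mix1[[cat_w]], t_age,
                               config$age_drift, n_frames)
        utt <- render_utterance(lexicon$frames[[cat_w]][[fi]], w)
        utts[[length(utts) + 1L]] <- utt
        n_tok <- n_tok + length(utt)
      }
      docs[[d]] <- cds_document(sprintf("doc%04d", d), d, utts)
    }
    list(
      corpus = cds_corpus(docs),
      probes = data.frame(word = words,
                          category = unname(lexicon$target_words[words]),
                          stringsAsFactors = FALSE),
      zipf_ranks = ranks
    )
  })
}

#' Re-embed a fraction of a word's occurrences in another category's frames
#'
#' Injects polysemy post hoc: each utterance in which `word` occurs as the
#' embedded target is, with probability `rate`, regenerated from a frame of
#' `second_category` with the same word in the slot. The word's total
#' occurrence count is unchanged.
#'
#' @param corpus A token-string `cds_corpus` produced by [generate_corpus()].
#' @param lexicon The [generate_lexicon()] result that produced it.
#' @param word A target word of the lexicon.
#' @param second_category A category name from the lexicon.
#' @param rate Probability in `[0,1]` of re-embedding each occurrence.
#' @param seed Integer seed.
#' @return The modified `cds_corpus`.
#' @export
inject_polysemy <- function(corpus, lexicon, word, second_category, rate,
                            seed = 1L) {
  stopifnot(inherits(corpus, "cds_corpus"), inherits(lexicon, "cds_lexicon"))
  if (!word %in% names(lexicon$target_words)) {
    stop(sprintf("'%s' is not a target word of the lexicon", word),
         call. = FALSE)
  }
  if (!second_category %in% lexicon$categories) {
    stop(sprintf("unknown category '%s'", second_category), call. = FALSE)
  }
  if (rate < 0 || rate > 1) stop("`rate` must be in [0, 1]", call. = FALSE)
  if (rate == 0) return(corpus)
  frames2 <- lexicon$frames[[second_category]]
  with_local_seed(seed, {
    docs <- lapply(corpus$documents, function(d) {
      d$utterances <- lapply(d$utterances, function(u) {
        if (word %in% u && stats::runif(1) < rate) {
          render_utterance(frames2[[sample.int(length(frames2), 1L)]], word)
        } else u
      })
      d
    })
    structure(list(documents = docs, ordering_key = corpus$ordering_key),
              class = "cds_corpus")
  })
}

#' Fit the rank-frequency slope of selected words
#'
#' Least-squares slope of log10(frequency) on log10(rank) over the words'
#' empirical corpus frequencies, a quick check that generated unigram
#' frequencies follow the configured power law.
#'
#' @param corpus A token-string `cds_corpus`.
#' @param words Words whose rank-frequency relation to fit.
#' @return The fitted slope (about `-zipf_exponent` for generated corpora).
#' @export
zipf_slope <- function(corpus, words) {
  tokens <- corpus_tokens(corpus)
  counts <- table(factor(tokens[tokens %in% words], levels = words))
  counts <- sort(as.integer(counts), decreasing = TRUE)
  counts <- counts[counts > 0]
  rank <- seq_along(counts)
  unname(stats::coef(stats::lm(log10(counts) ~ log10(rank)))[2])
}
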