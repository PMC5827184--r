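#' Construct a document of child-directed speech
#'
#' A document is one transcript: an ordered set of utterances addressed to a
#' child of a known age. Utterances are stored pre-tokenized (one character
#' vector per utterance); sentence-boundary punctuation (`.`, `!`, `,`, `?`)
#' is kept as standalone tokens so models can use it as a crude cue to
#' utterance boundaries and prosody.
#'
#' @param doc_id Opaque document identifier (coerced to character).
#' @param age_months Non-negative age of the addressed child, in months.
#' @param utterances List of character vectors, one vector per utterance.
#' @return An object of class `cds_document`.
#' @export
cds_document <- function(doc_id, age_months, utterances) {
  if (!is.numeric(age_months) || length(age_months) != 1L || is.na(age_months) ||
      age_months < 0) {
    stop("`age_months` must be a single non-negative number", call. = FALSE)
  }
  if (!is.list(utterances)) utterances <- list(utterances)
  utterances <- lapply(utterances, as.character)
  if (any(vapply(utterances, function(u) any(!nzchar(u)), logical(1)))) {
    stop("utterances must contain no empty token strings", call. = FALSE)
  }
  structure(
    list(doc_id = as.character(doc_id), age_months = as.numeric(age_months),
         utterances = utterances),
    class = "cds_document"
  )
}

#' Construct an age-ordered corpus
#'
#' Documents are sorted non-decreasing by child age so that training can
#' present the input in an age-appropriate order (the speech a younger child
#' hears before the speech an older child hears). Age ties are broken by
#' `doc_id` to make the ordering total and builds reproducible.
#'
#' @param documents List of [cds_document] objects.
#' @return An object of class `cds_corpus` with elements `documents` and
#'   `ordering_key` (the age vector used for sorting).
#' @export
cds_corpus <- function(documents) {
  stopifnot(is.list(documents), length(documents) >= 1L)
  ages <- vapply(documents, function(d) d$age_months, numeric(1))
  ids <- vapply(documents, function(d) d$doc_id, character(1))
  ord <- order(ages, ids)
  structure(
    list(documents = documents[ord], ordering_key = ages[ord]),
    class = "cds_corpus"
  )
}

#' @export
print.cds_corpus <- function(x, ...) {
  n_utt <- sum(vapply(x$documents, function(d) length(d$utterances), integer(1)))
  cat(sprintf(
    "<cds_corpus> %d documents, %d utterances, %d tokens; ages %s-%s months\n",
    length(x$documents), n_utt, length(corpus_tokens(x)),
    format(min(x$ordering_key)), format(max(x$ordering_key))
  ))
  invisible(x)
}

#' Flatten a corpus to a single token stream
#'
#' Concatenates all utterances of all documents in age order. This is the
#' stream the sequence models consume.
#'
#' @param corpus A `cds_corpus` (token strings or an encoded corpus of ids).
#' @return A vector of tokens (character) or token ids (integer).
#' @export
corpus_tokens <- function(corpus) {
  stopifnot(inherits(corpus, "cds_corpus"))
  unlist(lapply(corpus$documents, function(d) unlist(d$utterances, use.names = FALSE)),
         use.names = FALSE)
}

#' Normalize and tokenize one utterance
#'
#' Lower-cases the line, splits on whitespace, and emits sentence-boundary
#' punctuation (`.`, `!`, `,`, `?`) as separate tokens. Spelling is
#' regularized through an alias table (e.g. `play-doh` -> `playdoh`), and
#' proper names are replaced by gender tokens `FNAME`/`MNAME` via a supplied
#' name list, so that individual names do not fragment the distributional
#' statistics.
#'
#' @param raw_text A single utterance line.
#' @param aliases Named character vector mapping variant spellings to their
#'   canonical form, applied after lower-casing.
#' @param name_genders Named character vector mapping lower-case names to
#'   `"female"` or `"male"`.
#' @return Character vector of tokens; an empty line yields `character(0)`.
#' @export
#' @examples
#' normalize_utterance("you want play-doh ?", aliases = c("play-doh" = "playdoh"))
#' normalize_utterance("hi Anne !", name_genders = c(anne = "female"))
normalize_utterance <- function(raw_text, aliases = NULL, name_genders = NULL) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  x <- tolower(raw_text)
  x <- gsub("([.!,?])", " \\1 ", x)
  tokens <- strsplit(trimws(x), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) return(character(0))
  if (!is.null(aliases) && length(aliases)) {
    hit <- tokens %in% names(aliases)
    tokens[hit] <- unname(aliases[tokens[hit]])
  }
  if (!is.null(name_genders) && length(name_genders)) {
    hit <- tokens %in% names(name_genders)
    tokens[hit] <- ifelse(name_genders[tokens[hit]] == "female", "FNAME", "MNAME")
  }
  tokens
}

# Suffix rules tried longest-first; each row: regex suffix, emitted morph token.
.morph_rules <- list(
  c("'s$",  "-'s"),
  c("s'$",  "-s'"),
  c("ing$", "-ing"),
  c("ed$",  "-ed"),
  c("es$",  "-es"),
  c("ie$",  "-ie"),
  c("y$",   "-y"),
  c("s$",   "-s")
)

#' Split inflectional and diminutive suffixes off tokens
#'
#' A rule-based morphological splitter: plural (`-s`, `-es`), possessive
#' (`-'s`, `-s'`), diminutive (`-ie`, `-y`), past tense (`-ed`) and ongoing
#' (`-ing`) endings are emitted as tokens of their own, immediately after the
#' stem. A suffix is only split when the remaining stem occurs in the
#' supplied stem lexicon, which doubles as the exception mechanism: words
#' whose apparent suffix is not inflectional (e.g. "bus") are simply never
#' split because "bu" is not a known stem. Non-matching tokens pass through
#' unchanged.
#'
#' @param tokens Character vector of normalized tokens.
#' @param stems Character vector of known stems the splitter may produce.
#' @return Character vector, possibly longer than the input.
#' @export
#' @examples
#' morph_split(c("dogs", "jumped", "the"), stems = c("dog", "jump"))
morph_split <- function(tokens, stems = character()) {
  stopifnot(is.character(tokens))
  if (length(tokens) == 0L) return(character(0))
  out <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    res <- tok
    for (rule in .morph_rules) {
      if (grepl(rule[[1]], tok)) {
        stem <- sub(rule[[1]], "", tok)
        if (nzchar(stem) && stem %in% stems) {
          res <- c(stem, rule[[2]])
          break
        }
      }
    }
    out[[i]] <- res
  }
  unlist(out, use.names = FALSE)
}

#' Build a frequency-ranked vocabulary
#'
#' Ranks word types by training-corpus frequency and keeps the most frequent
#' `size_limit - 1` of them; the reserved symbol `UNKNOWN` occupies the final
#' inventory slot so the model's input/output width equals `size_limit`
#' exactly. Frequency ties are broken lexicographically so builds are
#' deterministic. The `UNKNOWN` frequency is the total count of all replaced
#' (out-of-vocabulary) tokens, so recorded frequencies always sum to the
#' corpus token count.
#'
#' @param corpus A tokenized `cds_corpus`.
#' @param size_limit Total inventory size including `UNKNOWN` (default 4096).
#' @return An object of class `cds_vocabulary` with fields `words` (rank
#'   order, `UNKNOWN` last), `ids` (named integer map onto `1..n`),
#'   `frequencies`, `unknown_symbol` and `size_limit`.
#' @export
build_vocabulary <- function(corpus, size_limit = 4096L) {
  stopifnot(inherits(corpus, "cds_corpus"))
  if (!is.numeric(size_limit) || length(size_limit) != 1L || size_limit < 2) {
    stop("`size_limit` must be a single integer >= 2", call. = FALSE)
  }
  size_limit <- as.integer(size_limit)
  tokens <- corpus_tokens(corpus)
  tab <- table(tokens)
  counts <- as.integer(tab)
  types <- names(tab)
  ord <- order(-counts, types)
  counts <- counts[ord]
  types <- types[ord]
  n_keep <- min(length(types), size_limit - 1L)
  kept <- types[seq_len(n_keep)]
  kept_counts <- counts[seq_len(n_keep)]
  oov_count <- sum(counts) - sum(kept_counts)
  words <- c(kept, "UNKNOWN")
  freqs <- c(kept_counts, oov_count)
  ids <- seq_along(words)
  names(ids) <- words
  names(freqs) <- words
  structure(
    list(words = words, ids = ids, frequencies = freqs,
         unknown_symbol = "UNKNOWN", size_limit = size_limit),
    class = "cds_vocabulary"
  )
}

#' @export
print.cds_vocabulary <- function(x, ...) {
  cat(sprintf("<cds_vocabulary> %d words (limit %d), UNKNOWN count %d\n",
              length(x$words), x$size_limit,
              x$frequencies[[x$unknown_symbol]]))
  invisible(x)
}

#' Encode tokens as vocabulary ids
#'
#' Out-of-vocabulary tokens map to the id of the `UNKNOWN` symbol.
#'
#' @param tokens Character vector of tokens.
#' @param vocab A `cds_vocabulary`.
#' @return Integer vector of ids.
#' @export
encode_tokens <- function(tokens, vocab) {
  stopifnot(inherits(vocab, "cds_vocabulary"))
  ids <- vocab$ids[tokens]
  ids[is.na(ids)] <- vocab$ids[[vocab$unknown_symbol]]
  unname(ids)
}

#' Decode vocabulary ids back to tokens
#'
#' @param ids Integer vector of ids in `1..length(vocab$words)`.
#' @param vocab A `cds_vocabulary`.
#' @return Character vector of words.
#' @export
decode_tokens <- function(ids, vocab) {
  stopifnot(inherits(vocab, "cds_vocabulary"))
  if (any(ids < 1L | ids > length(vocab$words))) {
    stop("id out of vocabulary range", call. = FALSE)
  }
  vocab$words[ids]
}

#' Encode every document of a corpus
#'
#' Document order and utterance boundaries are preserved; only the tokens are
#' replaced by their ids (out-of-vocabulary tokens by the `UNKNOWN` id).
#'
#' @param corpus A tokenized `cds_corpus`.
#' @param vocab A `cds_vocabulary`.
#' @return A `cds_corpus` whose utterances hold integer ids.
#' @export
encode_corpus <- function(corpus, vocab) {
  stopifnot(inherits(corpus, "cds_corpus"))
  docs <- lapply(corpus$documents, function(d) {
    d$utterances <- lapply(d$utterances, encode_tokens, vocab = vocab)
    d
  })
  structure(list(documents = docs, ordering_key = corpus$ordering_key),
            class = "cds_corpus")
}

#' Split a corpus into training and testing corpora
#'
#' The split is at the document level (no document straddles both sides),
#' reproducible given `seed`, and both outputs retain age ordering.
#'
#' @param corpus A `cds_corpus` with at least two documents.
#' @param test_fraction Fraction of documents held out, in (0, 1).
#' @param seed Integer seed controlling which documents are held out.
#' @return List with elements `train` and `test`, both `cds_corpus`.
#' @export
split_train_test <- function(corpus, test_fraction, seed) {
  stopifnot(inherits(corpus, "cds_corpus"))
  n <- length(corpus$documents)
  if (n < 2L) stop("need at least 2 documents to split", call. = FALSE)
  if (!is.numeric(test_fraction) || length(test_fraction) != 1L ||
      test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  }
  n_test <- max(1L, min(n - 1L, round(test_fraction * n)))
  test_idx <- with_local_seed(seed, sort(sample.int(n, n_test)))
  list(
    train = cds_corpus(corpus$documents[-test_idx]),
    test = cds_corpus(corpus$documents[test_idx])
  )
}

#' Partition an encoded token stream for the local-iteration regime
#'
#' Splits the training stream into `n_partitions` consecutive, equal-length
#' partitions of `floor(N / n_partitions)` tokens; trailing remainder tokens
#' are dropped and their count reported. With the reference corpus size of
#' 5,244,672 tokens and 256 partitions each partition holds exactly 20,487
#' tokens.
#'
#' @param encoded_train Integer vector of token ids (the flattened, encoded,
#'   age-ordered training corpus).
#' @param n_partitions Number of partitions (default 256).
#' @return An object of class `cds_partitions`: `partitions` (list of integer
#'   vectors), `tokens_per_partition`, `n_partitions`, `n_dropped`.
#' @export
partition_corpus <- function(encoded_train, n_partitions = 256L) {
  n_partitions <- stopifnot_scalar_count(n_partitions, "n_partitions")
  n <- length(encoded_train)
  if (n < n_partitions) {
    stop("token stream shorter than the number of partitions", call. = FALSE)
  }
  size <- n %/% n_partitions
  used <- size * n_partitions
  parts <- split(encoded_train[seq_len(used)],
                 rep(seq_len(n_partitions), each = size))
  names(parts) <- NULL
  structure(
    list(partitions = parts, tokens_per_partition = size,
         n_partitions = n_partitions, n_dropped = n - used),
    class = "cds_partitions"
  )
}

#' @export
print.cds_partitions <- function(x, ...) {
  cat(sprintf("<cds_partitions> %d partitions x %d tokens (%d dropped)\n",
              x$n_partitions, x$tokens_per_partition, x$n_dropped))
  invisible(x)
}

#' Read a corpus from utterance text plus an age sidecar
#'
#' The on-disk interchange format is UTF-8 plain text with one utterance per
#' line per document file, and a tab-separated sidecar with columns
#' `doc_id` and `age_months`. `doc_id` names the utterance file (without
#' extension) inside `dir`.
#'
#' @param dir Directory holding `<doc_id>.txt` files and `ages.tsv`.
#' @param aliases,name_genders Passed to [normalize_utterance()].
#' @param stems Optional stem lexicon passed to [morph_split()]; when empty,
#'   no morphological splitting is attempted.
#' @return A tokenized `cds_corpus`.
#' @export
read_corpus_dir <- function(dir, aliases = NULL, name_genders = NULL,
                            stems = character()) {
  ages <- utils::read.delim(file.path(dir, "ages.tsv"), header = TRUE,
                            colClasses = c("character", "numeric"))
  docs <- lapply(seq_len(nrow(ages)), function(i) {
    lines <- readLines(file.path(dir, paste0(ages$doc_id[i], ".txt")),
                       encoding = "UTF-8")
    utts <- lapply(lines, normalize_utterance, aliases = aliases,
                   name_genders = name_genders)
    if (length(stems)) utts <- lapply(utts, morph_split, stems = stems)
    utts <- utts[lengths(utts) > 0L]
    cds_document(ages$doc_id[i], ages$age_months[i], utts)
  })
  cds_corpus(docs)
}

#' Write a corpus to the plain-text interchange format
#'
#' @param corpus A tokenized `cds_corpus`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus_dir <- function(corpus, dir) {
  stopifnot(inherits(corpus, "cds_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ages <- data.frame(
    doc_id = vapply(corpus$documents, function(d) d$doc_id, character(1)),
    age_months = vapply(corpus$documents, function(d) d$age_months, numeric(1))
  )
  utils::write.table(ages, file.path(dir, "ages.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (d in corpus$documents) {
    writeLines(vapply(d$utterances, paste, character(1), collapse = " "),
               file.path(dir, paste0(d$doc_id, ".txt")))
  }
  invisible(dir)
}

#' Write a vocabulary as JSON
#'
#' Format: `{word: {id, freq}, ...}`.
#'
#' @param vocab A `cds_vocabulary`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vocabulary_json <- function(vocab, path) {
  stopifnot(inherits(vocab, "cds_vocabulary"))
  obj <- lapply(vocab$words, function(w) {
    list(id = unname(vocab$ids[[w]]), freq = unname(vocab$frequencies[[w]]))
  })
  names(obj) <- vocab$words
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}
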