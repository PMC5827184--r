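#' Extract averaged contextual representations from a recurrent model
#'
#' Re-inputs the corpus into the trained model (without updating weights),
#' saving the hidden state at the end of every context window, and averages,
#' for each word, all states from windows whose final token is that word.
#' The result is one vector per vocabulary word — the word's contextual
#' representation, with its per-occurrence variability averaged out. Words
#' that never occur get an undefined (all-`NA`) row and an occurrence count
#' of zero.
#'
#' @param weights Trained `srn_weights` or `lstm_weights`.
#' @param ids Integer token-id stream (the encoded corpus).
#' @param vocab Optional `cds_vocabulary` used to label rows with words.
#' @param batch_size Windows per forward batch.
#' @return Object of class `cds_reps`: `matrix` (`n_vocab x n_hidden`, row
#'   names = words when `vocab` given), `counts`, `source`.
#' @export
extract_contextual_reps <- function(weights, ids, vocab = NULL,
                                    batch_size = 512L) {
  stopifnot(inherits(weights, "srn_weights") || inherits(weights, "lstm_weights"))
  check_token_ids(weights, ids)
  V <- attr(weights, "n_vocab")
  H <- attr(weights, "n_hidden")
  sums <- matrix(0, V, H)
  counts <- integer(V)
  n <- length(ids)
  for (start in seq(1L, n, by = batch_size)) {
    end <- min(start + batch_size - 1L, n)
    pos <- start:end
    wm <- build_window_matrix(ids, pos)
    fwd <- rnn_forward(weights, wm$X, wm$lens)
    last <- ids[pos]
    agg <- rowsum(t(fwd$h_final), group = last)
    rid <- as.integer(rownames(agg))
    sums[rid, ] <- sums[rid, , drop = FALSE] + agg
    tab <- tabulate(last, nbins = V)
    counts <- counts + tab
  }
  M <- sums / counts
  M[counts == 0L, ] <- NA_real_
  if (!is.null(vocab)) rownames(M) <- vocab$words
  structure(list(matrix = M, counts = counts, source = "hidden-average"),
            class = "cds_reps")
}

#' Per-occurrence hidden states for one word
#'
#' The un-averaged counterpart of [extract_contextual_reps()]: the final
#' hidden state of every window ending in `word_id`, one row per occurrence.
#' Useful for diagnosing polysemy — an unambiguous word's occurrence states
#' are nearly identical, a polysemous word's fall into distinct clusters.
#'
#' @inheritParams extract_contextual_reps
#' @param word_id Vocabulary id of the word of interest.
#' @return Matrix with one row per occurrence of the word.
#' @export
occurrence_states <- function(weights, ids, word_id, batch_size = 512L) {
  check_token_ids(weights, c(ids, word_id))
  pos <- which(ids == word_id)
  if (length(pos) == 0L) {
    return(matrix(numeric(0), 0L, attr(weights, "n_hidden")))
  }
  out <- matrix(NA_real_, length(pos), attr(weights, "n_hidden"))
  for (start in seq(1L, length(pos), by = batch_size)) {
    end <- min(start + batch_size - 1L, length(pos))
    wm <- build_window_matrix(ids, pos[start:end])
    fwd <- rnn_forward(weights, wm$X, wm$lens)
    out[start:end, ] <- t(fwd$h_final)
  }
  out
}

#' Skip-gram word representations
#'
#' A skip-gram word's representation is simply its input-embedding row: the
#' weights connecting the word's input unit to the hidden layer.
#'
#' @param weights `skipgram_weights`.
#' @param vocab Optional `cds_vocabulary` for row names.
#' @param counts Optional per-id corpus counts recorded alongside.
#' @return A `cds_reps` object with `source = "input-embedding"`.
#' @export
skipgram_reps <- function(weights, vocab = NULL, counts = NULL) {
  stopifnot(inherits(weights, "skipgram_weights"))
  M <- weights$W_in
  if (!is.null(vocab)) rownames(M) <- vocab$words
  if (is.null(counts)) counts <- rep(NA_integer_, nrow(M))
  structure(list(matrix = M, counts = counts, source = "input-embedding"),
            class = "cds_reps")
}

#' @export
print.cds_reps <- function(x, ...) {
  cat(sprintf("<cds_reps> %d x %d (%s), %d undefined rows\n",
              nrow(x$matrix), ncol(x$matrix), x$source,
              sum(rowSums(is.na(x$matrix)) > 0)))
  invisible(x)
}

resolve_rep_rows <- function(reps, words) {
  M <- reps$matrix
  if (is.character(words)) {
    if (is.null(rownames(M))) stop("representations have no word labels",
                                   call. = FALSE)
    missing <- setdiff(words, rownames(M))
    if (length(missing)) {
      stop(sprintf("words not in representation matrix: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  sub <- M[words, , drop = FALSE]
  undef <- rowSums(is.na(sub)) > 0
  if (any(undef)) {
    warning(sprintf("dropping %d words with undefined representations: %s",
                    sum(undef),
                    paste(utils::head(rownames(sub)[undef], 5), collapse = ", ")),
            call. = FALSE)
    sub <- sub[!undef, , drop = FALSE]
  }
  sub
}

#' Pairwise similarity matrix of word representations
#'
#' `S[i, j]` is the Pearson correlation (optionally Spearman) between the
#' representation vectors of row word `i` and column word `j`. Words with
#' undefined representations are dropped with a warning; zero-variance
#' vectors produce `NA` entries with a warning.
#'
#' @param reps A `cds_reps` object.
#' @param rows Character vector of row words (or integer ids when `reps` is
#'   unlabelled).
#' @param cols Column words; defaults to `rows` (square, symmetric form).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A similarity matrix with entries in `[-1, 1]`, dimnames set from
#'   the words, class `cds_similarity`.
#' @export
similarity_matrix <- function(reps, rows, cols = NULL,
                              method = c("pearson", "spearman")) {
  stopifnot(inherits(reps, "cds_reps"))
  method <- match.arg(method)
  A <- resolve_rep_rows(reps, rows)
  square <- is.null(cols)
  B <- if (square) A else resolve_rep_rows(reps, cols)
  sd_a <- apply(A, 1, stats::sd)
  sd_b <- if (square) sd_a else apply(B, 1, stats::sd)
  if (any(sd_a == 0) || any(sd_b == 0)) {
    warning("zero-variance representation vectors yield undefined entries",
            call. = FALSE)
  }
  S <- suppressWarnings(stats::cor(t(A), t(B), method = method))
  if (square) diag(S) <- 1
  class(S) <- c("cds_similarity", class(S))
  S
}

#' Inter-model reliability of two similarity matrices
#'
#' Correlates two models' flattened word-by-word similarity matrices — the
#' semantic-space analogue of inter-rater reliability. Entries whose row
#' word equals the column word (self-similarities, uninformatively 1) are
#' excluded before flattening.
#'
#' @param S_a,S_b Similarity matrices with identical dimnames (typically the
#'   probe-by-vocabulary form).
#' @param method Correlation method, `"pearson"` by default.
#' @return A single correlation coefficient.
#' @export
model_reliability <- function(S_a, S_b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!all(dim(S_a) == dim(S_b))) {
    stop("similarity matrices have different shapes", call. = FALSE)
  }
  if (!identical(dimnames(S_a), dimnames(S_b))) {
    stop("similarity matrices cover different word sets", call. = FALSE)
  }
  keep <- TRUE
  if (!is.null(rownames(S_a)) && !is.null(colnames(S_a))) {
    keep <- outer(rownames(S_a), colnames(S_a), "!=")
  }
  stats::cor(S_a[keep], S_b[keep], method = method,
             use = "pairwise.complete.obs")
}
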