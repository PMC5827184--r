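#' Enumerate skip-gram (center, context) training pairs
#'
#' For each position in the token stream, pairs the center token with every
#' token within `window_size` positions on either side, truncated at the
#' sequence ends. Pairs are ordered by center position, then context
#' position.
#'
#' @param ids Integer vector of token ids.
#' @param window_size Bidirectional window radius (default 3).
#' @return A two-column integer matrix with columns `center` and `context`.
#' @export
skipgram_pairs <- function(ids, window_size = 3L) {
  window_size <- stopifnot_scalar_count(window_size, "window_size")
  n <- length(ids)
  if (n < 2L) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("center", "context"))))
  }
  offsets <- c(seq(-window_size, -1L), seq_len(window_size))
  ctr_pos <- rep(seq_len(n), each = length(offsets))
  ctx_pos <- ctr_pos + rep(offsets, times = n)
  keep <- ctx_pos >= 1L & ctx_pos <= n
  cbind(center = ids[ctr_pos[keep]], context = ids[ctx_pos[keep]])
}

#' Negative-sampling objective and gradients for one pair
#'
#' The objective for a (center, context) pair with negatives `n_1..n_k` is
#' `-log sigma(u_ctx . v_c) - sum_j log sigma(-u_nj . v_c)`, where `v` rows
#' live in the input embeddings and `u` rows in the output embeddings.
#' Exposed with explicit negatives so the gradient can be checked against
#' finite differences on the same frozen sample.
#'
#' @param weights `skipgram_weights`.
#' @param center,context Token ids of the positive pair.
#' @param negatives Integer vector of sampled negative context ids.
#' @return List with `loss` and `grads` (full-shape `W_in`/`W_out` arrays).
#' @export
skipgram_gradients <- function(weights, center, context, negatives) {
  stopifnot(inherits(weights, "skipgram_weights"))
  check_token_ids(weights, c(center, context, negatives))
  v <- weights$W_in[center, ]
  u_pos <- weights$W_out[context, ]
  s_pos <- sigmoid(sum(u_pos * v))
  loss <- -log(s_pos)
  grads <- zero_grads(weights)
  dv <- (s_pos - 1) * u_pos
  grads$W_out[context, ] <- grads$W_out[context, ] + (s_pos - 1) * v
  for (ng in negatives) {
    u_neg <- weights$W_out[ng, ]
    s_neg <- sigmoid(sum(u_neg * v))
    loss <- loss - log(1 - s_neg)
    dv <- dv + s_neg * u_neg
    grads$W_out[ng, ] <- grads$W_out[ng, ] + s_neg * v
  }
  grads$W_in[center, ] <- grads$W_in[center, ] + dv
  list(loss = loss, grads = grads)
}

# Draw k negatives from `noise_probs`, excluding `exclude` (the true context
# word) by redrawing collisions.
sample_negatives <- function(k, noise_probs, exclude) {
  V <- length(noise_probs)
  neg <- sample.int(V, k, replace = TRUE, prob = noise_probs)
  for (tries in seq_len(100L)) {
    hit <- neg == exclude
    if (!any(hit)) break
    neg[hit] <- sample.int(V, sum(hit), replace = TRUE, prob = noise_probs)
  }
  neg
}

#' One stochastic-gradient step of skip-gram with negative sampling
#'
#' Samples `k_negatives` noise words from `noise_probs` (a distribution that
#' excludes the correct context word: collisions are redrawn) and applies
#' one SGD step of the negative-sampling objective.
#'
#' @param weights `skipgram_weights`.
#' @param center,context The positive training pair (token ids).
#' @param k_negatives Number of negative samples (default 5).
#' @param noise_probs Noise distribution over the vocabulary; defaults to
#'   uniform. A unigram distribution raised to the 3/4 power is the standard
#'   choice when corpus counts are available (see [unigram_noise()]).
#' @param learning_rate SGD step size.
#' @return The updated `skipgram_weights`.
#' @export
skipgram_update <- function(weights, center, context, k_negatives = 5L,
                            noise_probs = NULL, learning_rate = 0.025) {
  stopifnot(inherits(weights, "skipgram_weights"))
  V <- attr(weights, "n_vocab")
  if (is.null(noise_probs)) noise_probs <- rep(1 / V, V)
  negatives <- sample_negatives(k_negatives, noise_probs, context)
  res <- skipgram_gradients(weights, center, context, negatives)
  rows <- unique(c(center, context, negatives))
  weights$W_in[rows, ] <- weights$W_in[rows, ] -
    learning_rate * res$grads$W_in[rows, ]
  weights$W_out[rows, ] <- weights$W_out[rows, ] -
    learning_rate * res$grads$W_out[rows, ]
  weights
}

#' Smoothed unigram noise distribution
#'
#' Unigram frequencies raised to the 3/4 power and renormalized, the
#' standard negative-sampling noise distribution.
#'
#' @param counts Integer vector of per-id corpus counts (length `n_vocab`).
#' @param power Smoothing exponent (default 0.75).
#' @return Probability vector over ids.
#' @export
unigram_noise <- function(counts, power = 0.75) {
  w <- pmax(as.numeric(counts), 0)^power
  if (sum(w) == 0) stop("all counts are zero", call. = FALSE)
  w / sum(w)
}

# Vectorized mini-chunk trainer used by train_model.skipgram_weights.
# Processes `chunk` pairs at a time: per-pair gradients are computed in one
# BLAS sweep and aggregated per embedding row before being applied, a
# mini-batch analogue of the sequential SGNS update.
sgns_train_epochs <- function(weights, ids, window_size, n_epochs, k_negatives,
                              noise_probs, lr_start, lr_min, chunk = 256L) {
  pairs <- skipgram_pairs(ids, window_size)
  n <- nrow(pairs)
  if (n == 0L) return(list(weights = weights, log = data.frame()))
  V <- attr(weights, "n_vocab")
  total_chunks <- n_epochs * ceiling(n / chunk)
  done <- 0L
  log_loss <- numeric(n_epochs)
  for (ep in seq_len(n_epochs)) {
    ep_loss <- 0
    ep_preds <- 0L
    for (start in seq(1L, n, by = chunk)) {
      end <- min(start + chunk - 1L, n)
      ctr <- pairs[start:end, 1L]
      ctx <- pairs[start:end, 2L]
      m <- length(ctr)
      lr <- max(lr_min, lr_start * (1 - done / total_chunks))
      neg <- matrix(sample.int(V, m * k_negatives, replace = TRUE,
                               prob = noise_probs), m, k_negatives)
      coll <- which(neg == ctx)  # recycles ctx down columns
      if (length(coll)) {
        neg[coll] <- sample.int(V, length(coll), replace = TRUE,
                                prob = noise_probs)
      }
      Vc <- weights$W_in[ctr, , drop = FALSE]          # m x H
      Up <- weights$W_out[ctx, , drop = FALSE]         # m x H
      s_pos <- sigmoid(rowSums(Vc * Up))
      dv <- (s_pos - 1) * Up
      dUp <- (s_pos - 1) * Vc
      loss <- -sum(log(s_pos))
      dNeg <- vector("list", k_negatives)
      for (j in seq_len(k_negatives)) {
        Un <- weights$W_out[neg[, j], , drop = FALSE]
        s_neg <- sigmoid(rowSums(Vc * Un))
        loss <- loss - sum(log1p(-s_neg))
        dv <- dv + s_neg * Un
        dNeg[[j]] <- s_neg * Vc
      }
      g_in <- rowsum(dv, group = ctr)
      rid <- as.integer(rownames(g_in))
      weights$W_in[rid, ] <- weights$W_in[rid, , drop = FALSE] - lr * g_in
      out_rows <- c(ctx, as.vector(neg))
      g_out <- rowsum(rbind(dUp, do.call(rbind, dNeg)), group = out_rows)
      rid <- as.integer(rownames(g_out))
      weights$W_out[rid, ] <- weights$W_out[rid, , drop = FALSE] - lr * g_out
      done <- done + 1L
      ep_loss <- ep_loss + loss
      ep_preds <- ep_preds + m
    }
    log_loss[ep] <- ep_loss / ep_preds
  }
  list(weights = weights,
       log = data.frame(epoch = seq_len(n_epochs), mean_loss = log_loss))
}
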