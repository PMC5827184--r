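#' Initialize model weights
#'
#' Weights are drawn from a truncated normal distribution with mean zero and
#' nominal standard deviation `1/m`, where `m` is the number of units in the
#' layer the weights project to (the "layer above"): hidden-layer weights use
#' `1/n_hidden`, output-layer weights `1/n_vocab`. Draws are truncated at
#' plus/minus two standard deviations. The output bias is initialized to
#' exactly zero, as are all LSTM gate biases (an optional forget-gate bias
#' offset is available). Skip-gram output embeddings start at zero, the
#' convention of reference negative-sampling implementations, so a word's
#' representation before training is exactly its random input-embedding row.
#'
#' @param arch One of `"srn"`, `"lstm"`, `"skipgram"`.
#' @param n_vocab Vocabulary inventory size (input/output width).
#' @param n_hidden Hidden layer size.
#' @param seed Integer seed; initialization is deterministic given it.
#' @param forget_bias Constant added to the LSTM forget-gate bias (default 0).
#' @return A weight list of class `c("<arch>_weights", "cdslm_weights")` with
#'   attributes `n_vocab` and `n_hidden`.
#' @export
init_weights <- function(arch = c("srn", "lstm", "skipgram"), n_vocab, n_hidden,
                         seed = 1L, forget_bias = 0) {
  arch <- match.arg(arch)
  n_vocab <- stopifnot_scalar_count(n_vocab, "n_vocab", min = 2L)
  n_hidden <- stopifnot_scalar_count(n_hidden, "n_hidden")
  w <- with_local_seed(seed, {
    draw <- function(nrow, ncol, m) {
      matrix(rtrunc_normal(nrow * ncol, sd = 1 / m), nrow, ncol)
    }
    switch(arch,
      srn = list(
        W_in = draw(n_vocab, n_hidden, n_hidden),
        W_rec = draw(n_hidden, n_hidden, n_hidden),
        W_out = draw(n_hidden, n_vocab, n_vocab),
        b_out = numeric(n_vocab)
      ),
      lstm = {
        gates <- c("i", "f", "o", "g")
        w <- list()
        for (gt in gates) w[[paste0("W_", gt)]] <- draw(n_vocab, n_hidden, n_hidden)
        for (gt in gates) w[[paste0("U_", gt)]] <- draw(n_hidden, n_hidden, n_hidden)
        for (gt in gates) w[[paste0("b_", gt)]] <- numeric(n_hidden)
        w$b_f <- w$b_f + forget_bias
        w$W_out <- draw(n_hidden, n_vocab, n_vocab)
        w$b_out <- numeric(n_vocab)
        w
      },
      skipgram = list(
        W_in = draw(n_vocab, n_hidden, n_hidden),
        W_out = matrix(0, n_vocab, n_hidden)
      )
    )
  })
  structure(w, class = c(paste0(arch, "_weights"), "cdslm_weights"),
            n_vocab = n_vocab, n_hidden = n_hidden)
}

#' @export
print.cdslm_weights <- function(x, ...) {
  cat(sprintf("<%s> |V| = %d, H = %d, %d parameters\n",
              class(x)[1], attr(x, "n_vocab"), attr(x, "n_hidden"),
              sum(vapply(unclass(x), length, integer(1)))))
  invisible(x)
}

check_token_ids <- function(weights, token_id) {
  V <- attr(weights, "n_vocab")
  if (any(token_id < 1L | token_id > V) || any(is.na(token_id))) {
    stop("token id out of vocabulary range", call. = FALSE)
  }
}

#' One SRN recurrence step
#'
#' The hidden state is `tanh(W_in[x, ] + t(W_rec) %*% h_prev)`: the current
#' word's input weights plus the recurrently weighted previous hidden state,
#' squashed into (-1, 1) by the hyperbolic tangent.
#'
#' @param weights `srn_weights` from [init_weights()].
#' @param token_id Current input token id.
#' @param h_prev Previous hidden state (length `n_hidden`).
#' @return The new hidden state vector.
#' @export
srn_step <- function(weights, token_id, h_prev) {
  stopifnot(inherits(weights, "srn_weights"),
            length(h_prev) == attr(weights, "n_hidden"))
  check_token_ids(weights, token_id)
  tanh(weights$W_in[token_id, ] + drop(crossprod(weights$W_rec, h_prev)))
}

#' One LSTM recurrence step
#'
#' Input, forget and output gates are sigmoids of affine functions of the
#' current input and the previous gated output; the memory cell accumulates
#' `forget * cell_prev + input * tanh(candidate)` without any squashing of
#' its own, and the gated output is `output_gate * tanh(cell)`.
#'
#' @param weights `lstm_weights` from [init_weights()].
#' @param token_id Current input token id.
#' @param state_prev List with elements `cell` and `output`, each length
#'   `n_hidden`.
#' @return List with the new `cell` and `output`.
#' @export
lstm_step <- function(weights, token_id, state_prev) {
  stopifnot(inherits(weights, "lstm_weights"))
  check_token_ids(weights, token_id)
  h <- state_prev$output
  gate <- function(W, U, b) drop(W[token_id, ] + crossprod(U, h) + b)
  i <- sigmoid(gate(weights$W_i, weights$U_i, weights$b_i))
  f <- sigmoid(gate(weights$W_f, weights$U_f, weights$b_f))
  o <- sigmoid(gate(weights$W_o, weights$U_o, weights$b_o))
  g <- tanh(gate(weights$W_g, weights$U_g, weights$b_g))
  cell <- f * state_prev$cell + i * g
  list(cell = cell, output = o * tanh(cell))
}

#' Next-word probability distribution from a hidden state
#'
#' Softmax of the output-layer logits `t(W_out) %*% hidden + b_out`, with
#' max-subtraction for numerical stability. Accepts a single hidden vector
#' or an `n_hidden x B` matrix of states (one column per sequence).
#'
#' @param weights `srn_weights` or `lstm_weights`.
#' @param hidden Hidden state vector or matrix.
#' @return A probability vector over the vocabulary (or a `n_vocab x B`
#'   matrix of column distributions).
#' @export
output_distribution <- function(weights, hidden) {
  z <- crossprod(weights$W_out, hidden) + weights$b_out
  if (is.matrix(z) && ncol(z) > 1L) {
    z <- sweep(z, 2, apply(z, 2, max))
    e <- exp(z)
    sweep(e, 2, colSums(e), "/")
  } else {
    z <- drop(z)
    e <- exp(z - max(z))
    e / sum(e)
  }
}

# ---- Batched window machinery ------------------------------------------
# A training example is a context window: the current word and up to six
# predecessors (length min(7, position)), plus the following word as the
# prediction target. Windows are right-aligned in a 7 x B id matrix; column
# b is inactive at steps <= 7 - lens[b], during which its hidden state is
# held at the reset value (zero) -- equivalent to starting the short window
# from a reset state.

window_span <- function() 7L

# positions: indices t of the *current* word; the window covers t-6..t.
build_window_matrix <- function(ids, positions) {
  S <- window_span()
  idx <- outer(seq(-S + 1L, 0L), positions, "+")
  lens <- pmin(positions, S)
  X <- matrix(ids[pmax(idx, 1L)], nrow = S)
  list(X = X, lens = as.integer(lens))
}

active_mask <- function(lens, s) s > window_span() - lens

# Forward pass for a batch of right-aligned windows.
# Returns hidden states per step and (for lstm) gate caches, needed by the
# matching backward pass.
rnn_forward <- function(weights, X, lens) {
  UseMethod("rnn_forward")
}

#' @export
rnn_forward.srn_weights <- function(weights, X, lens) {
  S <- nrow(X); B <- ncol(X); H <- attr(weights, "n_hidden")
  h <- matrix(0, H, B)
  Hs <- vector("list", S)
  for (s in seq_len(S)) {
    act <- active_mask(lens, s)
    h_new <- tanh(t(weights$W_in[X[s, ], , drop = FALSE]) +
                    crossprod(weights$W_rec, h))
    h_new[, !act] <- 0
    h <- h_new
    Hs[[s]] <- h
  }
  list(H = Hs, h_final = h)
}

#' @export
rnn_forward.lstm_weights <- function(weights, X, lens) {
  S <- nrow(X); B <- ncol(X); H <- attr(weights, "n_hidden")
  h <- matrix(0, H, B); cc <- matrix(0, H, B)
  cache <- vector("list", S)
  for (s in seq_len(S)) {
    act <- active_mask(lens, s)
    xs <- X[s, ]
    pre <- function(W, U, b) t(W[xs, , drop = FALSE]) + crossprod(U, h) + b
    gi <- sigmoid(pre(weights$W_i, weights$U_i, weights$b_i))
    gf <- sigmoid(pre(weights$W_f, weights$U_f, weights$b_f))
    go <- sigmoid(pre(weights$W_o, weights$U_o, weights$b_o))
    gg <- tanh(pre(weights$W_g, weights$U_g, weights$b_g))
    c_new <- gf * cc + gi * gg
    c_new[, !act] <- 0
    tc <- tanh(c_new)
    h_new <- go * tc
    h_new[, !act] <- 0
    cache[[s]] <- list(i = gi, f = gf, o = go, g = gg,
                       c_prev = cc, h_prev = h, c = c_new, tanh_c = tc)
    cc <- c_new
    h <- h_new
    cache[[s]]$h <- h
  }
  list(H = lapply(cache, `[[`, "h"), h_final = h, cache = cache)
}

zero_grads <- function(weights) {
  g <- lapply(unclass(weights), function(w) {
    if (is.matrix(w)) matrix(0, nrow(w), ncol(w)) else numeric(length(w))
  })
  attributes(g) <- attributes(weights)
  g
}

# Scatter-add t(dpre) (B x H) into rows `ids` of grad matrix G (V x H).
scatter_add_rows <- function(G, ids, dpre_t) {
  agg <- rowsum(dpre_t, group = ids)
  rid <- as.integer(rownames(agg))
  G[rid, ] <- G[rid, , drop = FALSE] + agg
  G
}

# dZ for the softmax cross-entropy at a set of (unit, column) targets,
# scaled per column.
softmax_delta <- function(P, targets, col_scale) {
  dZ <- sweep(P, 2, col_scale, "*")
  dZ[cbind(targets, seq_len(ncol(P)))] <-
    dZ[cbind(targets, seq_len(ncol(P)))] - col_scale
  dZ
}

# Batched loss + gradients for recurrent models. Returns the mean per-window
# loss and gradients of that mean. When all_steps = TRUE every step of the
# window predicts its following token and the per-window loss is the mean
# over its predictions; by default only the final step's prediction of
# `targets` incurs loss (one prediction error per word).
rnn_window_grads <- function(weights, X, lens, targets, all_steps = FALSE,
                             loss_only = FALSE) {
  S <- nrow(X); B <- ncol(X)
  fwd <- rnn_forward(weights, X, lens)
  n_preds <- if (all_steps) lens else rep(1L, B)
  # Predictions at step s target X[s+1, ] for s < S, `targets` at s = S.
  step_targets <- function(s) if (s == S) targets else X[s + 1L, ]
  step_valid <- function(s) {
    if (s == S) rep(TRUE, B) else active_mask(lens, s)
  }
  P_by_step <- list()
  loss_tot <- numeric(B)
  steps <- if (all_steps) seq_len(S) else S
  for (s in steps) {
    P <- output_distribution(weights, fwd$H[[s]])
    if (!is.matrix(P)) P <- matrix(P, ncol = 1L)
    P_by_step[[s]] <- P
    valid <- step_valid(s)
    tg <- step_targets(s)
    nll <- -log(P[cbind(tg, seq_len(B))])
    loss_tot <- loss_tot + ifelse(valid, nll, 0)
  }
  loss_per_window <- loss_tot / n_preds
  mean_loss <- mean(loss_per_window)
  if (loss_only) return(list(loss = mean_loss, per_window = loss_per_window))

  grads <- zero_grads(weights)
  # dh carried backwards through time; output-layer contribution added at
  # each step that incurred loss.
  H_mat <- attr(weights, "n_hidden")
  dh <- matrix(0, H_mat, B)
  if (inherits(weights, "lstm_weights")) dc <- matrix(0, H_mat, B)
  for (s in rev(seq_len(S))) {
    if (s %in% steps) {
      valid <- step_valid(s)
      scale <- ifelse(valid, 1 / (n_preds * B), 0)
      dZ <- softmax_delta(P_by_step[[s]], step_targets(s), scale)
      grads$W_out <- grads$W_out + fwd$H[[s]] %*% t(dZ)
      grads$b_out <- grads$b_out + rowSums(dZ)
      dh <- dh + weights$W_out %*% dZ
    }
    act <- active_mask(lens, s)
    if (inherits(weights, "srn_weights")) {
      dpre <- dh * (1 - fwd$H[[s]]^2)
      dpre[, !act] <- 0
      h_prev <- if (s > 1L) fwd$H[[s - 1L]] else matrix(0, H_mat, B)
      grads$W_rec <- grads$W_rec + h_prev %*% t(dpre)
      grads$W_in <- scatter_add_rows(grads$W_in, X[s, ], t(dpre))
      dh <- weights$W_rec %*% dpre
    } else {
      cs <- fwd$cache[[s]]
      dh_m <- dh
      dh_m[, !act] <- 0
      do_ <- dh_m * cs$tanh_c
      dc <- dc + dh_m * cs$o * (1 - cs$tanh_c^2)
      dc[, !act] <- 0
      df <- dc * cs$c_prev
      di <- dc * cs$g
      dg <- dc * cs$i
      dc_prev <- dc * cs$f
      dpre_i <- di * cs$i * (1 - cs$i)
      dpre_f <- df * cs$f * (1 - cs$f)
      dpre_o <- do_ * cs$o * (1 - cs$o)
      dpre_g <- dg * (1 - cs$g^2)
      dpre_i[, !act] <- 0; dpre_f[, !act] <- 0
      dpre_o[, !act] <- 0; dpre_g[, !act] <- 0
      hp <- cs$h_prev
      grads$U_i <- grads$U_i + hp %*% t(dpre_i)
      grads$U_f <- grads$U_f + hp %*% t(dpre_f)
      grads$U_o <- grads$U_o + hp %*% t(dpre_o)
      grads$U_g <- grads$U_g + hp %*% t(dpre_g)
      grads$W_i <- scatter_add_rows(grads$W_i, X[s, ], t(dpre_i))
      grads$W_f <- scatter_add_rows(grads$W_f, X[s, ], t(dpre_f))
      grads$W_o <- scatter_add_rows(grads$W_o, X[s, ], t(dpre_o))
      grads$W_g <- scatter_add_rows(grads$W_g, X[s, ], t(dpre_g))
      grads$b_i <- grads$b_i + rowSums(dpre_i)
      grads$b_f <- grads$b_f + rowSums(dpre_f)
      grads$b_o <- grads$b_o + rowSums(dpre_o)
      grads$b_g <- grads$b_g + rowSums(dpre_g)
      dh <- weights$U_i %*% dpre_i + weights$U_f %*% dpre_f +
        weights$U_o %*% dpre_o + weights$U_g %*% dpre_g
      dc <- dc_prev
    }
  }
  list(loss = mean_loss, per_window = loss_per_window, grads = grads)
}

as_window <- function(window) {
  window <- as.integer(window)
  if (length(window) < 1L || length(window) > window_span()) {
    stop("window must hold 1 to 7 token ids", call. = FALSE)
  }
  window
}

#' Cross-entropy loss of one context window
#'
#' Runs the recurrence from a reset state across the window (the current
#' word and up to six predecessors) and scores the prediction of `target`,
#' the token following the window: `loss = -ln p(target)` at the final step.
#' With `all_steps = TRUE` every step additionally predicts its following
#' window token and the loss is the mean over the window's predictions.
#'
#' @param weights `srn_weights` or `lstm_weights`.
#' @param window Integer vector of 1 to 7 token ids, oldest first.
#' @param target Id of the token following the window.
#' @param all_steps Score every step's prediction instead of only the last.
#' @return The scalar loss (natural-log cross-entropy).
#' @export
window_loss <- function(weights, window, target, all_steps = FALSE) {
  window <- as_window(window)
  check_token_ids(weights, c(window, target))
  S <- window_span()
  X <- matrix(c(rep(1L, S - length(window)), window), ncol = 1L)
  res <- rnn_window_grads(weights, X, length(window), as.integer(target),
                          all_steps = all_steps, loss_only = TRUE)
  res$loss
}

#' Gradients of the window loss (truncated BPTT)
#'
#' Backpropagation through time across the (at most 7-step) window, giving
#' the gradient of [window_loss()] with respect to every weight array.
#'
#' @inheritParams window_loss
#' @return A list of gradient arrays matching the weight shapes.
#' @export
backprop_window <- function(weights, window, target, all_steps = FALSE) {
  window <- as_window(window)
  check_token_ids(weights, c(window, target))
  S <- window_span()
  X <- matrix(c(rep(1L, S - length(window)), window), ncol = 1L)
  res <- rnn_window_grads(weights, X, length(window), as.integer(target),
                          all_steps = all_steps)
  res$grads
}
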