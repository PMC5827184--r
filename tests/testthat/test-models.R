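test_that("initialization is seeded, truncated, and zero-biased", {
  w1 <- init_weights("srn", n_vocab = 100, n_hidden = 20, seed = 4)
  w2 <- init_weights("srn", n_vocab = 100, n_hidden = 20, seed = 4)
  expect_identical(w1, w2)
  w3 <- init_weights("srn", n_vocab = 100, n_hidden = 20, seed = 5)
  expect_false(identical(w1$W_in, w3$W_in))

  expect_identical(w1$b_out, numeric(100))
  lw <- init_weights("lstm", n_vocab = 20, n_hidden = 8, seed = 1)
  expect_identical(lw$b_out, numeric(20))
  expect_identical(lw$b_i, numeric(8))
  lw2 <- init_weights("lstm", n_vocab = 20, n_hidden = 8, seed = 1,
                      forget_bias = 1)
  expect_identical(lw2$b_f, rep(1, 8))

  # nominal sd 1/m for the layer above; draws truncated at +/- 2 sd, which
  # shrinks the realized sd to ~0.8796/m
  big <- init_weights("srn", n_vocab = 512, n_hidden = 256, seed = 2)
  m_out <- 512
  expect_true(all(abs(big$W_out) <= 2 / m_out + 1e-12))
  shrink <- sqrt(1 - 4 * dnorm(2) / (pnorm(2) - pnorm(-2)))
  expect_lt(abs(sd(big$W_out) - shrink / m_out) / (shrink / m_out), 0.05)
  m_hid <- 256
  expect_lt(abs(sd(big$W_in) - shrink / m_hid) / (shrink / m_hid), 0.05)

  # skip-gram output embeddings start at zero: a word's representation
  # before training is its input row
  sg <- init_weights("skipgram", n_vocab = 30, n_hidden = 8, seed = 3)
  expect_identical(sg$W_out, matrix(0, 30, 8))
})

test_that("srn_step computes tanh recurrence and stays inside (-1, 1)", {
  w <- init_weights("srn", n_vocab = 2, n_hidden = 1, seed = 1)
  w$W_in[] <- 0; w$W_rec[] <- 0
  expect_identical(srn_step(w, 1L, 0), 0)

  # hand computation: h = tanh(w_in + w_rec * h_prev) = tanh(1 + 0.5 * 0.2)
  w$W_in[1, 1] <- 1; w$W_rec[1, 1] <- 0.5
  expect_equal(srn_step(w, 1L, 0.2), tanh(1.1))

  w2 <- rand_weights("srn", 10, 4, seed = 8, sd = 2)
  h <- runif(4)
  expect_true(all(abs(srn_step(w2, 3L, h)) < 1))
  expect_error(srn_step(w2, 99L, h), "out of vocabulary")
})

test_that("lstm gates control cell read/write as designed", {
  H <- 3
  w <- init_weights("lstm", n_vocab = 5, n_hidden = H, seed = 2)
  state <- list(cell = c(1, -2, 0.5), output = c(0.1, 0.2, -0.1))

  # forget gate forced to zero flushes the cell
  w0 <- w; w0$b_f[] <- -1e9
  s1 <- lstm_step(w0, 2L, state)
  s2 <- lstm_step(w0, 2L, list(cell = c(-5, 5, 9), output = state$output))
  expect_equal(s1$cell, s2$cell)

  # input gate forced to zero makes cell = forget * cell_prev exactly
  wi <- rand_weights("lstm", 5, H, seed = 3); wi$b_i[] <- -1e9
  s <- lstm_step(wi, 2L, state)
  f <- 1 / (1 + exp(-(wi$W_f[2, ] + drop(crossprod(wi$U_f, state$output)) + wi$b_f)))
  expect_equal(s$cell, f * state$cell, tolerance = 1e-6)

  # all-zero weights: every gate is sigmoid(0) = 0.5, candidate tanh(0) = 0
  wz <- w
  for (k in names(unclass(wz))) wz[[k]][] <- 0
  s <- lstm_step(wz, 1L, state)
  expect_equal(s$cell, 0.5 * state$cell)
  expect_equal(s$output, 0.5 * tanh(0.5 * state$cell))

  # gates open (biases large positive): the cell is an unbounded accumulator
  wa <- wz; wa$b_i[] <- 1e9; wa$b_f[] <- 1e9; wa$b_o[] <- 1e9
  wa$W_g[] <- 1e9  # candidate saturates at tanh = 1
  st <- list(cell = numeric(H), output = numeric(H))
  for (i in 1:10) st <- lstm_step(wa, 1L, st)
  expect_equal(st$cell, rep(10, H))
})

test_that("output_distribution is a proper, shift-invariant softmax", {
  w <- init_weights("srn", n_vocab = 6, n_hidden = 3, seed = 1)
  w$W_out[] <- 0; w$b_out[] <- 0
  p <- output_distribution(w, c(1, 2, 3))
  expect_equal(p, rep(1 / 6, 6))

  # logits (0, ln 3) -> (0.25, 0.75)
  w2 <- init_weights("srn", n_vocab = 2, n_hidden = 1, seed = 1)
  w2$W_out[] <- 0
  w2$b_out <- c(0, log(3))
  expect_equal(output_distribution(w2, 0), c(0.25, 0.75))

  # arbitrary finite logits: positive, sums to 1, shift-invariant
  set.seed(5)
  w3 <- rand_weights("srn", 8, 4, seed = 5, sd = 3)
  h <- rnorm(4)
  p3 <- output_distribution(w3, h)
  expect_true(all(p3 > 0))
  expect_lt(abs(sum(p3) - 1), 1e-12)
  w3b <- w3; w3b$b_out <- w3$b_out + 123.4
  expect_equal(output_distribution(w3b, h), p3)
})

test_that("window loss equals the negative log probability of the target", {
  # uniform model over V symbols -> loss ln V
  w <- init_weights("srn", n_vocab = 4096, n_hidden = 2, seed = 1)
  for (k in c("W_in", "W_rec", "W_out", "b_out")) w[[k]][] <- 0
  expect_equal(window_loss(w, c(5L, 9L), 17L), log(4096))

  # two equally likely words -> loss ln 2
  w2 <- init_weights("srn", n_vocab = 2, n_hidden = 2, seed = 1)
  for (k in c("W_in", "W_rec", "W_out", "b_out")) w2[[k]][] <- 0
  expect_equal(window_loss(w2, 1L, 2L), log(2))

  # a model assigning p(target) ~ 1 -> loss ~ 0
  w3 <- w2; w3$b_out <- c(0, 200)
  expect_lt(window_loss(w3, 1L, 2L), 1e-10)

  # all-steps variant averages the per-step prediction losses
  w4 <- rand_weights("srn", 6, 3, seed = 9)
  win <- c(2L, 4L, 1L)
  manual <- mean(c(
    window_loss(w4, win[1], win[2]),
    window_loss(w4, win[1:2], win[3]),
    window_loss(w4, win, 5L)
  ))
  expect_equal(window_loss(w4, win, 5L, all_steps = TRUE), manual)
})

test_that("skipgram_pairs enumerates clipped bidirectional windows in order", {
  a <- 1L; b <- 2L; c_ <- 3L; d <- 4L
  p <- skipgram_pairs(c(a, b, c_), window_size = 1)
  expect_identical(unname(p),
                   rbind(c(a, b), c(b, a), c(b, c_), c(c_, b)))
  expect_identical(nrow(skipgram_pairs(c(a), window_size = 2)), 0L)
  expect_identical(nrow(skipgram_pairs(c(a, b, c_, d), window_size = 3)), 12L)
  # every pair is within the window radius
  set.seed(3)
  ids <- sample.int(5, 40, replace = TRUE)
  p <- skipgram_pairs(ids, 3)
  expect_identical(nrow(p), sum(vapply(seq_along(ids), function(t) {
    length(intersect(seq_along(ids), (t - 3):(t + 3))) - 1L
  }, integer(1))))
})

test_that("skipgram updates move embeddings and respect a zero learning rate", {
  w <- rand_weights("skipgram", 8, 3, seed = 11)
  w_same <- skipgram_update(w, 2L, 5L, k_negatives = 3, learning_rate = 0)
  expect_equal(w_same$W_in, w$W_in)
  expect_equal(w_same$W_out, w$W_out)

  set.seed(1)
  w_up <- skipgram_update(w, 2L, 5L, k_negatives = 3, learning_rate = 0.1)
  expect_false(identical(w_up$W_in[2, ], w$W_in[2, ]))
  # only touched rows change
  expect_equal(w_up$W_in[c(1, 3, 4), ], w$W_in[c(1, 3, 4), ])
})

test_that("skipgram separates two planted categories on a toy stream", {
  # two "categories" of words, each co-occurring only with its own context
  set.seed(42)
  ids <- integer(0)
  for (i in 1:400) {
    if (runif(1) < 0.5) ids <- c(ids, sample(1:3, 1), sample(7:8, 1))
    else ids <- c(ids, sample(4:6, 1), sample(9:10, 1))
  }
  w <- init_weights("skipgram", 10, 8, seed = 2)
  cfg <- training_config(local_iterations = 1, sg_n_epochs = 10,
                         sg_window_size = 1)
  fit <- train_model(w, ids, cfg, seed = 3)
  emb <- fit$weights$W_in[1:6, ]
  S <- cor(t(emb))
  within <- mean(S[1:3, 1:3][upper.tri(S[1:3, 1:3])])
  within <- mean(c(within, mean(S[4:6, 4:6][upper.tri(S[4:6, 4:6])])))
  between <- mean(S[1:3, 4:6])
  expect_gt(within, between)
})
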