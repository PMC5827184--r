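test_that("perplexity matches its closed forms", {
  # perfect predictor: probability ~1 on the constant next word
  w <- init_weights("srn", n_vocab = 3, n_hidden = 2, seed = 1)
  for (k in c("W_in", "W_rec", "W_out")) w[[k]][] <- 0
  w$b_out <- c(0, 400, 0)
  ids <- rep(2L, 200)
  expect_equal(perplexity(w, ids), 1, tolerance = 1e-9)

  # uniform over 50 equally likely words scores 50
  w50 <- init_weights("srn", n_vocab = 50, n_hidden = 4, seed = 1)
  for (k in c("W_in", "W_rec", "W_out", "b_out")) w50[[k]][] <- 0
  set.seed(2)
  ids <- sample.int(50, 500, replace = TRUE)
  expect_equal(perplexity(w50, ids), 50, tolerance = 1e-9)

  # constant-probability predictor: ppl = 1/p exactly
  wp <- init_weights("srn", n_vocab = 4, n_hidden = 2, seed = 1)
  for (k in c("W_in", "W_rec", "W_out")) wp[[k]][] <- 0
  wp$b_out <- log(c(0.4, 0.3, 0.2, 0.1))
  ids <- rep(1L, 100)
  expect_equal(perplexity(wp, ids), 1 / 0.4, tolerance = 1e-9)

  # any proper model scores >= 1
  wr <- rand_weights("lstm", 12, 4, seed = 3)
  set.seed(3)
  expect_gte(perplexity(wr, sample.int(12, 300, replace = TRUE)), 1)
  expect_error(perplexity(wr, integer(0)), "test tokens")
  # batching does not change the result
  set.seed(4)
  ids <- sample.int(12, 101, replace = TRUE)
  expect_equal(perplexity(wr, ids, batch_size = 7),
               perplexity(wr, ids, batch_size = 512))
})

test_that("balanced accuracy is 1 for an oracle similarity matrix", {
  words <- paste0("w", 1:8)
  pm <- setNames(rep(c("A", "B"), each = 4), words)
  S <- outer(pm, pm, function(a, b) ifelse(a == b, 1, 0))
  diag(S) <- 1
  dimnames(S) <- list(words, words)
  rep <- balanced_accuracy_sweep(S, data.frame(word = words, category = pm))
  expect_equal(rep$mean_balanced_accuracy, 1)
  expect_true(all(rep$per_probe$sensitivity == 1))
  expect_true(all(rep$per_probe$specificity == 1))
})

test_that("hand-built 4-probe case matches exhaustive enumeration", {
  words <- c("a1", "a2", "b1", "b2")
  pm <- setNames(c("A", "A", "B", "B"), words)
  S <- matrix(c(1, .8, .3, .2,
                .8, 1, .4, .1,
                .3, .4, 1, .55,
                .2, .1, .55, 1), 4, 4, byrow = TRUE,
              dimnames = list(words, words))
  grid <- threshold_grid(step = 0.01)
  got <- balanced_accuracy_sweep(S, data.frame(word = words, category = pm),
                                 grid = grid)
  want <- brute_force_sweep(S, pm, grid)
  expect_equal(got$mean_balanced_accuracy, want$mean_balanced_accuracy)
  expect_equal(got$best_threshold, want$best_threshold)
  expect_equal(got$per_probe$balanced_accuracy, want$per_probe)
})

test_that("sweep equals the brute-force oracle on random probe sets", {
  set.seed(11)
  grid <- threshold_grid(step = 0.02)
  for (trial in 1:30) {
    n <- sample(4:8, 1)
    words <- paste0("w", seq_len(n))
    pm <- setNames(sample(LETTERS[1:3], n, replace = TRUE), words)
    # guarantee two categories that each have a same-category partner
    pm[1:4] <- c("A", "A", "B", "B")
    M <- matrix(runif(n * n), n, n)
    S <- (M + t(M)) / 2
    diag(S) <- 1
    dimnames(S) <- list(words, words)
    got <- suppressWarnings(
      balanced_accuracy_sweep(S, data.frame(word = words, category = pm),
                              grid = grid))
    want <- brute_force_sweep(S, pm, grid)
    expect_equal(got$mean_balanced_accuracy, want$mean_balanced_accuracy)
    expect_equal(got$best_threshold, want$best_threshold)
  }
})

test_that("sweep is invariant to probe order and flags partnerless probes", {
  words <- c("a1", "a2", "a3", "b1", "b2", "solo")
  pm <- setNames(c("A", "A", "A", "B", "B", "C"), words)
  set.seed(12)
  M <- matrix(runif(36), 6, 6)
  S <- (M + t(M)) / 2
  diag(S) <- 1
  dimnames(S) <- list(words, words)
  expect_warning(
    r1 <- balanced_accuracy_sweep(S, data.frame(word = words, category = pm)),
    "no same-category partner"
  )
  perm <- c(4, 2, 6, 1, 5, 3)
  expect_warning(
    r2 <- balanced_accuracy_sweep(
      S, data.frame(word = words[perm], category = pm[perm])),
    "no same-category partner"
  )
  expect_equal(r1$mean_balanced_accuracy, r2$mean_balanced_accuracy)
  expect_equal(r1$best_threshold, r2$best_threshold)
  expect_false("solo" %in% r1$per_probe$word)
})

test_that("nearest neighbors rank by similarity with lexicographic tie-break", {
  M <- rbind(w = c(1, 0, 0), x = c(1, 0, 0), b = c(0.9, 0.1, 0),
             a = c(0.9, 0.1, 0), z = c(0, 1, 0))
  M <- M + matrix(rep(c(0, 0.001, 0.002), each = 5), 5)  # break zero variance
  S <- similarity_matrix(reps_from_matrix(M), rows = rownames(M))
  nn <- nearest_neighbors(S, "w", k = 4)
  expect_identical(nn$word[1], "x")      # duplicate vector first, sim 1
  expect_equal(nn$similarity[1], 1)
  expect_identical(nn$word[2:3], c("a", "b"))  # tie broken lexicographically
  expect_identical(nrow(nearest_neighbors(S, "w", k = 0)), 0L)
  # matches a brute-force sort
  sims <- S["w", setdiff(rownames(M), "w")]
  ord <- order(-sims, names(sims))
  expect_identical(nn$word, names(sims)[ord][1:4])
  expect_error(nearest_neighbors(S, "nope", 3), "not in similarity")
})

test_that("category similarity matrix averages pairs without the diagonal", {
  words <- c("a1", "a2", "b1", "b2")
  pm <- data.frame(word = words, category = c("A", "A", "B", "B"))
  S <- matrix(c(1, 1, 0, 0,
                1, 1, 0, 0,
                0, 0, 1, 1,
                0, 0, 1, 1), 4, 4, dimnames = list(words, words))
  M <- category_similarity_matrix(S, pm, cluster = FALSE)
  expect_equal(unname(M), diag(2) * 1 + 0)

  # constant similarities give a constant matrix
  Sc <- matrix(0.4, 4, 4, dimnames = list(words, words))
  Mc <- category_similarity_matrix(Sc, pm, cluster = FALSE)
  expect_true(all(Mc == 0.4))

  # 6-probe brute-force enumeration
  words6 <- paste0("w", 1:6)
  pm6 <- setNames(c("A", "A", "A", "B", "B", "C"), words6)
  set.seed(13)
  R <- matrix(runif(36), 6, 6)
  S6 <- (R + t(R)) / 2
  dimnames(S6) <- list(words6, words6)
  expect_warning(
    M6 <- category_similarity_matrix(
      S6, data.frame(word = words6, category = pm6), cluster = FALSE),
    "singleton"
  )
  manual <- function(c1, c2) {
    vals <- c()
    for (i in words6[pm6 == c1]) for (j in words6[pm6 == c2]) {
      if (i != j) vals <- c(vals, S6[i, j])
    }
    mean(vals)
  }
  expect_equal(M6["A", "B"], manual("A", "B"))
  expect_equal(M6["A", "A"], manual("A", "A"))
  expect_true(is.na(M6["C", "C"]))  # singleton within-cell undefined

  # permuting the probe list permutes nothing in the unclustered matrix
  perm <- sample(6)
  expect_warning(
    M6p <- category_similarity_matrix(
      S6, data.frame(word = words6[perm], category = pm6[perm]),
      cluster = FALSE),
    "singleton"
  )
  expect_equal(M6p, M6)
})

test_that("hierarchical clustering merges tight pairs first and groups blocks", {
  S <- matrix(c(1, 0.99, 0.1,
                0.99, 1, 0.1,
                0.1, 0.1, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  hc <- hierarchical_cluster(S)
  # identical-ish pair merges first at distance ~0
  expect_equal(hc$height[1], 0.01)
  first <- hc$merge[1, ]
  expect_setequal(hc$labels[-first], c("a", "b"))

  # two identical items merge at exactly zero
  S2 <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(hierarchical_cluster(S2)$height[1], 0)

  # block-structured matrix keeps blocks contiguous in the leaf order
  set.seed(14)
  blocks <- rep(1:3, each = 4)
  S3 <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.9, 0.1)) +
    matrix(runif(144, -0.02, 0.02), 12)
  S3 <- (S3 + t(S3)) / 2
  diag(S3) <- 1
  dimnames(S3) <- list(paste0("i", 1:12), paste0("i", 1:12))
  ord_blocks <- blocks[hierarchical_cluster(S3)$order]
  expect_identical(length(rle(ord_blocks)$lengths), 3L)

  expect_error(hierarchical_cluster(matrix(1, 1, 1)), "at least 2")
})

test_that("pca reports centered components and variance fractions", {
  # variation along a single direction
  t_ <- seq(-1, 1, length.out = 20)
  M <- cbind(t_, 2 * t_, -t_)
  rownames(M) <- paste0("w", 1:20)
  p <- pca_loadings(reps_from_matrix(M))
  expect_equal(p$variance_fraction[1], 1)
  expect_true(all(p$variance_fraction >= 0))
  expect_lte(sum(p$variance_fraction), 1 + 1e-12)

  # isotropic 2-D data: two roughly equal fractions
  set.seed(15)
  M2 <- matrix(rnorm(4000), 2000, 2)
  p2 <- pca_loadings(reps_from_matrix(M2))
  expect_lt(abs(p2$variance_fraction[1] - 0.5), 0.1)

  expect_error(pca_loadings(matrix(1, 1, 3)), "at least 2")
  # undefined rows are dropped before the fit
  M3 <- rbind(M, NA)
  expect_equal(pca_loadings(reps_from_matrix(M3))$variance_fraction,
               p$variance_fraction)
})

test_that("pca separates planted word classes on a trained model", {
  # train a small SRN on a two-category corpus, then run PCA over the probe
  # words' contextual representations: the first component should line up
  # with the planted class split (point-biserial correlation)
  study <- small_study(seed = 41, tokens_per_document = 1200, n_documents = 4)
  parts <- partition_corpus(study$ids, 2)
  fit <- train_model(init_weights("srn", length(study$vocab$words), 16, seed = 6),
                     parts, training_config(local_iterations = 2))
  reps <- extract_contextual_reps(fit$weights, study$ids, study$vocab)
  p <- pca_loadings(reps$matrix[study$probes$word, ])
  is_first <- as.integer(study$probes$category == study$probes$category[1])
  expect_gt(abs(cor(p$scores[, 1], is_first)), 0.8)
})
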