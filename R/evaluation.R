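#' Mean per-word perplexity on a held-out token stream
#'
#' `exp` of the mean negative log probability assigned to each next word,
#' with context windows built exactly as in training (the current word plus
#' up to six predecessors). A perfect predictor scores 1; a model spreading
#' its probability uniformly over `k` words scores `k`, so an untrained
#' model scores about the vocabulary inventory size.
#'
#' @param weights Trained or untrained `srn_weights`/`lstm_weights`.
#' @param ids Integer token-id stream encoded with the training vocabulary.
#' @param batch_size Windows per forward batch.
#' @return The scalar perplexity (>= 1 for any proper model).
#' @export
perplexity <- function(weights, ids, batch_size = 512L) {
  if (length(ids) < 2L) {
    stop("need at least 2 test tokens to score predictions", call. = FALSE)
  }
  check_token_ids(weights, ids)
  positions <- seq_len(length(ids) - 1L)
  targets <- ids[positions + 1L]
  nll_sum <- 0
  for (start in seq(1L, length(positions), by = batch_size)) {
    end <- min(start + batch_size - 1L, length(positions))
    wm <- build_window_matrix(ids, positions[start:end])
    fwd <- rnn_forward(weights, wm$X, wm$lens)
    P <- output_distribution(weights, fwd$h_final)
    if (!is.matrix(P)) P <- matrix(P, ncol = 1L)
    nll_sum <- nll_sum - sum(log(P[cbind(targets[start:end],
                                         seq_len(ncol(P)))]))
  }
  exp(nll_sum / length(positions))
}

#' Decision-threshold grid for the balanced-accuracy sweep
#'
#' @param lower,upper,step Grid bounds and step; the default is 0 to 1 in
#'   steps of 0.001. Negative similarities therefore fall below every
#'   threshold and are always classified "different category".
#' @return Strictly increasing numeric vector of thresholds.
#' @export
threshold_grid <- function(lower = 0, upper = 1, step = 0.001) {
  if (step <= 0 || upper <= lower) stop("invalid grid", call. = FALSE)
  seq(lower, upper, by = step)
}

as_probe_map <- function(probes) {
  if (is.data.frame(probes)) {
    stopifnot(all(c("word", "category") %in% names(probes)))
    stats::setNames(as.character(probes$category), as.character(probes$word))
  } else if (!is.null(names(probes))) {
    stats::setNames(as.character(probes), names(probes))
  } else {
    stop("`probes` must be a data.frame(word, category) or named vector",
         call. = FALSE)
  }
}

#' Balanced-accuracy sweep for semantic category classification
#'
#' Treats every probe pair as a same-category judgment in a signal-detection
#' framework. For a probe word `w` at threshold `r`, each partner `x != w`
#' contributes: a hit if same category and `S > r`; a miss if same category
#' and `S <= r`; a false alarm if different category and `S > r`; a correct
#' rejection otherwise. Per probe, sensitivity = hits / (hits + misses) and
#' specificity = correct rejections / (correct rejections + false alarms);
#' their mean is the probe's balanced accuracy, which removes the bias from
#' most pairs being different-category. The summary statistic is the mean of
#' all probes' balanced accuracies at the single threshold that maximizes
#' it.
#'
#' @param S Square probe-by-probe similarity matrix with word dimnames.
#' @param probes data.frame with `word`, `category` columns (or named
#'   category vector). Probes lacking any same-category partner are excluded
#'   with a warning.
#' @param grid Threshold grid from [threshold_grid()].
#' @return Object of class `cds_ba_report`: `best_threshold`,
#'   `mean_balanced_accuracy`, `per_probe` (data.frame at the best
#'   threshold), `per_category` (mean per category), and `curve`
#'   (mean balanced accuracy at every threshold).
#' @export
balanced_accuracy_sweep <- function(S, probes, grid = threshold_grid()) {
  pm <- as_probe_map(probes)
  words <- names(pm)
  if (is.null(rownames(S))) stop("`S` needs word dimnames", call. = FALSE)
  missing <- setdiff(words, rownames(S))
  if (length(missing)) {
    stop(sprintf("probes absent from similarity matrix: %s",
                 paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  }
  S <- unclass(S)[words, words]
  cats <- pm[words]
  n_same_partners <- vapply(words, function(w) sum(cats == cats[[w]]) - 1L,
                            integer(1))
  lonely <- n_same_partners == 0L
  if (any(lonely)) {
    warning(sprintf("excluding %d probes with no same-category partner",
                    sum(lonely)), call. = FALSE)
    words <- words[!lonely]
    cats <- cats[!lonely]
    S <- S[words, words]
  }
  # a probe with no different-category partner has undefined specificity
  no_diff <- vapply(words, function(w) all(cats == cats[[w]]), logical(1))
  if (any(no_diff)) {
    warning(sprintf("excluding %d probes with no different-category partner",
                    sum(no_diff)), call. = FALSE)
    words <- words[!no_diff]
    cats <- cats[!no_diff]
    S <- S[words, words]
  }
  if (length(words) < 2L) {
    stop("probe set degenerate: need probes with both same- and different-category partners",
         call. = FALSE)
  }
  n <- length(words)
  G <- length(grid)
  sens <- matrix(NA_real_, n, G)
  spec <- matrix(NA_real_, n, G)
  same_mask <- outer(cats, cats, "==")
  diag(same_mask) <- NA  # self-pairs excluded
  for (i in seq_len(n)) {
    s_same <- sort(S[i, which(same_mask[i, ])])
    s_diff <- sort(S[i, which(!same_mask[i, ])])
    # counts of similarities <= r for every grid threshold at once
    le_same <- findInterval(grid, s_same)
    le_diff <- findInterval(grid, s_diff)
    sens[i, ] <- (length(s_same) - le_same) / length(s_same)
    spec[i, ] <- le_diff / length(s_diff)
  }
  ba <- (sens + spec) / 2
  curve <- colMeans(ba)
  best <- which.max(curve)
  per_probe <- data.frame(
    word = words, category = unname(cats),
    sensitivity = sens[, best], specificity = spec[, best],
    balanced_accuracy = ba[, best], stringsAsFactors = FALSE
  )
  per_category <- stats::aggregate(balanced_accuracy ~ category, per_probe,
                                   mean)
  structure(
    list(best_threshold = grid[best], mean_balanced_accuracy = curve[best],
         per_probe = per_probe, per_category = per_category,
         curve = data.frame(threshold = grid, mean_balanced_accuracy = curve)),
    class = "cds_ba_report"
  )
}

#' @export
print.cds_ba_report <- function(x, ...) {
  cat(sprintf(
    "<cds_ba_report> %d probes, %d categories; best threshold %.3f, mean balanced accuracy %.3f\n",
    nrow(x$per_probe), nrow(x$per_category), x$best_threshold,
    x$mean_balanced_accuracy))
  invisible(x)
}

#' Nearest semantic neighbors of a word
#'
#' Ranks the `k` most similar words, excluding the word itself, with
#' similarity ties broken lexicographically.
#'
#' @param S A similarity matrix with word dimnames, or a `cds_reps` object
#'   (similarities to all defined rows are computed on the fly).
#' @param word The query word.
#' @param k Number of neighbors.
#' @return data.frame with columns `word` and `similarity`, `k` rows.
#' @export
nearest_neighbors <- function(S, word, k = 5L) {
  if (inherits(S, "cds_reps")) {
    all_words <- rownames(S$matrix)[rowSums(is.na(S$matrix)) == 0]
    if (!word %in% all_words) {
      stop(sprintf("'%s' has no defined representation", word), call. = FALSE)
    }
    S <- similarity_matrix(S, rows = word, cols = all_words)
    sims <- stats::setNames(drop(S), all_words)
  } else {
    if (!word %in% rownames(S)) {
      stop(sprintf("'%s' not in similarity matrix", word), call. = FALSE)
    }
    sims <- stats::setNames(unclass(S)[word, ], colnames(S))
  }
  sims <- sims[names(sims) != word]
  ord <- order(-sims, names(sims))
  top <- utils::head(ord, max(0L, k))
  data.frame(word = names(sims)[top], similarity = unname(sims[top]),
             stringsAsFactors = FALSE)
}

#' Category-averaged similarity matrix
#'
#' Removes the self-similarity diagonal from the probe-by-probe matrix, then
#' averages similarities within and between each pair of categories. Rows
#' and columns are reordered by hierarchical clustering of the category
#' matrix (average linkage on `1 - S`), so related categories sit together,
#' unless `cluster = FALSE`. A singleton category's within-category cell is
#' undefined (`NA`) and flagged with a warning.
#'
#' @param S Square probe similarity matrix with word dimnames.
#' @param probes data.frame with `word`, `category` (or named vector).
#' @param cluster Reorder rows/columns by hierarchical clustering.
#' @return A `K x K` matrix with category dimnames; attribute `hclust`
#'   carries the clustering when performed.
#' @export
category_similarity_matrix <- function(S, probes, cluster = TRUE) {
  pm <- as_probe_map(probes)
  words <- names(pm)
  S <- unclass(S)[words, words]
  diag(S) <- NA  # remove self-similarities before averaging
  cats <- sort(unique(unname(pm)))
  K <- length(cats)
  M <- matrix(NA_real_, K, K, dimnames = list(cats, cats))
  for (a in seq_len(K)) {
    for (b in seq_len(a)) {
      block <- S[pm == cats[a], pm == cats[b], drop = FALSE]
      M[a, b] <- M[b, a] <- mean(block, na.rm = TRUE)
    }
  }
  singleton <- table(pm)[cats] == 1L
  if (any(singleton)) {
    warning(sprintf("singleton categories with undefined within-cell: %s",
                    paste(cats[singleton], collapse = ", ")), call. = FALSE)
    dM <- diag(M)
    dM[singleton] <- NA
    diag(M) <- dM
  }
  if (cluster && K >= 2L && !anyNA(M)) {
    hc <- hierarchical_cluster(M)
    ord <- hc$order
    M <- M[ord, ord]
    attr(M, "hclust") <- hc
  }
  M
}

#' Agglomerative clustering of a similarity matrix
#'
#' Average-linkage hierarchical clustering on the distance `1 - S`, with
#' `stats::hclust`'s deterministic merge order and leaf ordering.
#'
#' @param S Square similarity matrix (dimnames become labels).
#' @return An `hclust` object.
#' @export
hierarchical_cluster <- function(S) {
  S <- unclass(S)
  if (!is.matrix(S) || nrow(S) != ncol(S) || nrow(S) < 2L) {
    stop("need a square similarity matrix with at least 2 items",
         call. = FALSE)
  }
  d <- stats::as.dist(1 - S)
  stats::hclust(d, method = "average")
}

#' Principal components of word representations
#'
#' PCA of the word-by-hidden-unit matrix after centering (no scaling: hidden
#' units share a common activation range). Rows with undefined
#' representations are dropped. Per-word component loadings (scores) reveal
#' which abstract features individual hidden dimensions encode; the variance
#' fractions say how much of the hidden layer's variance each component
#' explains.
#'
#' @param reps A `cds_reps` object (or plain matrix) with at least 2 defined
#'   rows.
#' @return Object of class `cds_pca`: `scores` (word x component),
#'   `rotation`, `variance_fraction`.
#' @export
pca_loadings <- function(reps) {
  M <- if (inherits(reps, "cds_reps")) reps$matrix else as.matrix(reps)
  M <- M[rowSums(is.na(M)) == 0, , drop = FALSE]
  if (nrow(M) < 2L) {
    stop("need at least 2 defined word representations", call. = FALSE)
  }
  p <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  vf <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = p$x, rotation = p$rotation, variance_fraction = vf),
            class = "cds_pca")
}

#' @export
print.cds_pca <- function(x, ...) {
  cat(sprintf("<cds_pca> %d words x %d components; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), ncol(x$scores),
              100 * x$variance_fraction[1],
              100 * ifelse(length(x$variance_fraction) > 1,
                           x$variance_fraction[2], 0)))
  invisible(x)
}
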