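#' Training configuration
#'
#' Collects the optimization hyperparameters of the age-ordered
#' local-iteration regime. The learning rate (0.01), Adagrad optimization
#' and mini-batch size (64) are the reference settings for the recurrent
#' models; `local_iterations` — how many times each age-ordered partition is
#' repeated before moving on, modelling consolidation of a day's input — has
#' no canonical value and must be supplied explicitly.
#'
#' @param local_iterations Consecutive repetitions of each partition (>= 1).
#' @param learning_rate Positive step size (default 0.01).
#' @param mini_batch_size Windows per weight update (default 64); the update
#'   uses the mean gradient over the mini-batch.
#' @param epsilon Adagrad denominator offset (default 1e-8).
#' @param all_steps Score every window step instead of only the final one.
#' @param sg_n_epochs,sg_window_size,sg_k_negatives,sg_lr_start,sg_lr_min
#'   Skip-gram settings: epochs (default 20), bidirectional window radius
#'   (default 3), negatives per pair (default 5), and the linearly decaying
#'   learning-rate range (0.025 to 1e-4).
#' @return An object of class `cds_training_config`.
#' @export
training_config <- function(local_iterations, learning_rate = 0.01,
                            mini_batch_size = 64L, epsilon = 1e-8,
                            all_steps = FALSE, sg_n_epochs = 20L,
                            sg_window_size = 3L, sg_k_negatives = 5L,
                            sg_lr_start = 0.025, sg_lr_min = 1e-4) {
  stopifnot_scalar_count(local_iterations, "local_iterations")
  stopifnot_scalar_count(mini_batch_size, "mini_batch_size")
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    stop("`learning_rate` must be positive", call. = FALSE)
  }
  structure(
    list(local_iterations = as.integer(local_iterations),
         learning_rate = learning_rate,
         mini_batch_size = as.integer(mini_batch_size), epsilon = epsilon,
         all_steps = isTRUE(all_steps), sg_n_epochs = as.integer(sg_n_epochs),
         sg_window_size = as.integer(sg_window_size),
         sg_k_negatives = as.integer(sg_k_negatives),
         sg_lr_start = sg_lr_start, sg_lr_min = sg_lr_min),
    class = "cds_training_config"
  )
}

#' Build the local-iteration partition schedule
#'
#' Each age-ordered partition index appears `local_iterations` times
#' consecutively before the next partition starts: with 3 partitions and 4
#' local iterations the schedule is 1,1,1,1,2,2,2,2,3,3,3,3. This models
#' day-scale consolidation of linguistic experience rather than corpus-scale
#' epochs.
#'
#' @param n_partitions Number of partitions.
#' @param local_iterations Consecutive repetitions per partition.
#' @return Integer vector of length `n_partitions * local_iterations`.
#' @export
build_schedule <- function(n_partitions, local_iterations) {
  n_partitions <- stopifnot_scalar_count(n_partitions, "n_partitions")
  local_iterations <- stopifnot_scalar_count(local_iterations, "local_iterations")
  rep(seq_len(n_partitions), each = local_iterations)
}

#' One Adagrad update
#'
#' Accumulates squared gradients per weight and scales each step by the
#' inverse root of the accumulator, so rarely updated weights take larger
#' steps than frequently updated ones:
#' `acc <- acc + g^2; w <- w - lr * g / (sqrt(acc) + eps)`.
#'
#' @param weights A `cdslm_weights` list.
#' @param grads Gradient list of matching shapes.
#' @param state Optimizer state from a previous call, or `NULL` to start
#'   with zero accumulators.
#' @param learning_rate Step size.
#' @param epsilon Denominator offset.
#' @return List with updated `weights` and `state` (accumulators + `step`).
#' @export
adagrad_update <- function(weights, grads, state = NULL, learning_rate = 0.01,
                           epsilon = 1e-8) {
  nm <- names(unclass(weights))
  if (is.null(state)) {
    state <- list(acc = lapply(unclass(weights), function(w) w * 0), step = 0L)
  }
  for (k in nm) {
    g <- grads[[k]]
    state$acc[[k]] <- state$acc[[k]] + g * g
    weights[[k]] <- weights[[k]] -
      learning_rate * g / (sqrt(state$acc[[k]]) + epsilon)
  }
  state$step <- state$step + 1L
  list(weights = weights, state = state)
}

# Iterate the mini-batched windows of one partition and apply Adagrad
# updates. Returns weights, optimizer state, and the partition's mean loss.
train_one_partition <- function(weights, state, ids, config) {
  n <- length(ids)
  if (n < 2L) stop("partition too short to form windows", call. = FALSE)
  positions <- seq_len(n - 1L)  # current-word positions; target = next token
  targets <- ids[positions + 1L]
  B <- config$mini_batch_size
  loss_sum <- 0
  n_windows <- 0L
  for (start in seq(1L, length(positions), by = B)) {
    end <- min(start + B - 1L, length(positions))
    wm <- build_window_matrix(ids, positions[start:end])
    res <- rnn_window_grads(weights, wm$X, wm$lens, targets[start:end],
                            all_steps = config$all_steps)
    upd <- adagrad_update(weights, res$grads, state,
                          learning_rate = config$learning_rate,
                          epsilon = config$epsilon)
    weights <- upd$weights
    state <- upd$state
    loss_sum <- loss_sum + sum(res$per_window)
    n_windows <- n_windows + (end - start + 1L)
  }
  list(weights = weights, state = state, mean_loss = loss_sum / n_windows)
}

#' Train a model on a partitioned corpus
#'
#' For the recurrent architectures this runs the age-ordered local-iteration
#' regime: partitions are visited in the order given by [build_schedule()],
#' each visit sweeps the partition's context windows in corpus order,
#' gradients are averaged over mini-batches of `mini_batch_size` windows,
#' and weights are updated with Adagrad. Adagrad accumulators persist across
#' partition visits. The per-visit mean window loss is logged. For skip-gram
#' weights the partitions are concatenated back into a token stream and
#' trained with negative-sampling SGD for `sg_n_epochs` epochs with a
#' linearly decaying learning rate.
#'
#' Training is deterministic given the weight-initialization seed (recurrent
#' models involve no sampling) and `seed` (skip-gram negative sampling);
#' replicates differ only by their seeds.
#'
#' @param weights Initialized `cdslm_weights`.
#' @param partitions A `cds_partitions` (or, for skip-gram, optionally a
#'   plain integer id vector).
#' @param config A [training_config()].
#' @param seed Seed for skip-gram noise sampling (ignored for srn/lstm).
#' @return List of class `cds_fit`: `weights`, `log` (data.frame), `state`
#'   (optimizer accumulators; `NULL` for skip-gram), `config`.
#' @export
train_model <- function(weights, partitions, config, seed = 1L) {
  stopifnot(inherits(weights, "cdslm_weights"),
            inherits(config, "cds_training_config"))
  ids_all <- if (inherits(partitions, "cds_partitions")) {
    unlist(partitions$partitions, use.names = FALSE)
  } else {
    as.integer(partitions)
  }
  if (max(ids_all) > attr(weights, "n_vocab")) {
    stop("corpus ids exceed the model's vocabulary inventory", call. = FALSE)
  }
  if (inherits(weights, "skipgram_weights")) {
    counts <- tabulate(ids_all, nbins = attr(weights, "n_vocab"))
    noise <- unigram_noise(counts)
    res <- with_local_seed(seed, {
      sgns_train_epochs(weights, ids_all, config$sg_window_size,
                        config$sg_n_epochs, config$sg_k_negatives, noise,
                        config$sg_lr_start, config$sg_lr_min)
    })
    return(structure(list(weights = res$weights, log = res$log, state = NULL,
                          config = config), class = "cds_fit"))
  }
  if (!inherits(partitions, "cds_partitions")) {
    stop("recurrent models require a `cds_partitions` corpus", call. = FALSE)
  }
  schedule <- build_schedule(partitions$n_partitions, config$local_iterations)
  state <- NULL
  log <- data.frame(visit = seq_along(schedule), partition = schedule,
                    mean_loss = NA_real_)
  for (v in seq_along(schedule)) {
    p <- schedule[v]
    out <- train_one_partition(weights, state, partitions$partitions[[p]],
                               config)
    weights <- out$weights
    state <- out$state
    log$mean_loss[v] <- out$mean_loss
  }
  structure(list(weights = weights, log = log, state = state, config = config),
            class = "cds_fit")
}

#' @export
print.cds_fit <- function(x, ...) {
  cat(sprintf("<cds_fit> %s; %d logged visits; final mean loss %.4f\n",
              class(x$weights)[1], nrow(x$log),
              utils::tail(x$log$mean_loss, 1)))
  invisible(x)
}
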