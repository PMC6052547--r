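#' Root-mean-square error between two profiles
#'
#' The training cost: `sqrt(mean((pred - target)^2))` over all `N x 20`
#' entries.
#'
#' @param pred,target Numeric matrices of equal shape.
#' @return Non-negative scalar; zero iff the matrices are equal.
#' @export
rmse_loss <- function(pred, target) {
  pred <- unclass(pred); target <- unclass(target)
  if (!all(dim(pred) == dim(target))) abort("pred and target shapes differ")
  sqrt(mean((pred - target)^2))
}

#' Randomly crop a training pair from a random start site
#'
#' The start site is drawn uniformly from `1..N` (not confined to the
#' N-terminus, to avoid overfitting the predictor to specific sites); the pair
#' is cut to at most `max_len` positions from there, sequence and target rows
#' kept aligned. Uses the current RNG stream.
#'
#' @param residues Residue string.
#' @param target Matrix of target rows, `nrow == nchar(residues)`.
#' @param max_len Crop length cap (default 1000, the training length ceiling).
#' @return List with `residues` and `target` for positions
#'   `s..min(N, s + max_len - 1)`.
#' @export
crop_random_start <- function(residues, target, max_len = 1000L) {
  n <- nchar(residues)
  if (nrow(target) != n) abort("target rows must equal sequence length")
  s <- sample.int(n, 1L)
  e <- min(n, s + max_len - 1L)
  list(residues = substr(residues, s, e),
       target = target[s:e, , drop = FALSE])
}

#' Subsample an epoch from a dataset
#'
#' Draws `k` pairs uniformly without replacement — the epoch scheme used when
#' the full dataset cannot be visited every epoch.
#'
#' @param dataset List of training pairs.
#' @param k Subsample size (`k <= length(dataset)`).
#' @return List of `k` pairs.
#' @export
sample_epoch <- function(dataset, k) {
  if (k > length(dataset)) abort("k exceeds dataset size")
  dataset[sample.int(length(dataset), k)]
}

#' Training configuration
#'
#' Defaults document the reference full-scale condition of the method:
#' mini-batch size 200, epochs of 40,000 subsampled sequences, a 5000-epoch
#' budget, dropout ratio 0.5 between the embedding output and the LSTM input,
#' and 20,000 validation instances. Desk-scale runs override these.
#'
#' @param batch_size Sequences per mini-batch.
#' @param epoch_subsample Pairs drawn (without replacement) per epoch.
#' @param max_epochs Epoch budget (fixed stop; curves are monitored, no
#'   automatic patience rule).
#' @param dropout_ratio Unit-dropout ratio on the embedding output, active
#'   only in training passes; inverted scaling.
#' @param validation_size Pairs held out (disjoint from training).
#' @param optimizer Adam hyperparameters: list with `step_size`, `beta1`,
#'   `beta2`, `epsilon`.
#' @param max_len Random-crop length cap (default 1000).
#' @param seed Integer seed governing every stochastic element of the run
#'   (shuffling, epoch subsampling, crops, dropout masks).
#' @return A `training_config` list.
#' @export
training_config <- function(batch_size = 200L, epoch_subsample = 40000L,
                            max_epochs = 5000L, dropout_ratio = 0.5,
                            validation_size = 20000L,
                            optimizer = list(step_size = 1e-3, beta1 = 0.9,
                                             beta2 = 0.999, epsilon = 1e-8),
                            max_len = 1000L, seed = 1L) {
  if (dropout_ratio < 0 || dropout_ratio >= 1)
    abort("dropout_ratio must be in [0, 1)")
  if (batch_size < 1L || max_epochs < 1L || epoch_subsample < 1L)
    abort("batch_size, epoch_subsample and max_epochs must be >= 1")
  structure(list(batch_size = as.integer(batch_size),
                 epoch_subsample = as.integer(epoch_subsample),
                 max_epochs = as.integer(max_epochs),
                 dropout_ratio = dropout_ratio,
                 validation_size = as.integer(validation_size),
                 optimizer = optimizer,
                 max_len = as.integer(max_len),
                 seed = as.integer(seed)),
            class = "training_config")
}

# encode a list of pairs once: integer codes + bare target matrices
encode_pairs <- function(pairs) {
  lapply(pairs, function(p) list(codes = encode_residues(p$residues),
                                 target = unclass(p$profile)))
}

#' Train the profile generator
#'
#' Mini-batch Adam on the RMSE cost between network outputs and teacher
#' profile columns, with unit dropout on the embedding output during training
#' passes, random start-site cropping, per-epoch subsampling without
#' replacement, and training/validation loss curves. Batches are built by
#' sorting the epoch's crops by length (lockstep batching of unequal lengths;
#' positions past a sequence's end contribute nothing to the cost). The whole
#' run is reproducible from `config$seed`.
#'
#' @param pairs List of training pairs, each with `residues` and `profile`
#'   (as from [sample_dataset()]); must be larger than
#'   `config$validation_size`.
#' @param d,H Model dimensions (see [init_profiler()]).
#' @param config A [training_config()].
#' @param init Optional `seqprof_model` to start from (its dimensions must
#'   match `d` and `H`); by default a fresh model is initialized from
#'   `config$seed`.
#' @param verbose Print per-epoch losses (default `FALSE`).
#' @return An object of class `seqprof_fit`: list with `model`
#'   (`seqprof_model`), `train_loss` and `valid_loss` (numeric, one entry per
#'   completed epoch), `epochs`, `steps` (Adam updates), `wall_time_s`,
#'   `dims`, `config`.
#' @export
train_profiler <- function(pairs, d = 16L, H = 64L,
                           config = training_config(), init = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(config, "training_config"))
  if (length(pairs) <= config$validation_size)
    abort("dataset must be larger than validation_size")
  t0 <- proc.time()[["elapsed"]]
  set.seed(config$seed)

  perm <- sample.int(length(pairs))
  valid_idx <- perm[seq_len(config$validation_size)]
  train_idx <- setdiff(perm, valid_idx)
  enc_valid <- encode_pairs(pairs[valid_idx])
  enc_train <- encode_pairs(pairs[train_idx])

  vl_ord <- order(-vapply(enc_valid, function(p) length(p$codes), 1L))
  v_seqs <- lapply(enc_valid[vl_ord], `[[`, "codes")
  v_tgts <- lapply(enc_valid[vl_ord], `[[`, "target")

  if (is.null(init)) {
    model <- init_profiler(d = d, H = H, seed = config$seed)
  } else {
    stopifnot(inherits(init, "seqprof_model"),
              init$dims$d == d, init$dims$H == H)
    model <- init
  }
  par_names <- c("embed", "Wx", "Wh", "b", "Wy", "by")
  m1 <- lapply(model[par_names], function(x) x * 0)
  m2 <- m1
  opt <- config$optimizer
  step <- 0L

  k_epoch <- min(config$epoch_subsample, length(enc_train))
  train_curve <- numeric(0)
  valid_curve <- numeric(0)

  for (epoch in seq_len(config$max_epochs)) {
    sub <- enc_train[sample.int(length(enc_train), k_epoch)]
    crops <- lapply(sub, function(p) {
      n <- length(p$codes)
      s <- sample.int(n, 1L)
      e <- min(n, s + config$max_len - 1L)
      list(codes = p$codes[s:e], target = p$target[s:e, , drop = FALSE])
    })
    ord <- order(-vapply(crops, function(p) length(p$codes), 1L))
    crops <- crops[ord]
    n_batches <- ceiling(length(crops) / config$batch_size)
    epoch_loss <- 0
    epoch_n <- 0
    for (bi in seq_len(n_batches)) {
      lo <- (bi - 1L) * config$batch_size + 1L
      hi <- min(length(crops), bi * config$batch_size)
      batch <- crops[lo:hi]
      dseed <- sample.int(.Machine$integer.max, 1L)
      res <- cpp_batch_grad(lapply(batch, `[[`, "codes"),
                            lapply(batch, `[[`, "target"),
                            model[par_names],
                            config$dropout_ratio, dseed)
      if (!is.finite(res$loss))
        abort(sprintf("training diverged: non-finite loss at epoch %d, batch %d",
                      epoch, bi))
      step <- step + 1L
      b1t <- 1 - opt$beta1^step
      b2t <- 1 - opt$beta2^step
      for (nm in par_names) {
        g <- res$grads[[nm]]
        m1[[nm]] <- opt$beta1 * m1[[nm]] + (1 - opt$beta1) * g
        m2[[nm]] <- opt$beta2 * m2[[nm]] + (1 - opt$beta2) * g^2
        model[[nm]] <- model[[nm]] -
          opt$step_size * (m1[[nm]] / b1t) / (sqrt(m2[[nm]] / b2t) + opt$epsilon)
      }
      model$embed[PAD_CODE, ] <- 0
      epoch_loss <- epoch_loss + res$loss * length(batch)
      epoch_n <- epoch_n + length(batch)
    }
    train_curve[epoch] <- epoch_loss / epoch_n
    valid_curve[epoch] <- if (length(v_seqs) > 0L)
      cpp_batch_loss(v_seqs, v_tgts, model[par_names]) else NA_real_
    if (verbose)
      message(sprintf("epoch %4d  train %.5f  valid %.5f",
                      epoch, train_curve[epoch], valid_curve[epoch]))
  }

  structure(list(model = model,
                 train_loss = train_curve,
                 valid_loss = valid_curve,
                 epochs = config$max_epochs,
                 steps = step,
                 wall_time_s = proc.time()[["elapsed"]] - t0,
                 dims = list(d = as.integer(d), H = as.integer(H)),
                 config = config),
            class = "seqprof_fit")
}

#' Validation loss of a model on held-out pairs
#'
#' Mean RMSE over pairs with dropout inactive.
#'
#' @param model A `seqprof_model`.
#' @param pairs List of pairs with `residues` and `profile`.
#' @return Scalar mean loss.
#' @export
validate_profiler <- function(model, pairs) {
  if (length(pairs) == 0L) abort("no validation pairs supplied")
  losses <- vapply(pairs, function(p) {
    rmse_loss(forward_profile(model, p$residues), p$profile)
  }, numeric(1))
  mean(losses)
}

#' @export
print.seqprof_fit <- function(x, ...) {
  cat(sprintf("<seqprof_fit> d = %d, H = %d; %d epochs, %d Adam steps, %.1f s\n",
              x$dims$d, x$dims$H, x$epochs, x$steps, x$wall_time_s))
  cat(sprintf("  final train loss %.5f, final validation loss %.5f\n",
              tail(x$train_loss, 1), tail(x$valid_loss, 1)))
  invisible(x)
}

#' Tidy the learning curves of a fit
#'
#' @param x A `seqprof_fit`.
#' @param ... Unused.
#' @return Tibble with columns `epoch`, `train_loss`, `valid_loss`.
#' @export
tidy.seqprof_fit <- function(x, ...) {
  tibble(epoch = seq_along(x$train_loss),
         train_loss = x$train_loss,
         valid_loss = x$valid_loss)
}

#' One-row summary of a fit
#'
#' @param x A `seqprof_fit`.
#' @param ... Unused.
#' @return One-row tibble: dimensions, epochs, Adam steps, final losses,
#'   wall time.
#' @export
glance.seqprof_fit <- function(x, ...) {
  tibble(d = x$dims$d, H = x$dims$H, epochs = x$epochs, steps = x$steps,
         final_train_loss = tail(x$train_loss, 1),
         final_valid_loss = tail(x$valid_loss, 1),
         wall_time_s = x$wall_time_s)
}

#' Plot learning curves
#'
#' @param object A `seqprof_fit`.
#' @param ... Unused.
#' @return A ggplot of training and validation loss per epoch.
#' @export
autoplot.seqprof_fit <- function(object, ...) {
  df <- tidy(object)
  long <- tibble(epoch = rep(df$epoch, 2L),
                 loss = c(df$train_loss, df$valid_loss),
                 curve = rep(c("training", "validation"), each = nrow(df)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "RMSE loss", colour = NULL) +
    ggplot2::theme_minimal()
}
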