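test_that("rmse_loss matches hand computations and is symmetric", {
  p <- random_profile(5, seed = 1)
  expect_equal(rmse_loss(p, p), 0)

  uniform <- matrix(1 / 20, 1, 20)
  onehot <- matrix(c(1, rep(0, 19)), 1, 20)
  expect_equal(rmse_loss(uniform, onehot),
               sqrt((0.95^2 + 19 * 0.05^2) / 20))
  expect_equal(round(rmse_loss(uniform, onehot), 4), 0.2179)

  a <- random_profile(3, seed = 2); b <- random_profile(3, seed = 3)
  expect_equal(rmse_loss(a, b), rmse_loss(b, a))
  expect_error(rmse_loss(matrix(0, 2, 20), matrix(0, 3, 20)), "shapes")
})

test_that("random-start cropping slices sequence and target in register", {
  res <- "ACDEFGHIKL"
  tgt <- bare(random_profile(10, seed = 4))
  set.seed(1); s_draw <- sample.int(10, 1)  # peek at what the stream yields
  set.seed(1)
  cr <- crop_random_start(res, tgt, max_len = 3)
  expect_equal(cr$residues, substr(res, s_draw, min(10, s_draw + 2)))
  expect_equal(cr$target, tgt[s_draw:min(10, s_draw + 2), , drop = FALSE])

  # full-length cap keeps the pair intact when the start lands at 1
  repeat {
    seed <- sample(1e6, 1); set.seed(seed)
    if (sample.int(10, 1) == 1) break
  }
  set.seed(seed)
  cr <- crop_random_start(res, tgt, max_len = 100)
  expect_equal(cr$residues, res)
  expect_equal(cr$target, tgt)

  # same seed, same crop
  set.seed(99); c1 <- crop_random_start(res, tgt, 5)
  set.seed(99); c2 <- crop_random_start(res, tgt, 5)
  expect_identical(c1, c2)
})

test_that("epoch subsampling is uniform and without replacement", {
  ds <- as.list(1:10)
  set.seed(2)
  full <- sample_epoch(ds, 10)
  expect_setequal(unlist(full), 1:10)
  expect_error(sample_epoch(ds, 11), "exceeds")

  set.seed(31)
  draws <- replicate(10000, unlist(sample_epoch(ds, 1)))
  freq <- table(factor(draws, levels = 1:10)) / 10000
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_true(all(abs(freq - 0.1) < 3 * se + 1e-12))
})

test_that("training learns a learnable task and is seed-reproducible", {
  teacher <- make_teacher(teacher_config(context_k = 1L, seed = 7))
  pairs <- sample_dataset(teacher, 80, seed = 8)
  cfg <- training_config(batch_size = 20L, epoch_subsample = 60L,
                         max_epochs = 15L, dropout_ratio = 0.5,
                         validation_size = 20L,
                         optimizer = list(step_size = 3e-3, beta1 = 0.9,
                                          beta2 = 0.999, epsilon = 1e-8),
                         seed = 5L)
  fit1 <- train_profiler(pairs, d = 8, H = 16, config = cfg)
  expect_lt(tail(fit1$valid_loss, 1), fit1$valid_loss[1])
  expect_length(fit1$train_loss, 15L)
  expect_equal(fit1$steps, 15L * 3L)

  fit2 <- train_profiler(pairs, d = 8, H = 16, config = cfg)
  expect_identical(fit1$train_loss, fit2$train_loss)
  expect_identical(fit1$valid_loss, fit2$valid_loss)
  expect_identical(fit1$model$Wx, fit2$model$Wx)

  td <- tidy(fit1)
  expect_equal(names(td), c("epoch", "train_loss", "valid_loss"))
  expect_equal(nrow(td), 15L)
  expect_equal(glance(fit1)$final_valid_loss, tail(fit1$valid_loss, 1))
})

test_that("dropout slows the fit to a small training set", {
  teacher <- make_teacher(teacher_config(context_k = 1L, seed = 11))
  pairs <- sample_dataset(teacher, 55, seed = 12)
  final_train <- function(drop, seed) {
    cfg <- training_config(batch_size = 25L, epoch_subsample = 50L,
                           max_epochs = 12L, dropout_ratio = drop,
                           validation_size = 5L,
                           optimizer = list(step_size = 3e-3, beta1 = 0.9,
                                            beta2 = 0.999, epsilon = 1e-8),
                           seed = seed)
    tail(train_profiler(pairs, d = 8, H = 16, config = cfg)$train_loss, 1)
  }
  no_drop <- mean(vapply(1:3, function(s) final_train(0, s), numeric(1)))
  with_drop <- mean(vapply(1:3, function(s) final_train(0.5, s), numeric(1)))
  expect_lt(no_drop, with_drop)
})

test_that("training aborts when the dataset cannot cover the validation split", {
  teacher <- make_teacher(teacher_config(seed = 1))
  pairs <- sample_dataset(teacher, 5, seed = 1)
  cfg <- training_config(validation_size = 5L, max_epochs = 1L)
  expect_error(train_profiler(pairs, d = 4, H = 4, config = cfg),
               "larger than validation_size")
})

test_that("validation loss is a mean over pairs, invariant to order", {
  teacher <- make_teacher(teacher_config(seed = 3))
  pairs <- sample_dataset(teacher, 6, seed = 4)
  m <- init_profiler(d = 4, H = 8, seed = 2)
  v1 <- validate_profiler(m, pairs)
  v2 <- validate_profiler(m, rev(pairs))
  expect_equal(v1, v2)
  one <- validate_profiler(m, pairs[1])
  expect_equal(one, rmse_loss(forward_profile(m, pairs[[1]]$residues),
                              pairs[[1]]$profile))
  expect_error(validate_profiler(m, list()), "no validation pairs")

  # a model scored against its own outputs is perfect
  self_pairs <- lapply(pairs, function(p) {
    list(residues = p$residues, profile = forward_profile(m, p$residues))
  })
  expect_equal(validate_profiler(m, self_pairs), 0)
})

test_that("gradients match central finite differences on a tiny model", {
  set.seed(42)
  m <- init_profiler(2, 3, 7)
  par <- m[c("embed", "Wx", "Wh", "b", "Wy", "by")]
  tgt <- unclass(random_profile(4))
  seqs <- list(c(1L, 5L, 9L, 14L))
  tgts <- list(tgt)
  res <- seqprof:::cpp_batch_grad(seqs, tgts, par, 0, 1L)
  lossf <- function(p) seqprof:::cpp_batch_loss(seqs, tgts, p)
  expect_equal(res$loss, lossf(par), tolerance = 1e-12)
  eps <- 1e-5
  worst <- 0
  for (nm in names(par)) {
    g <- res$grads[[nm]]
    for (i in seq_along(par[[nm]])) {
      if (nm == "embed" && (i %% 21 == 0)) next  # fixed padding row
      p2 <- par
      p2[[nm]][i] <- p2[[nm]][i] + eps; up <- lossf(p2)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps; dn <- lossf(p2)
      fd <- (up - dn) / (2 * eps)
      worst <- max(worst, abs(fd - g[i]) / max(abs(fd), abs(g[i]), 1e-6))
    }
  }
  expect_lt(worst, 1e-5)
})
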