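ns <- asNamespace("dstage")

test_that("cosine schedule hits the base rate, midpoint and floor", {
  cfg <- train_config()
  expect_equal(cosine_lr(0, cfg), 1e-3)
  expect_equal(cosine_lr(cfg$max_epochs, cfg), cfg$min_lr)
  expect_equal(cosine_lr(cfg$max_epochs / 2, cfg), (1e-3 + cfg$min_lr) / 2)
  expect_equal(cosine_lr(0, cfg, base_lr = cfg$lr1), 1e-4)
  expect_error(cosine_lr(-1, cfg), "epoch")
  expect_error(cosine_lr(cfg$max_epochs + 1, cfg), "epoch")
})

test_that("training configuration defaults match the published protocol", {
  cfg <- train_config()
  expect_equal(cfg$lr0, 1e-3)
  expect_equal(cfg$lr1, 1e-4)
  expect_identical(cfg$batch_size, 16L)
  expect_identical(cfg$max_epochs, 50L)
  expect_identical(cfg$patience, 10L)
  expect_equal(cfg$weight_decay, 1e-4)
  expect_equal(cfg$dropout, 0.1)
  expect_error(train_config(patience = 50, max_epochs = 50), "patience")
  expect_error(train_config(scale_range = c(1.1, 1.2)), "scale_range")
})

test_that("mse loss: direct arithmetic and homogeneity", {
  expect_equal(mse_loss(c(0, 0), c(1, 3)), 5)
  expect_identical(mse_loss(1:5, 1:5), 0)
  p <- rnorm(10); y <- rnorm(10)
  expect_equal(mse_loss(y + 3 * (p - y), y), 9 * mse_loss(p, y),
               tolerance = 1e-12)
  expect_error(mse_loss(numeric(), numeric()), "empty")
})

test_that("temporal jitter is a per-epoch circular shift", {
  set.seed(30)
  x <- array(rnorm(3 * 20 * 5), c(3, 20, 5))
  expect_identical(augment_temporal_jitter(x, 0L), x)
  y <- augment_temporal_jitter(x, 5L)
  # multiset of samples preserved per channel and epoch
  for (n in 1:5) for (ch in 1:3)
    expect_equal(sort(y[ch, , n]), sort(x[ch, , n]))
  # a known shift applied then inverted restores the signal
  ord <- function(s) ((seq_len(20) - 1L - s) %% 20L) + 1L
  xs <- x[, ord(3L), , drop = FALSE]
  expect_identical(xs[, ord(-3L), , drop = FALSE], x)
  expect_error(augment_temporal_jitter(x, 20L), "max_shift")
})

test_that("amplitude scaling draws one scalar per epoch from the range", {
  set.seed(31)
  x <- array(rnorm(2 * 10 * 4), c(2, 10, 4))
  expect_equal(augment_amplitude_scale(x, c(1, 1)), x, tolerance = 1e-15)
  y <- augment_amplitude_scale(x, c(0.5, 2))
  r <- y / x
  for (n in 1:4) expect_equal(max(r[, , n]) - min(r[, , n]), 0, tolerance = 1e-12)
  # Monte-Carlo mean of the drawn scalar
  draws <- replicate(200, {
    z <- augment_amplitude_scale(array(1, c(1, 1, 50)), c(0.9, 1.1))
    mean(z)
  })
  expect_equal(mean(draws), 1, tolerance = 3 * sd(draws) / sqrt(200) + 1e-3)
  expect_error(augment_amplitude_scale(x, c(0, 1)), "positive")
})

test_that("per-channel z-scoring: definition, idempotence, affine invariance", {
  set.seed(32)
  x <- array(rnorm(4 * 30 * 3, mean = 5, sd = 2), c(4, 30, 3))
  z <- standardize_epochs(x)
  for (n in 1:3) for (ch in 1:4) {
    expect_equal(mean(z[ch, , n]), 0, tolerance = 1e-10)
    expect_equal(sd(z[ch, , n]), 1, tolerance = 1e-10)
  }
  expect_equal(standardize_epochs(z), z, tolerance = 1e-10)
  xa <- x
  for (ch in 1:4) xa[ch, , ] <- 3.5 * x[ch, , ] - ch   # per-channel affine
  expect_equal(standardize_epochs(xa), z, tolerance = 1e-10)
  xz <- x; xz[2, , 1] <- 7
  expect_error(standardize_epochs(xz), "zero-variance channel 2 in epoch 1")
})

test_that("early stopping follows the strict-improvement trace semantics", {
  vals <- c(3, rep(2, 11))
  es <- ns$es_init(10L)
  stopped_at <- NA_integer_
  for (e in seq_along(vals)) {
    es <- ns$es_step(es, e, vals[e])
    if (es$stop) { stopped_at <- e; break }
  }
  expect_identical(stopped_at, 12L)
  expect_identical(es$best_epoch, 2L)
  expect_identical(es$best, 2)
  # never stops before the patience budget is exhausted
  es2 <- ns$es_init(5L)
  for (e in 1:5) es2 <- ns$es_step(es2, e, 10 - e)   # monotone improvement
  expect_false(es2$stop)
})

test_that("training on a zero-noise constant-target cohort drives MSE to zero", {
  co <- tiny_cohort(rt_noise_sd = 0, trial_latent_sd = 0, p_noise_sd = 0,
                    pink_sd = 0.1)
  co$rt$labels[] <- 500                           # constant target
  set.seed(1)
  model <- dstage(dstage_config_desk(C = 6L, T_in = 40L))
  cfg <- train_config(max_epochs = 12L, patience = 11L, seed = 1L,
                      jitter_max_frames = 2L)
  res <- train_loop(model, co$rt, cfg, task = 0L)
  expect_lt(res$best_val_loss, 0.05)
  expect_true(all(diff(res$history$epoch) == 1))  # history monotone in epoch
})

test_that("same-seed training runs are bitwise identical", {
  co <- tiny_cohort()
  run <- function() {
    set.seed(7)
    model <- dstage(dstage_config_desk(C = 6L, T_in = 40L))
    cfg <- train_config(max_epochs = 3L, patience = 2L, seed = 3L,
                        jitter_max_frames = 2L)
    train_loop(model, co$rt, cfg, task = 0L)
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$params, r2$model$params)
})

test_that("early stopping returns the minimum observed validation loss", {
  co <- tiny_cohort()
  set.seed(2)
  model <- dstage(dstage_config_desk(C = 6L, T_in = 40L))
  cfg <- train_config(max_epochs = 6L, patience = 2L, seed = 2L,
                      jitter_max_frames = 2L)
  res <- train_loop(model, co$rt, cfg, task = 0L)
  expect_equal(res$best_val_loss, min(res$history$val_loss))
  expect_identical(res$best_epoch, res$history$epoch[which.min(res$history$val_loss)])
})
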