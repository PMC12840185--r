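ns <- asNamespace("dstage")

test_that("forward output has one prediction per epoch and is finite", {
  m <- tiny_model()
  x <- tiny_signal(m$config, B = 4L)
  pred <- dstage_forward(m, x, task = 0L)
  expect_length(pred, 4L)
  expect_true(all(is.finite(pred)))
})

test_that("evaluation-mode forward is deterministic and batch-equivariant", {
  m <- tiny_model(dropout = 0.3)   # dropout must be inert in eval mode
  x <- tiny_signal(m$config, B = 4L)
  p1 <- dstage_forward(m, x, 0L)
  p2 <- dstage_forward(m, x, 0L)
  expect_identical(p1, p2)
  perm <- c(3L, 1L, 4L, 2L)
  p3 <- dstage_forward(m, x[, , perm], 0L)
  expect_equal(p3, p1[perm], tolerance = 1e-12)
})

test_that("front-end streams have the configured shapes", {
  cfg <- dstage_config_desk(C = 8L, T_in = 40L)
  set.seed(1)
  m <- dstage(cfg)
  x <- array(rnorm(8 * 40 * 2), c(8, 40, 2))
  fe <- multiscale_frontend(m, x)
  expect_identical(dim(fe$temporal), c(2L, cfg$T_prime, cfg$D))
  expect_identical(dim(fe$spatial),
                   c(2L, cfg$T_prime, cfg$C,
                     length(cfg$branch_specs) * cfg$dw_multiplier))
  expect_true(all(is.finite(fe$temporal)))
  ht <- temporal_path(m, fe$temporal)
  expect_identical(dim(ht), c(2L, cfg$T_prime, cfg$D_t))
  hs <- spatial_path(m, fe$spatial)
  expect_identical(dim(hs), c(2L, cfg$T_prime, cfg$D_s))
})

test_that("odd frame counts and config mismatches are rejected", {
  expect_error(dstage_config(T_in = 199L), "even")
  m <- tiny_model()
  bad <- array(0, c(m$config$C, m$config$T_in + 2L, 1L))
  expect_error(ns$model_forward(m, bad, 0L), "expects C=")
  nonfinite <- array(NA_real_, c(m$config$C, m$config$T_in, 1L))
  expect_error(ns$model_forward(m, nonfinite, 0L), "non-finite")
  expect_error(dstage_config(D_t = 30L, h = 4L), "divisible")
})

test_that("gated fusion is an elementwise convex combination with gate in (0,1)", {
  m <- tiny_model()
  Df <- m$config$D_f
  set.seed(11)
  for (rep in 1:20) {
    B <- 2L; Tp <- m$config$T_prime
    Ht <- array(rnorm(B * Tp * Df, sd = 3), c(B, Tp, Df))
    Hs <- array(rnorm(B * Tp * Df, sd = 3), c(B, Tp, Df))
    fu <- st_gate_fuse(m, Ht, Hs)
    expect_true(all(fu$G > 0 & fu$G < 1))
    lo <- pmin(Ht, Hs); hi <- pmax(Ht, Hs)
    expect_true(all(fu$H_f >= lo - 1e-6 & fu$H_f <= hi + 1e-6))
  }
})

test_that("gate limit cases select one stream or their mean", {
  m <- tiny_model()
  # force the gate pre-activation via its bias: +/- large => G ~ 1 or 0
  B <- 1L; Tp <- m$config$T_prime; Df <- m$config$D_f
  set.seed(12)
  Ht <- array(rnorm(B * Tp * Df), c(B, Tp, Df))
  Hs <- array(rnorm(B * Tp * Df), c(B, Tp, Df))
  m$params[["fuse.g2.W"]][] <- 0
  m$params[["fuse.g2.b"]][] <- 50
  expect_equal(st_gate_fuse(m, Ht, Hs)$H_f, Ht, tolerance = 1e-8)
  m$params[["fuse.g2.b"]][] <- 0      # zero pre-activation => G = 0.5
  expect_equal(st_gate_fuse(m, Ht, Hs)$H_f, (Ht + Hs) / 2, tolerance = 1e-12)
})

test_that("identity-configured adapter is exact and constant-shift works", {
  m <- tiny_model()    # built with gamma=1, beta=0, zero bottleneck output
  B <- 2L; Tp <- m$config$T_prime; Df <- m$config$D_f
  set.seed(13)
  Hf <- array(rnorm(B * Tp * Df), c(B, Tp, Df))
  expect_identical(tar_block(m, Hf, 0L), Hf)
  # gamma = 0, beta = b: output constant b across epochs and frames
  m$params[["tar.bg"]][] <- 0
  bvec <- rnorm(Df)
  m$params[["tar.bb"]] <- bvec
  out <- tar_block(m, Hf, 1L)
  expect_equal(out[1, 1, ], bvec, tolerance = 1e-12)
  expect_equal(out[2, 5, ], bvec, tolerance = 1e-12)
  expect_error(tar_block(m, Hf, 5L), "unknown task id")
})

test_that("adapter arithmetic matches a hand-computed modulation + bottleneck", {
  cfg <- tiny_config(D_f = 2L, bottleneck_dim = 1L)
  set.seed(14)
  m <- dstage(cfg)
  m$params[["tar.emb"]][1, ] <- c(1, 0, 0)
  m$params[["tar.Wg"]] <- matrix(c(0.5, 0, 0, -0.2, 0, 0), 3, 2)
  m$params[["tar.bg"]] <- c(0.1, 0.3)
  m$params[["tar.Wb"]] <- matrix(c(0.2, 0, 0, 0.4, 0, 0), 3, 2)
  m$params[["tar.bb"]] <- c(-0.1, 0.2)
  m$params[["tar.down.W"]] <- matrix(c(1, -1), 2, 1)
  m$params[["tar.down.b"]] <- 0.5
  m$params[["tar.up.W"]] <- matrix(c(2, 1), 1, 2)
  m$params[["tar.up.b"]] <- c(0, -1)
  Hf <- array(c(0.7, -0.3), c(1, 1, 2))
  gam <- c(0.5 + 0.1, -0.2 + 0.3)
  bet <- c(0.2 - 0.1, 0.4 + 0.2)
  hmod <- gam * c(0.7, -0.3) + bet
  z <- sum(hmod * c(1, -1)) + 0.5
  gz <- 0.5 * z * (1 + tanh(sqrt(2 / pi) * (z + 0.044715 * z^3)))
  want <- hmod + c(2 * gz + 0, 1 * gz - 1)
  got <- tar_block(m, Hf, 0L)
  expect_equal(as.vector(got), want, tolerance = 1e-10)
})

test_that("head pooling is frame-mean: constant and duplicated frames are invariant", {
  m <- tiny_model()
  Df <- m$config$D_f
  set.seed(15)
  v <- rnorm(Df)
  Hconst <- array(rep(v, each = 6), c(1, 6, Df))
  single <- array(v, c(1, 1, Df))
  expect_equal(regression_head(m, Hconst), regression_head(m, single),
               tolerance = 1e-12)
  H <- array(rnorm(2 * 4 * Df), c(2, 4, Df))
  Hdup <- H[, rep(1:4, each = 2), , drop = FALSE]
  expect_equal(regression_head(m, Hdup), regression_head(m, H),
               tolerance = 1e-12)
})

test_that("parameter counts: toy closed form, additivity, weight invariance", {
  cfg <- tiny_config()
  m <- tiny_model()
  rep1 <- count_parameters(m)
  expect_identical(sum(rep1$components), rep1$total)
  # closed-form enumeration of weight/bias shapes for the tiny config
  C <- 4L; D <- 6L; ch <- 2L
  fe <- 3 * (3 * C * ch + ch) + (3 * ch) * D + D + 2 * D +
    3 * (C * 2 * 3 + C * 2)                         # dw streams: w + bias
  Dt <- 6L; f <- 8L
  tp <- D * Dt + Dt +                               # input projection
    (2 * Dt + 4 * (Dt^2 + Dt) + 2 * Dt + (3 * Dt + Dt) + 2 * Dt +
       (Dt * f + f + f * Dt + Dt)) + 2 * Dt         # one layer + final norm
  sp <- (3 * 2) * 5 + 5 + 5 * 5 + 5                 # gcn + projection
  Df <- 6L; gh <- 4L
  fuse <- Dt * Df + Df + 5 * Df + Df + (2 * Df * gh + gh + gh * Df + Df)
  tar <- 2 * 3 + 2 * (3 * Df + Df) + (Df * 2 + 2 + 2 * Df + Df)
  head <- Df * 5 + 5 + 5 + 1
  expect_identical(unname(rep1$components),
                   as.integer(c(fe, tp, sp, fuse, tar, head)))
  # counts are structure-only
  m2 <- m
  for (nm in names(m2$params)) m2$params[[nm]][] <- 99
  expect_identical(count_parameters(m2)$components, rep1$components)
})

test_that("reference-scale forward pass produces finite predictions with published shapes", {
  set.seed(8)
  m <- dstage(dstage_config())
  x <- array(rnorm(128 * 200 * 2, sd = 1), c(128, 200, 2))
  fe <- multiscale_frontend(m, x)
  expect_identical(dim(fe$temporal), c(2L, 100L, 256L))
  set.seed(9)
  x4 <- array(rnorm(128 * 200 * 4), c(128, 200, 4))
  pred <- dstage_forward(m, x4, task = 0L)
  expect_length(pred, 4L)
  expect_true(all(is.finite(pred)))
})

test_that("reference calibration hits the published parameter budgets exactly", {
  set.seed(1)
  m <- dstage(dstage_config())
  rep_full <- count_parameters(m)
  backbone <- sum(rep_full$components[c("front_end", "temporal_path",
                                        "spatial_path", "st_gate")])
  adapter <- sum(rep_full$components[c("tar_block", "head")])
  expect_identical(backbone, 593792L)
  expect_identical(adapter, 10436L)
  expect_identical(rep_full$total, 604228L)
})
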