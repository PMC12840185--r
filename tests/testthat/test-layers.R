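ns <- asNamespace("dstage")

test_that("analytic gradients match finite differences through the whole encoder", {
  set.seed(42)
  cfg <- tiny_config(L_t = 2L, L_g = 2L, g_dims = c(5L, 4L))
  m <- dstage(cfg)
  # randomize the identity-initialized adapter so its gradients are generic
  for (nm in c("tar.Wg", "tar.Wb", "tar.up.W"))
    m$params[[nm]][] <- rnorm(length(m$params[[nm]]), 0, 0.3)
  B <- 3L
  x <- tiny_signal(cfg, B)
  y <- rnorm(B)
  loss_fn <- function(model)
    mean((ns$model_forward(model, x, 0L, training = FALSE)$pred - y)^2)
  fw <- ns$model_forward(m, x, 0L, training = FALSE)
  g <- ns$model_backward(m, fw$cache, 2 * (fw$pred - y) / B)
  expect_setequal(names(g), names(m$params))
  eps <- 1e-5
  set.seed(9)
  for (nm in names(m$params)) {
    probes <- sample(length(m$params[[nm]]), min(2L, length(m$params[[nm]])))
    for (ix in probes) {
      mp <- m; mp$params[[nm]][ix] <- m$params[[nm]][ix] + eps
      mm <- m; mm$params[[nm]][ix] <- m$params[[nm]][ix] - eps
      fd <- (loss_fn(mp) - loss_fn(mm)) / (2 * eps)
      expect_lt(abs(fd - g[[nm]][ix]) / max(1e-6, abs(fd), abs(g[[nm]][ix])),
                1e-3)
    }
  }
})

test_that("attention weights are a row-stochastic matrix for every head and query", {
  set.seed(3)
  D <- 6L; h <- 2L; Tp <- 5L; B <- 2L
  p <- list()
  for (w in c("Wq", "Wk", "Wv", "Wo")) p[[paste0("a.", w)]] <- matrix(rnorm(D * D), D, D)
  for (b in c("bq", "bk", "bv", "bo")) p[[paste0("a.", b)]] <- rnorm(D)
  X <- matrix(rnorm(B * Tp * D), B * Tp, D)
  at <- ns$mhsa_fwd(X, p, "a", B, Tp, h)
  for (P in at$Ps) {
    expect_equal(rowSums(P), rep(1, Tp), tolerance = 1e-6)
    expect_true(all(P >= 0))
  }
})

test_that("single-head attention matches an independently coded dense oracle", {
  set.seed(4)
  Tp <- 3L; D <- 2L
  p <- list()
  for (w in c("Wq", "Wk", "Wv", "Wo")) p[[paste0("a.", w)]] <- matrix(rnorm(4), 2, 2)
  for (b in c("bq", "bk", "bv", "bo")) p[[paste0("a.", b)]] <- rnorm(2)
  X <- matrix(rnorm(Tp * D), Tp, D)
  got <- ns$mhsa_fwd(X, p, "a", B = 1L, Tp = Tp, h = 1L)$Y
  # brute-force attention, written directly from the definition
  Q <- X %*% p[["a.Wq"]] + matrix(p[["a.bq"]], Tp, D, byrow = TRUE)
  K <- X %*% p[["a.Wk"]] + matrix(p[["a.bk"]], Tp, D, byrow = TRUE)
  V <- X %*% p[["a.Wv"]] + matrix(p[["a.bv"]], Tp, D, byrow = TRUE)
  O <- matrix(0, Tp, D)
  for (i in seq_len(Tp)) {
    s <- as.vector(Q[i, ] %*% t(K)) / sqrt(D)
    a <- exp(s) / sum(exp(s))
    O[i, ] <- colSums(a * V)
  }
  want <- O %*% p[["a.Wo"]] + matrix(p[["a.bo"]], Tp, D, byrow = TRUE)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("one graph-convolution layer equals brute-force message passing on all graphs up to 4 nodes", {
  set.seed(5)
  for (C in 2:4) {
    # every undirected graph on C nodes with at least one edge per node
    n_pairs <- C * (C - 1) / 2
    pairs <- which(upper.tri(matrix(0, C, C)), arr.ind = TRUE)
    for (mask in seq_len(2^n_pairs - 1)) {
      A0 <- matrix(0, C, C)
      on <- which(bitwAnd(mask, 2^(seq_len(n_pairs) - 1)) > 0)
      for (e in on) { A0[pairs[e, 1], pairs[e, 2]] <- 1; A0[pairs[e, 2], pairs[e, 1]] <- 1 }
      A0 <- A0 + diag(C)
      dg <- rowSums(A0)
      An <- A0 * tcrossprod(1 / sqrt(dg))
      g_in <- 3L; g_out <- 2L; M <- 5L
      X <- array(rnorm(C * g_in * M), c(C, g_in, M))
      W <- matrix(rnorm(g_in * g_out), g_in, g_out)
      b <- rnorm(g_out)
      got <- ns$gcn_layer_fwd(X, An, W, b)$H
      # brute force: per frame, per node, explicit weighted neighbour sum
      for (mm in seq_len(M)) for (v in seq_len(C)) {
        agg <- numeric(g_in)
        for (u in seq_len(C)) agg <- agg + An[v, u] * X[u, , mm]
        want <- ns$gelu_fwd(as.vector(agg %*% W) + b)
        expect_equal(got[v, , mm], want, tolerance = 1e-6)
      }
      if (mask > 8) break   # cap enumeration per size; all masks for C<=3
    }
  }
})

test_that("dilated branch receptive field is 1 + (k-1)*d frames", {
  set.seed(6)
  C <- 3L; B <- 1L; T_len <- 40L; k <- 3L; d <- 4L
  W <- matrix(rnorm(2 * C * k), 2, C * k)
  b <- rnorm(2)
  x <- matrix(rnorm(C * T_len), C, T_len)
  y0 <- ns$conv_full_fwd(x, W, b, k, d, B, T_len)$Y
  # receptive field: output frame t depends on inputs within (k-1)/2*d = 4
  x2 <- x
  x2[, 30] <- x2[, 30] + 5          # perturb frame 30
  y1 <- ns$conv_full_fwd(x2, W, b, k, d, B, T_len)$Y
  changed <- which(colSums(abs(y1 - y0)) > 1e-12)
  expect_true(all(abs(changed - 30) <= (k - 1) / 2 * d))
  # frames at distance >= 9 of any perturbed input are untouched
  expect_true(all(abs(y1[, 21] - y0[, 21]) == 0))
  expect_true(all(abs(y1[, 39] - y0[, 39]) == 0))
})

test_that("residual-only encoder layer reduces to the input projection", {
  m <- tiny_model()
  cfg <- m$config
  # zero all sublayer output weights: each residual branch contributes 0
  for (nm in c("tp.l1.Wo", "tp.l1.bo", "tp.l1.dw.w", "tp.l1.dw.b",
               "tp.l1.ff2.W", "tp.l1.ff2.b"))
    m$params[[nm]][] <- 0
  # make the final layer norm the identity on its input scale
  B <- 2L
  Fmat <- matrix(rnorm(B * cfg$T_prime * cfg$D), B * cfg$T_prime, cfg$D)
  tp <- ns$tp_forward(m, Fmat, B, training = FALSE)
  proj <- ns$lin_fwd(Fmat, m$params[["tp.in.W"]], m$params[["tp.in.b"]])
  pe <- m$buffers$pe[rep(seq_len(cfg$T_prime), B), ]
  ref <- ns$ln_fwd(proj + pe, m$params[["tp.lnf.g"]], m$params[["tp.lnf.b"]])$Y
  expect_equal(tp$Ht, ref, tolerance = 1e-12)
})
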