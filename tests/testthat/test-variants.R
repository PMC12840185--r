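test_that("single-branch variants widen the surviving branch", {
  base <- dstage_config_desk()
  v1 <- variant_config("branch1_only", base)
  expect_length(v1$branch_specs, 1L)
  expect_identical(v1$branch_specs[[1]][1:2], c(7L, 1L))    # kernel, dilation kept
  expect_identical(v1$branch_specs[[1]][3], 24L)            # 3 x 8 channels
  v3 <- variant_config("branch3_only", base)
  expect_identical(v3$branch_specs[[1]][1:2], c(3L, 4L))
  # front-end concat width is conserved => projection input unchanged
  set.seed(1); m_full <- dstage(base)
  set.seed(1); m_b1 <- dstage(v1)
  expect_identical(dim(m_full$params[["fe.proj.W"]]),
                   dim(m_b1$params[["fe.proj.W"]]))
})

test_that("fixed-fusion variants drop the gate parameters", {
  base <- dstage_config_desk()
  set.seed(1)
  m_avg <- dstage(variant_config("average_fusion", base))
  expect_false(any(grepl("fuse.g", names(m_avg$params))))
  set.seed(1)
  m_cat <- dstage(variant_config("concat_fusion", base))
  expect_true("fuse.cat.W" %in% names(m_cat$params))
  expect_false(any(c("fuse.g1.W", "fuse.g2.W") %in% names(m_cat$params)))
  # average fusion equals the elementwise mean of projected streams
  ns <- asNamespace("dstage")
  Df <- base$D_f
  Ht <- matrix(rnorm(10 * base$D_t), 10)
  Hs <- matrix(rnorm(10 * base$D_s), 10)
  fu <- ns$fuse_forward(m_avg, Ht, Hs, training = FALSE)
  Htp <- ns$lin_fwd(Ht, m_avg$params[["fuse.pt.W"]], m_avg$params[["fuse.pt.b"]])
  Hsp <- ns$lin_fwd(Hs, m_avg$params[["fuse.ps.W"]], m_avg$params[["fuse.ps.b"]])
  expect_equal(fu$Hf, (Htp + Hsp) / 2, tolerance = 1e-12)
  expect_null(fu$G)
})

test_that("single-path variants omit the unused path entirely", {
  set.seed(1)
  m_t <- dstage(variant_config("temporal_only", dstage_config_desk()))
  expect_false(any(startsWith(names(m_t$params), "sp.")))
  expect_false(any(startsWith(names(m_t$params), "fe.dw")))
  set.seed(1)
  m_s <- dstage(variant_config("spatial_only", dstage_config_desk()))
  expect_false(any(startsWith(names(m_s$params), "tp.")))
  expect_identical(count_parameters(m_s)$components[["temporal_path"]], 0L)
})

test_that("adapter-less transfer trains only the head", {
  pol <- dstage:::variant_policy("transfer_without_tar")
  m <- tiny_model()
  m2 <- apply_freeze_policy(m, pol)
  rep2 <- count_parameters(m2)
  expect_identical(rep2$trainable, rep2$components[["head"]])
})

test_that("unknown variants are rejected with the list of valid ids", {
  expect_error(variant_config("bogus"), "full, branch1_only")
  expect_error(run_variant("bogus", list()), "valid ids")
  expect_identical(length(variant_ids()), 12L)
})

test_that("a small ablation grid trains, evaluates and compares variants", {
  co <- tiny_cohort(n_subjects = 10L, epochs_per_subject = 8L)
  cfg <- train_config(max_epochs = 2L, patience = 1L, jitter_max_frames = 2L)
  grid <- run_ablation_grid("average_fusion", co,
                            base_config = dstage_config_desk(C = 6L, T_in = 40L),
                            train_cfg = cfg, seeds = 0:1)
  expect_identical(nrow(grid$runs), 4L)            # 2 variants x 2 seeds
  expect_identical(grid$comparison$variant, "average_fusion")
  expect_true(all(is.finite(grid$runs$r2)))
  expect_true(is.finite(grid$comparison$t) || grid$comparison$degenerate)
})
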