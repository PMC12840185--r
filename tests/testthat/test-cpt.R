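test_that("freeze policies expose the documented component sets", {
  pre <- freeze_policy("pretrain")
  expect_length(pre$frozen, 0)
  tr <- freeze_policy("transfer")
  expect_setequal(tr$frozen, c("front_end", "temporal_path", "spatial_path",
                               "st_gate"))
  expect_setequal(tr$trainable, c("tar_block", "head"))
  m <- tiny_model()
  m1 <- apply_freeze_policy(m, pre)
  expect_equal(count_parameters(m1)$trainable_fraction_pct, 100)
  m2 <- apply_freeze_policy(m, tr)
  rep2 <- count_parameters(m2)
  expect_identical(rep2$trainable,
                   sum(rep2$components[c("tar_block", "head")]))
  bad <- tr; bad$trainable <- c("head", "nonexistent")
  expect_error(apply_freeze_policy(m, bad), "unknown component")
})

test_that("reference calibration under the transfer policy matches the published budget", {
  set.seed(1)
  m <- apply_freeze_policy(dstage(dstage_config()), "transfer")
  rep_tr <- count_parameters(m)
  expect_identical(rep_tr$trainable, 10436L)
  expect_identical(rep_tr$total, 604228L)
  expect_equal(trainable_fraction(rep_tr)$pct_1dp, 1.7)
})

test_that("trainable fraction arithmetic", {
  rep1 <- list(total = 200L, trainable = 1L,
               components = c(a = 199L, b = 1L))
  class(rep1) <- "dstage_param_report"
  expect_equal(trainable_fraction(rep1)$pct, 0.5)
  rep2 <- list(total = 604228L, trainable = 604228L)
  class(rep2) <- "dstage_param_report"
  expect_equal(trainable_fraction(rep2)$pct, 100)
  rep3 <- list(total = 0L, trainable = 0L)
  class(rep3) <- "dstage_param_report"
  expect_error(trainable_fraction(rep3), "total = 0")
})

test_that("frozen backbone weights are bitwise unchanged by optimizer steps", {
  co <- tiny_cohort()
  set.seed(3)
  model <- dstage(dstage_config_desk(C = 6L, T_in = 40L))
  model$stage <- "pretrained"
  before <- model$params
  cfg <- train_config(max_epochs = 3L, patience = 2L, seed = 3L,
                      jitter_max_frames = 2L)
  fit <- transfer(model, co$pfactor, cfg)
  comp <- dstage:::component_of(names(before))
  backbone_names <- names(before)[comp %in% c("front_end", "temporal_path",
                                              "spatial_path", "st_gate")]
  for (nm in backbone_names)
    expect_identical(fit$model$params[[nm]], before[[nm]])
  # adapter and head did move
  moved <- vapply(c("tar.emb", "head.h.W"),
                  function(nm) !identical(fit$model$params[[nm]], before[[nm]]),
                  TRUE)
  expect_true(all(moved))
})

test_that("transfer demands matching labels and warns on a cold backbone", {
  co <- tiny_cohort()
  set.seed(4)
  model <- dstage(dstage_config_desk(C = 6L, T_in = 40L))
  cfg <- train_config(max_epochs = 2L, patience = 1L, seed = 1L,
                      jitter_max_frames = 2L)
  expect_error(transfer(model, co$rt, cfg), "pfactor")
  expect_warning(fit <- transfer(model, co$pfactor, cfg), "not pre-trained")
  expect_s3_class(fit, "dstage_fit")
  expect_error(pretrain(model, co$pfactor, cfg), "rt_ms")
})

test_that("fit object supports the standard modelling methods", {
  co <- tiny_cohort()
  set.seed(5)
  model <- dstage(dstage_config_desk(C = 6L, T_in = 40L))
  cfg <- train_config(max_epochs = 2L, patience = 1L, seed = 1L,
                      jitter_max_frames = 2L)
  fit <- pretrain(model, co$rt, cfg)
  expect_output(print(fit), "Fitted encoder")
  expect_type(coef(fit), "list")
  pr <- predict(fit, co$rt, split = "test")
  expect_length(pr, sum(co$rt$split == "test"))
  expect_equal(unname(pr), fit$held_out$test$predicted, tolerance = 1e-10)
  res <- residuals(fit)
  expect_length(res, length(pr))
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tf))
  unlink(tf)
})
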