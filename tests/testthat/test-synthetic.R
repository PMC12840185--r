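test_that("identical configurations generate bitwise-identical cohorts", {
  c1 <- tiny_cohort(seed = 5L)
  c2 <- tiny_cohort(seed = 5L)
  expect_identical(c1$rt$epochs, c2$rt$epochs)
  expect_identical(c1$rt$labels, c2$rt$labels)
  expect_identical(c1$pfactor$labels, c2$pfactor$labels)
  expect_identical(c1$rt$split, c2$rt$split)
  c3 <- tiny_cohort(seed = 6L)
  expect_false(identical(c1$rt$epochs, c3$rt$epochs))
})

test_that("with all noise off, reaction time is a deterministic map of efficiency", {
  co <- tiny_cohort(rt_noise_sd = 0, trial_latent_sd = 0, p_noise_sd = 0)
  e <- co$rt$gen_meta$trial_efficiency
  keep <- co$rt$labels > 150   # clipping floor excluded
  expect_equal(cor(e[keep], co$rt$labels[keep]), -1, tolerance = 1e-12)
  # psychopathology is exactly -a_p * z
  z <- co$pfactor$gen_meta$latent
  subj <- co$pfactor$subject
  expect_equal(co$pfactor$labels, -0.8 * z[subj], tolerance = 1e-12)
})

test_that("subject-mean RT correlates with psychopathology as the slopes imply", {
  co <- study_cohorts()
  cfg <- co$rt$gen_meta$config
  rt_bar <- tapply(co$rt$labels, co$rt$subject, mean)
  p <- tapply(co$pfactor$labels, co$pfactor$subject, function(v) v[1])
  got <- cor(rt_bar, p)
  n_e <- cfg$epochs_per_subject
  analytic <- cfg$a_p * cfg$beta_rt /
    sqrt((cfg$beta_rt^2 * (1 + cfg$trial_latent_sd^2 / n_e) +
            cfg$rt_noise_sd^2 / n_e) * (cfg$a_p^2 + cfg$p_noise_sd^2))
  expect_equal(got, analytic, tolerance = 0.1)
  expect_true(all(co$rt$labels >= 150))
  expect_true(all(is.finite(co$rt$epochs)))
})

test_that("shuffling subject identity destroys the RT-mean/psychopathology link", {
  co <- study_cohorts()
  rt_bar <- tapply(co$rt$labels, co$rt$subject, mean)
  p <- tapply(co$pfactor$labels, co$pfactor$subject, function(v) v[1])
  observed <- abs(cor(rt_bar, p))
  set.seed(99)
  null_abs <- replicate(200, abs(cor(rt_bar, sample(p))))
  expect_gt(observed, quantile(null_abs, 0.99))
})

test_that("a linear probe on alpha-band power learns held-out reaction time", {
  co <- study_cohorts()
  ap <- alpha_band_power(co$rt)
  tr <- co$rt$split == "train"; te <- co$rt$split == "test"
  beta <- lm.fit(cbind(1, ap[tr, ]), co$rt$labels[tr])$coefficients
  pred <- as.vector(cbind(1, ap[te, ]) %*% beta)
  expect_gt(r2_score(co$rt$labels[te], pred), 0)
})

test_that("subject splits partition subjects with the documented counts", {
  co <- tiny_cohort(n_subjects = 10L)
  re <- split_by_subject(co$rt, c(0.8, 0.1, 0.1), seed = 4L)
  tab <- table(unique(data.frame(s = re$subject, g = re$split))$g)
  expect_identical(as.integer(tab[c("train", "val", "test")]), c(8L, 1L, 1L))
  # no subject in two splits
  expect_identical(anyDuplicated(unique(data.frame(s = re$subject, g = re$split))$s), 0L)
  one <- tiny_cohort(n_subjects = 3L)
  expect_error(split_by_subject(one$rt, c(1, 0, 0)), "empty")
})

test_that("variance decomposition reports components consistently", {
  co <- tiny_cohort(seed = 2L)
  rep1 <- snr_report(co$rt)
  expect_equal(sum(rep1$variance_share), 1)
  # independent pass over the stored per-epoch decomposition
  expect_equal(rep1$mean_component_var,
               colMeans(co$rt$gen_meta$component_var))
  # no pink noise => zero noise share; doubling sd quadruples its variance
  co0 <- tiny_cohort(pink_sd = 0)
  expect_identical(unname(snr_report(co0$rt)$variance_share["pink"]), 0)
  co2 <- tiny_cohort(pink_sd = 2)
  expect_equal(unname(snr_report(co2$rt)$mean_component_var["pink"]), 4)
})

test_that("degenerate generator settings are rejected", {
  expect_error(synthetic_config(n_subjects = 2), "3 subjects")
  expect_error(synthetic_config(epochs_per_subject = 0), "epoch")
  expect_error(synthetic_config(rt_noise_sd = -1), "nonnegative")
})
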