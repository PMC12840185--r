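# Shared fixtures: tiny configurations and cohorts built in code.

tiny_config <- function(...) {
  args <- list(C = 4L, T_in = 12L, D = 6L,
               branch_specs = list(c(3L, 1L, 2L), c(3L, 2L, 2L), c(3L, 4L, 2L)),
               dw_multiplier = 2L, D_t = 6L, h = 2L, L_t = 1L, ffn_dim = 8L,
               dw_kernel = 3L, L_g = 1L, g_dims = 5L, D_s = 5L, D_f = 6L,
               gate_hidden = 4L, D_e = 3L, bottleneck_dim = 2L,
               head_hidden = 5L, dropout = 0, knn_k = 2L)
  over <- list(...)
  args[names(over)] <- over
  do.call(dstage_config, args)
}

tiny_model <- function(seed = 1, ...) {
  set.seed(seed)
  dstage(tiny_config(...))
}

tiny_signal <- function(cfg, B = 3L, seed = 2) {
  set.seed(seed)
  array(rnorm(cfg$C * cfg$T_in * B), c(cfg$C, cfg$T_in, B))
}

# A small but learnable cohort for fast end-to-end training tests.
tiny_cohort <- function(n_subjects = 8L, epochs_per_subject = 6L, seed = 0L,
                        ...) {
  generate_cohort(synthetic_config(n_subjects = n_subjects,
                                   epochs_per_subject = epochs_per_subject,
                                   C = 6L, T_len = 40L,
                                   seed = seed, ...))
}

# The acceptance-scale study objects are expensive; build them once per test
# run and share across test files.
.study_env <- new.env(parent = emptyenv())

study_cohorts <- function() {
  if (is.null(.study_env$cohorts))
    .study_env$cohorts <- generate_cohort(synthetic_config())
  .study_env$cohorts
}

# Desk-study training protocols (see the methods vignette for the rationale
# of the epoch budgets).
pretrain_protocol <- function(seed = 0L)
  train_config(max_epochs = 10L, patience = 5L, seed = seed)

transfer_protocol <- function(seed = 0L)
  train_config(max_epochs = 10L, patience = 4L, seed = seed,
               jitter_max_frames = 0L, scale_range = c(1, 1))

study_pretrained <- function() {
  if (is.null(.study_env$pretrained)) {
    co <- study_cohorts()
    set.seed(0)
    model <- dstage(dstage_config_desk())
    .study_env$pretrained <- pretrain(model, co$rt, pretrain_protocol())
  }
  .study_env$pretrained
}
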