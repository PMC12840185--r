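#' Ablation variant identifiers
#'
#' The harness covers the architectural ablations of the encoder (single
#' front-end branches with width matched to keep the concatenated dimension,
#' single encoder paths, fixed fusion rules) and the transfer-protocol
#' comparators (adapter transfer with and without the task-adaptive block,
#' training from scratch, full fine-tuning).
#'
#' @return Character vector of valid variant ids.
#' @export
variant_ids <- function() {
  c("full", "branch1_only", "branch2_only", "branch3_only",
    "temporal_only", "spatial_only", "concat_fusion", "average_fusion",
    "transfer_with_tar", "transfer_without_tar", "from_scratch",
    "full_finetune")
}

rt_variants <- function() {
  c("full", "branch1_only", "branch2_only", "branch3_only",
    "temporal_only", "spatial_only", "concat_fusion", "average_fusion")
}

#' Build the model configuration for an architectural variant
#'
#' Single-branch variants widen the remaining branch to keep the total
#' front-end output width; fusion variants replace the learned gate with
#' concatenation-projection or elementwise averaging; path variants drop one
#' encoder stream.
#'
#' @param variant a variant id from [variant_ids()].
#' @param base a `dstage_config` to derive from.
#' @return A `dstage_config`.
#' @export
variant_config <- function(variant, base = dstage_config_desk()) {
  if (!variant %in% variant_ids())
    stop("unknown variant '", variant, "'; valid ids: ",
         paste(variant_ids(), collapse = ", "))
  args <- unclass(base)
  args$T_prime <- NULL
  total_ch <- sum(vapply(base$branch_specs, function(b) b[3], 1L))
  if (variant %in% c("branch1_only", "branch2_only", "branch3_only")) {
    i <- as.integer(substr(variant, 7, 7))
    spec <- base$branch_specs[[i]]
    spec[3] <- total_ch
    args$branch_specs <- list(spec)
  } else if (variant == "temporal_only") {
    args$paths <- "temporal"
  } else if (variant == "spatial_only") {
    args$paths <- "spatial"
  } else if (variant == "concat_fusion") {
    args$fusion <- "concat"
  } else if (variant == "average_fusion") {
    args$fusion <- "average"
  }
  do.call(dstage_config, args)
}

# Trainable-component policy for the transfer-protocol variants.
variant_policy <- function(variant) {
  switch(variant,
    transfer_with_tar = freeze_policy("transfer"),
    transfer_without_tar = {
      pol <- freeze_policy("transfer")
      pol$frozen <- c(pol$frozen, "tar_block")
      pol$trainable <- "head"
      pol
    },
    full_finetune = freeze_policy("full_finetune"),
    from_scratch = freeze_policy("pretrain"),
    freeze_policy("pretrain"))
}

#' Run one experiment variant over seeds
#'
#' Architectural variants (see [rt_variants()]) are trained from scratch on
#' the reaction-time cohort; transfer-protocol variants start from the given
#' pre-trained fit (or random initialization for `from_scratch`) and train on
#' the transfer cohort. One row of held-out test metrics is produced per
#' seed.
#'
#' @param variant a variant id.
#' @param cohorts list with `rt` and `pfactor` cohorts ([generate_cohort()]).
#' @param base_config `dstage_config` for the architecture.
#' @param train_cfg `dstage_train_config`; the seed field is overridden per
#'   run.
#' @param seeds integer vector of run seeds.
#' @param pretrained optional `dstage_fit` backbone for the transfer-stage
#'   variants.
#' @return Data frame with columns variant, seed, r2, mae, nmse, best_epoch.
#' @export
run_variant <- function(variant, cohorts, base_config = dstage_config_desk(),
                        train_cfg = train_config(), seeds = 0:4,
                        pretrained = NULL) {
  if (!variant %in% variant_ids())
    stop("unknown variant '", variant, "'; valid ids: ",
         paste(variant_ids(), collapse = ", "))
  rows <- list()
  feat_cache <- NULL   # frozen-backbone features are seed-invariant
  for (sd in seeds) {
    cfg <- train_cfg
    cfg$seed <- as.integer(sd)
    if (variant %in% rt_variants()) {
      vcfg <- variant_config(variant, base_config)
      set.seed(sd)
      model <- dstage(vcfg)
      fit <- pretrain(model, cohorts$rt, cfg)
    } else if (variant == "from_scratch") {
      set.seed(sd)
      model <- dstage(base_config)
      model <- apply_freeze_policy(model, variant_policy(variant))
      fit <- suppressWarnings(
        train_fit(model, cohorts$pfactor, cfg, task = 1L, base_lr = cfg$lr1))
    } else {
      if (is.null(pretrained))
        stop("variant '", variant, "' needs a pretrained fit")
      model <- apply_freeze_policy(pretrained$model, variant_policy(variant))
      bb <- variant == "full_finetune"
      if (!bb && is.null(feat_cache) && train_cfg$jitter_max_frames == 0L &&
          all(train_cfg$scale_range == 1))
        feat_cache <- backbone_features(model,
                                        standardize_epochs(cohorts$pfactor$epochs))
      fit <- train_fit(model, cohorts$pfactor, cfg, task = 1L,
                       base_lr = cfg$lr1, backbone = bb,
                       feature_cache = if (bb) NULL else feat_cache)
    }
    ev <- eval_report(fit$held_out$test$actual, fit$held_out$test$predicted)
    rows[[length(rows) + 1L]] <-
      data.frame(variant = variant, seed = sd, r2 = ev$r2, mae = ev$mae,
                 nmse = ev$nmse, best_epoch = fit$best_epoch)
  }
  do.call(rbind, rows)
}

# Shared trainer for protocol variants: train_loop plus held-out evaluation.
train_fit <- function(model, cohort, cfg, task, base_lr, backbone = NULL,
                      feature_cache = NULL) {
  res <- train_loop(model, cohort, cfg, task = task, base_lr = base_lr,
                    backbone = backbone, feature_cache = feature_cache)
  res$stage <- "variant"
  res$task <- task
  res <- attach_eval(res, cohort)
  class(res) <- c("dstage_fit", class(res))
  res
}

#' Run an ablation grid and compare variants against the full model
#'
#' Trains each requested variant over the given seeds, then performs paired
#' per-seed comparisons of held-out R2 against the reference variant with
#' Bonferroni adjustment over the family of comparisons.
#'
#' @param variants variant ids to run (the reference `"full"` is added if
#'   absent).
#' @param cohorts list with `rt` and `pfactor` cohorts.
#' @param base_config,train_cfg,seeds,pretrained forwarded to
#'   [run_variant()].
#' @param alpha family-wise significance level.
#' @return List with `runs` (per-seed metric rows) and `comparison` (one row
#'   per non-reference variant: mean R2s, t, adjusted p decision).
#' @export
run_ablation_grid <- function(variants, cohorts,
                              base_config = dstage_config_desk(),
                              train_cfg = train_config(), seeds = 0:1,
                              pretrained = NULL, alpha = 0.05) {
  variants <- union("full", variants)
  runs <- do.call(rbind, lapply(variants, run_variant, cohorts = cohorts,
                                base_config = base_config,
                                train_cfg = train_cfg, seeds = seeds,
                                pretrained = pretrained))
  others <- setdiff(variants, "full")
  fam <- length(others)
  ref <- runs$r2[runs$variant == "full"]
  comp <- lapply(others, function(v) {
    r2v <- runs$r2[runs$variant == v]
    cr <- compare_runs(ref, r2v, alpha = alpha, n_comparisons = max(1L, fam))
    data.frame(variant = v, mean_r2_full = mean(ref), mean_r2_variant = mean(r2v),
               t = cr$t, p_value = cr$p_value,
               significant = cr$significant, degenerate = cr$degenerate)
  })
  list(runs = runs, comparison = do.call(rbind, comp))
}
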