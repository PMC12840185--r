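#' Freeze policies for the two training stages
#'
#' The pre-training stage trains every parameter. The transfer stage freezes
#' the backbone — front-end, temporal path, spatial path and fusion gate —
#' and trains only the task-adaptive block and regression head. An optional
#' `full_finetune` policy keeps everything trainable at the transfer learning
#' rate, for efficiency comparisons.
#'
#' @param stage `"pretrain"`, `"transfer"` or `"full_finetune"`.
#' @return An object of class `dstage_freeze_policy` with `stage`, `frozen`
#'   and `trainable` component sets.
#' @export
freeze_policy <- function(stage = c("pretrain", "transfer", "full_finetune")) {
  stage <- match.arg(stage)
  all_comp <- c("front_end", "temporal_path", "spatial_path", "st_gate",
                "tar_block", "head")
  frozen <- if (stage == "transfer")
    c("front_end", "temporal_path", "spatial_path", "st_gate") else character()
  pol <- list(stage = stage, frozen = frozen,
              trainable = setdiff(all_comp, frozen))
  class(pol) <- "dstage_freeze_policy"
  pol
}

#' Apply a freeze policy to a model
#'
#' Disables gradient updates for every parameter belonging to the policy's
#' frozen components; [count_parameters()] reflects the change.
#'
#' @param model a [dstage()] model.
#' @param policy a [freeze_policy()], or a character stage name.
#' @return The model with updated trainable flags.
#' @export
apply_freeze_policy <- function(model, policy) {
  stopifnot(inherits(model, "dstage"))
  if (is.character(policy)) policy <- freeze_policy(policy)
  known <- c("front_end", "temporal_path", "spatial_path", "st_gate",
             "tar_block", "head")
  bad <- setdiff(c(policy$frozen, policy$trainable), known)
  if (length(bad) > 0L)
    stop("unknown component name(s): ", paste(bad, collapse = ", "))
  comp <- component_of(names(model$params))
  model$trainable[] <- comp %in% policy$trainable
  model$policy <- policy$stage
  model
}

#' Stage 1: cognitive pre-training on reaction time
#'
#' Trains every parameter of the encoder on trial-level reaction-time labels
#' (task id 0) with the stage-1 protocol: Adam at the base rate `cfg$lr0`
#' with cosine annealing, MSE loss and early stopping. Splits must be
#' subject-disjoint.
#'
#' @param model a [dstage()] model.
#' @param cohort_rt a `dstage_cohort` with `label_kind == "rt_ms"` and
#'   assigned splits.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return A `dstage_fit` (see [train_loop()] for the components); the
#'   embedded model is tagged as pre-trained.
#' @export
pretrain <- function(model, cohort_rt, cfg = train_config(), verbose = FALSE) {
  if (cohort_rt$label_kind != "rt_ms")
    stop("pre-training expects reaction-time labels (label_kind 'rt_ms')")
  model <- apply_freeze_policy(model, freeze_policy("pretrain"))
  res <- train_loop(model, cohort_rt, cfg, task = 0L, base_lr = cfg$lr0,
                    verbose = verbose)
  res$model$stage <- "pretrained"
  res$stage <- "pretrain"
  res$task <- 0L
  res <- attach_eval(res, cohort_rt)
  class(res) <- c("dstage_fit", class(res))
  res
}

#' Stage 2: adapter-only transfer to a new target
#'
#' Freezes the backbone of a pre-trained encoder and fine-tunes only the
#' task-adaptive block and regression head (task id 1) at the transfer
#' learning rate `cfg$lr1`. The frozen backbone runs in inference mode, so
#' its weights and normalization statistics are bitwise unchanged by any
#' number of optimizer steps.
#'
#' @param fit a `dstage_fit` from [pretrain()], or a bare [dstage()] model
#'   (a warning is issued when the backbone is not pre-trained, supporting
#'   the from-scratch ablation).
#' @param cohort_pf a `dstage_cohort` with the transfer labels
#'   (`label_kind == "pfactor"`).
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return A `dstage_fit` for the transfer stage.
#' @export
transfer <- function(fit, cohort_pf, cfg = train_config(), verbose = FALSE) {
  model <- if (inherits(fit, "dstage_fit")) fit$model else fit
  stopifnot(inherits(model, "dstage"))
  if (cohort_pf$label_kind != "pfactor")
    stop("transfer expects psychopathology labels (label_kind 'pfactor')")
  if (!identical(model$stage, "pretrained"))
    warning("backbone is not pre-trained; transferring from its current state")
  model <- apply_freeze_policy(model, freeze_policy("transfer"))
  res <- train_loop(model, cohort_pf, cfg, task = 1L, base_lr = cfg$lr1,
                    backbone = FALSE, verbose = verbose)
  res$model$stage <- "transferred"
  res$stage <- "transfer"
  res$task <- 1L
  res <- attach_eval(res, cohort_pf)
  class(res) <- c("dstage_fit", class(res))
  res
}

# Store held-out predictions (original label scale) in the fit so that
# residuals/plot/summary need no re-computation.
attach_eval <- function(res, cohort) {
  out <- list()
  for (sp in "test") {
    idx <- which(cohort$split == sp)
    if (length(idx) == 0L) next
    x_sp <- standardize_epochs(cohort$epochs[, , idx, drop = FALSE])
    pr <- predict_epochs(res$model, x_sp, res$task)
    pr <- pr * res$target_stats["sd"] + res$target_stats["mu"]
    out[[sp]] <- data.frame(actual = cohort$labels[idx], predicted = unname(pr),
                            subject = cohort$subject[idx])
  }
  res$held_out <- out
  res$label_kind <- cohort$label_kind
  res
}

#' @export
print.dstage_fit <- function(x, ...) {
  cat(sprintf("Fitted encoder (%s stage, %s labels)\n", x$stage, x$label_kind))
  cat(sprintf("  best epoch %d of %d run, validation MSE %.4f (standardized)\n",
              x$best_epoch, nrow(x$history), x$best_val_loss))
  if (!is.null(x$held_out$test)) {
    ev <- eval_report(x$held_out$test$actual, x$held_out$test$predicted)
    cat(sprintf("  held-out test: MAE %.3f, NMSE %.3f, R2 %.3f (n=%d)\n",
                ev$mae, ev$nmse, ev$r2, ev$n))
  }
  pr <- x$param_report
  cat(sprintf("  parameters: %s total, %s trainable (%.1f%%)\n",
              format(pr$total, big.mark = ","),
              format(pr$trainable, big.mark = ","),
              pr$trainable_fraction_pct))
  invisible(x)
}

#' @export
summary.dstage_fit <- function(object, ...) {
  print(object)
  cat("\nTraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5L), row.names = FALSE)
  invisible(object)
}

#' @export
coef.dstage_fit <- function(object, ...) object$model$params

#' Predict phenotype values for new epochs
#'
#' @param object a `dstage_fit`.
#' @param cohort a `dstage_cohort` (or a `channels x frames x epochs` array).
#' @param split optional split name to restrict prediction to.
#' @param ... unused.
#' @return Numeric predictions on the original label scale.
#' @export
predict.dstage_fit <- function(object, cohort, split = NULL, ...) {
  x <- if (inherits(cohort, "dstage_cohort")) {
    idx <- if (is.null(split)) seq_len(dim(cohort$epochs)[3]) else
      which(cohort$split == split)
    cohort$epochs[, , idx, drop = FALSE]
  } else cohort
  pr <- predict_epochs(object$model, standardize_epochs(x), object$task)
  unname(pr * object$target_stats["sd"] + object$target_stats["mu"])
}

#' @export
residuals.dstage_fit <- function(object, split = "test", ...) {
  ho <- object$held_out[[split]]
  if (is.null(ho)) stop("no held-out predictions stored for split ", split)
  ho$predicted - ho$actual
}

#' Diagnostic plots for a fitted encoder
#'
#' Left: training and validation loss by epoch. Right: held-out predictions
#' against actual values with the identity line.
#'
#' @param x a `dstage_fit`.
#' @param split split for the agreement panel.
#' @param ... unused.
#' @export
plot.dstage_fit <- function(x, split = "test", ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "MSE (standardized)",
                    main = "learning curves")
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  ho <- x$held_out[[split]]
  if (!is.null(ho)) {
    graphics::plot(ho$actual, ho$predicted, pch = 16, cex = 0.5,
                   col = grDevices::adjustcolor("steelblue", 0.6),
                   xlab = "actual", ylab = "predicted",
                   main = paste("held-out", split))
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
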