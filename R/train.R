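#' Training configuration
#'
#' Defaults are the published protocol: Adam with learning rate `1e-3` for
#' pre-training and `1e-4` for transfer, cosine annealing, batch size 16, at
#' most 50 epochs with early stopping patience 10, weight decay `1e-4`,
#' dropout 0.1, MSE loss, temporal jittering and amplitude scaling
#' augmentation. The cosine floor (`min_lr = 1e-5`) and the augmentation
#' magnitudes (`jitter_max_frames = 10`, `scale_range = c(0.9, 1.1)`) are
#' package choices, fixed once.
#'
#' @param lr0,lr1 base learning rates for the pre-training and transfer stages.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement); must be smaller than `max_epochs`.
#' @param weight_decay L2 penalty added to gradients.
#' @param dropout dropout probability (recorded here; the model carries its
#'   own copy from [dstage_config()]).
#' @param min_lr cosine annealing floor.
#' @param jitter_max_frames maximum circular temporal shift, in frames.
#' @param scale_range amplitude scaling range `(lo, hi)`; must contain 1.
#' @param seed RNG seed used by [train_loop()] for shuffling, augmentation
#'   and dropout.
#' @return An object of class `dstage_train_config`.
#' @export
train_config <- function(lr0 = 1e-3, lr1 = 1e-4, batch_size = 16L,
                         max_epochs = 50L, patience = 10L,
                         weight_decay = 1e-4, dropout = 0.1, min_lr = 1e-5,
                         jitter_max_frames = 10L, scale_range = c(0.9, 1.1),
                         seed = 0L) {
  cfg <- list(lr0 = lr0, lr1 = lr1, batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs), patience = as.integer(patience),
              weight_decay = weight_decay, dropout = dropout, min_lr = min_lr,
              jitter_max_frames = as.integer(jitter_max_frames),
              scale_range = as.numeric(scale_range), seed = as.integer(seed))
  if (cfg$patience >= cfg$max_epochs)
    stop("patience must be smaller than max_epochs")
  if (length(cfg$scale_range) != 2L || cfg$scale_range[1] > 1 ||
      cfg$scale_range[2] < 1)
    stop("scale_range must be (lo, hi) with lo <= 1 <= hi")
  class(cfg) <- "dstage_train_config"
  cfg
}

#' Cosine annealing schedule
#'
#' `lr(e) = min_lr + (base_lr - min_lr) * (1 + cos(pi * e / max_epochs)) / 2`,
#' so epoch 0 gives the base rate and epoch `max_epochs` the floor.
#'
#' @param epoch integer in `0..max_epochs`.
#' @param cfg a [train_config()].
#' @param base_lr base learning rate (defaults to the pre-training rate).
#' @return The learning rate.
#' @export
cosine_lr <- function(epoch, cfg, base_lr = cfg$lr0) {
  if (epoch < 0 || epoch > cfg$max_epochs)
    stop("epoch must be in 0..max_epochs")
  cfg$min_lr + 0.5 * (base_lr - cfg$min_lr) * (1 + cos(pi * epoch / cfg$max_epochs))
}

#' Mean squared error
#'
#' @param pred,target equal-length numeric vectors.
#' @return Mean of squared differences.
#' @export
mse_loss <- function(pred, target) {
  if (length(pred) == 0L) stop("empty input")
  if (length(pred) != length(target)) stop("length mismatch")
  mean((pred - target)^2)
}

#' Temporal jittering augmentation
#'
#' Circularly shifts each epoch along the frame axis by an integer drawn
#' uniformly from `[-max_shift, max_shift]` (each epoch gets its own draw).
#' The per-channel sample multiset is preserved exactly.
#'
#' @param x `channels x frames x epochs` array.
#' @param max_shift maximum shift in frames; must be smaller than the frame
#'   count.
#' @return Array of the same shape.
#' @export
augment_temporal_jitter <- function(x, max_shift) {
  T_len <- dim(x)[2]
  if (max_shift >= T_len) stop("max_shift must be smaller than the frame count")
  if (max_shift == 0L) return(x)
  N <- dim(x)[3]
  shifts <- sample.int(2L * max_shift + 1L, N, replace = TRUE) - max_shift - 1L
  for (s in unique(shifts)) {
    if (s == 0L) next
    idx <- which(shifts == s)
    ord <- ((seq_len(T_len) - 1L - s) %% T_len) + 1L
    x[, , idx] <- x[, ord, idx, drop = FALSE]
  }
  x
}

#' Amplitude scaling augmentation
#'
#' Multiplies each whole epoch by one scalar drawn from `Uniform(lo, hi)`.
#'
#' @param x `channels x frames x epochs` array.
#' @param range length-2 vector `(lo, hi)` with `0 < lo <= hi`.
#' @return Array of the same shape.
#' @export
augment_amplitude_scale <- function(x, range) {
  if (range[1] <= 0) stop("scale range lower bound must be positive")
  if (range[1] > range[2]) stop("scale range must be (lo, hi) with lo <= hi")
  N <- dim(x)[3]
  s <- stats::runif(N, range[1], range[2])
  x * rep(s, each = dim(x)[1] * dim(x)[2])
}

#' Per-channel, per-epoch z-scoring
#'
#' Standardizes every channel of every epoch to mean 0 and (sample) standard
#' deviation 1 along the frame axis. Affine per-channel transformations of the
#' input therefore leave the output unchanged.
#'
#' @param x `channels x frames x epochs` array.
#' @return Standardized array of the same shape.
#' @export
standardize_epochs <- function(x) {
  C <- dim(x)[1]; T_len <- dim(x)[2]; N <- dim(x)[3]
  M <- matrix(aperm(x, c(2, 1, 3)), T_len, C * N)
  mu <- colMeans(M)
  sdv <- sqrt(colSums((M - rep(mu, each = T_len))^2) / (T_len - 1))
  bad <- which(sdv <= 0)
  if (length(bad) > 0L) {
    ch <- (bad[1] - 1L) %% C + 1L
    ep <- (bad[1] - 1L) %/% C + 1L
    stop("zero-variance channel ", ch, " in epoch ", ep)
  }
  M <- (M - rep(mu, each = T_len)) / rep(sdv, each = T_len)
  aperm(array(M, c(T_len, C, N)), c(2, 1, 3))
}

# --- Adam ---------------------------------------------------------------------

# State is kept as one flat vector over the trainable parameters (offsets
# recorded at init); the whole update is a handful of vectorized operations.
adam_init <- function(params, trainable) {
  nms <- names(params)[trainable[names(params)]]
  sizes <- vapply(nms, function(n) length(params[[n]]), 1L)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  n_tot <- sum(sizes)
  list(nms = nms, starts = starts, ends = ends,
       m = numeric(n_tot), v = numeric(n_tot),
       t = 0L, b1 = 0.9, b2 = 0.999, eps = 1e-8)
}

adam_step <- function(opt, params, grads, lr, weight_decay) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$b1^opt$t
  c2 <- 1 - opt$b2^opt$t
  nms <- opt$nms
  g_flat <- unlist(lapply(nms, function(n) grads[[n]]), use.names = FALSE)
  th_flat <- unlist(lapply(nms, function(n) params[[n]]), use.names = FALSE)
  if (length(g_flat) != length(th_flat))
    stop("missing gradient for a trainable parameter")
  g_flat <- g_flat + weight_decay * th_flat
  opt$m <- opt$b1 * opt$m + (1 - opt$b1) * g_flat
  opt$v <- opt$b2 * opt$v + (1 - opt$b2) * g_flat * g_flat
  th_flat <- th_flat - lr * (opt$m / c1) / (sqrt(opt$v / c2) + opt$eps)
  for (i in seq_along(nms))
    params[[nms[i]]][] <- th_flat[opt$starts[i]:opt$ends[i]]
  list(opt = opt, params = params)
}

# --- early stopping state machine ---------------------------------------------
# Strict-improvement rule: the best epoch is the first one attaining the
# minimum validation loss; training stops once `patience` consecutive epochs
# fail to improve on it.

es_init <- function(patience) {
  list(best = Inf, best_epoch = 0L, since = 0L, patience = patience,
       stop = FALSE, improved = FALSE)
}

es_step <- function(es, epoch, val_loss) {
  if (val_loss < es$best) {
    es$best <- val_loss; es$best_epoch <- epoch; es$since <- 0L
    es$improved <- TRUE
  } else {
    es$since <- es$since + 1L
    es$improved <- FALSE
    if (es$since >= es$patience) es$stop <- TRUE
  }
  es
}

# --- training loop ------------------------------------------------------------

#' Optimization loop shared by both training stages
#'
#' Adam with weight decay and a per-epoch cosine schedule; temporal jitter and
#' amplitude scaling are applied to training batches only; validation is
#' augmentation-free and runs in evaluation mode. Training stops early when
#' the validation loss has not improved for `patience` epochs, and the
#' returned model carries the parameters (and batch-norm statistics) of the
#' best validation epoch. Targets are z-scored with training-split statistics
#' for optimization; predictions are rescaled on evaluation.
#'
#' @param model a [dstage()] model.
#' @param cohort a cohort (see [generate_cohort()]) with split assignments.
#' @param cfg a [train_config()].
#' @param task integer task id passed to the encoder.
#' @param base_lr base learning rate (stage-dependent).
#' @param backbone logical; `FALSE` skips gradient computation for frozen
#'   backbone components (transfer stage).
#' @param verbose print one line per epoch.
#' @return An object of class `dstage_stage_result`: `model` (best
#'   checkpoint), `history` (data frame: epoch, train_loss, val_loss, lr),
#'   `best_epoch`, `target_stats` and `param_report`.
#' @export
train_loop <- function(model, cohort, cfg, task = 0L, base_lr = cfg$lr0,
                       backbone = NULL, verbose = FALSE,
                       feature_cache = NULL) {
  stopifnot(inherits(model, "dstage"), inherits(cfg, "dstage_train_config"))
  check_cohort(cohort)
  if (is.null(backbone)) {
    bb <- component_of(names(model$params)) %in%
      c("front_end", "temporal_path", "spatial_path", "st_gate")
    backbone <- any(model$trainable[names(model$params)][bb])
  }
  tr <- which(cohort$split == "train")
  va <- which(cohort$split == "val")
  if (length(tr) == 0L || length(va) == 0L) stop("empty train or validation split")
  set.seed(cfg$seed)
  x_all <- standardize_epochs(cohort$epochs)
  y_mu <- mean(cohort$labels[tr])
  y_sd <- stats::sd(cohort$labels[tr])
  if (y_sd == 0) y_sd <- 1
  y_all <- (cohort$labels - y_mu) / y_sd

  opt <- adam_init(model$params, model$trainable)
  es <- es_init(cfg$patience)
  best_params <- model$params; best_buffers <- model$buffers
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), lr = numeric())

  # A fully frozen backbone runs in inference mode; without augmentation its
  # features are input-fixed, so they are computed once and reused.
  frozen_bb <- backbone_frozen(model)
  use_cache <- frozen_bb && cfg$jitter_max_frames == 0L &&
    all(cfg$scale_range == 1)
  Tp <- model$config$T_prime
  if (use_cache)
    Hf_all <- if (is.null(feature_cache)) backbone_features(model, x_all) else
      feature_cache

  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- cosine_lr(epoch - 1L, cfg, base_lr)
    ord <- sample(tr)
    n_tr <- length(ord)
    batch_starts <- seq(1L, n_tr, by = cfg$batch_size)
    ep_loss <- 0
    for (s in batch_starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n_tr)]
      yb <- y_all[idx]
      if (use_cache) {
        rows <- rep((idx - 1L) * Tp, each = Tp) + seq_len(Tp)
        fw <- adapter_forward(model, Hf_all[rows, , drop = FALSE], task,
                              length(idx), training = TRUE)
      } else {
        xb <- x_all[, , idx, drop = FALSE]
        if (cfg$jitter_max_frames > 0L)
          xb <- augment_temporal_jitter(xb, cfg$jitter_max_frames)
        xb <- augment_amplitude_scale(xb, cfg$scale_range)
        fw <- model_forward(model, xb, task, training = !frozen_bb)
        if (!frozen_bb) {
          model$buffers[["bn.rmean"]] <- fw$bn_state$rmean
          model$buffers[["bn.rvar"]] <- fw$bn_state$rvar
        }
      }
      loss <- mse_loss(fw$pred, yb)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", epoch,
             " (diverged; reduce the learning rate)")
      ep_loss <- ep_loss + loss * length(idx)
      dpred <- 2 * (fw$pred - yb) / length(idx)
      grads <- if (use_cache) adapter_backward(model, fw$cache, dpred) else
        model_backward(model, fw$cache, dpred, backbone = backbone)
      st <- adam_step(opt, model$params, grads, lr, cfg$weight_decay)
      opt <- st$opt
      model$params <- st$params
    }
    train_loss <- ep_loss / n_tr
    if (use_cache) {
      rows <- rep((va - 1L) * Tp, each = Tp) + seq_len(Tp)
      val_pred <- adapter_forward(model, Hf_all[rows, , drop = FALSE], task,
                                  length(va), training = FALSE)$pred
    } else {
      val_pred <- predict_epochs(model, x_all[, , va, drop = FALSE], task)
    }
    val_loss <- mse_loss(val_pred, y_all[va])
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = train_loss,
                                   val_loss = val_loss, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e",
                      epoch, train_loss, val_loss, lr))
    es <- es_step(es, epoch, val_loss)
    if (es$improved) {
      best_params <- model$params; best_buffers <- model$buffers
    }
    if (es$stop) break
  }
  model$params <- best_params
  model$buffers <- best_buffers
  res <- list(model = model, history = hist, best_epoch = es$best_epoch,
              best_val_loss = es$best,
              target_stats = c(mu = y_mu, sd = y_sd),
              param_report = count_parameters(model))
  class(res) <- "dstage_stage_result"
  res
}

# Fused-feature cache: with the whole backbone frozen it runs in inference
# mode, so its output for a fixed input never changes; compute it once and
# train the adapter and head on the stored features. Only valid when the
# training batches see exactly the inputs the cache saw (no augmentation).
backbone_frozen <- function(model) {
  comp <- component_of(names(model$params))
  bb <- comp %in% c("front_end", "temporal_path", "spatial_path", "st_gate")
  !any(model$trainable[names(model$params)][bb])
}

backbone_features <- function(model, x, batch = 64L) {
  cfg <- model$config
  N <- dim(x)[3]; Tp <- cfg$T_prime
  Hf <- matrix(0, N * Tp, cfg$D_f)
  for (s in seq(1L, N, by = batch)) {
    idx <- s:min(s + batch - 1L, N)
    B <- length(idx)
    fe <- fe_forward(model, x[, , idx, drop = FALSE], training = FALSE)
    Ht <- if ("temporal" %in% cfg$paths)
      tp_forward(model, fe$Fmat, B, training = FALSE)$Ht else NULL
    Hs <- if ("spatial" %in% cfg$paths)
      sp_forward(model, fe$node, B, training = FALSE)$Hs else NULL
    fu <- fuse_forward(model, Ht, Hs, training = FALSE)
    rows <- rep((idx - 1L) * Tp, each = Tp) + seq_len(Tp)
    Hf[rows, ] <- fu$Hf
  }
  Hf
}

adapter_forward <- function(model, Hf_batch, task, B, training) {
  ta <- tar_forward(model, Hf_batch, task, training)
  hd <- head_forward(model, ta$Hout, B, training)
  list(pred = hd$pred, cache = list(ta = ta$cache, hd = hd$cache))
}

adapter_backward <- function(model, cache, dpred) {
  hb <- head_backward(model, cache$hd, dpred)
  tb <- tar_backward(model, cache$ta, hb$dHout)
  c(hb$grads, tb$grads)
}

# Batched evaluation-mode forward on standardized epochs (standardized target
# scale).
predict_epochs <- function(model, x, task, batch = 128L) {
  N <- dim(x)[3]
  out <- numeric(N)
  for (s in seq(1L, N, by = batch)) {
    idx <- s:min(s + batch - 1L, N)
    out[idx] <- model_forward(model, x[, , idx, drop = FALSE], task,
                              training = FALSE)$pred
  }
  out
}
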