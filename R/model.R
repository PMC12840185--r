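#' Build a dual-path spatio-temporal encoder
#'
#' Allocates and initializes all parameters of the encoder described by a
#' [dstage_config()]: the multi-scale dilated convolution front-end (a
#' channel-mixing stream projected to dimension `D` and a channel-preserving
#' depthwise stream feeding the graph path), the temporal transformer path,
#' the spatial graph-convolution path over the electrode adjacency, the
#' sigmoid fusion gate, the task-adaptive modulation block and the regression
#' head.
#'
#' The task-adaptive block is initialized as an exact identity: modulation
#' scale 1, shift 0, and a zero-initialized bottleneck output layer, so a
#' freshly attached adapter does not perturb the backbone's function.
#' Initialization draws from the current RNG state; call `set.seed()` first
#' for reproducible builds.
#'
#' Throughout the package, epoched signals are stored as
#' `channels x frames x epochs` arrays (column-major friendly); encoder
#' feature blocks are `frames x features` per epoch.
#'
#' @param config a [dstage_config()].
#' @param coords optional `C x 3` electrode coordinates; defaults to a
#'   deterministic spherical-cap layout ([electrode_coords()]).
#' @param A optional precomputed adjacency from [build_adjacency()];
#'   overrides `coords`.
#' @return An object of class `dstage`: a list with elements `config`,
#'   `params` (named list of weight arrays), `buffers` (batch-norm running
#'   statistics, positional encoding, adjacency, coordinates), `trainable`
#'   (named logical vector) and `stage` (`"untrained"` until fitted).
#' @export
dstage <- function(config = dstage_config(), coords = NULL, A = NULL) {
  validate_config(config)
  cfg <- config
  if (is.null(A)) {
    if (is.null(coords)) coords <- electrode_coords(cfg$C)
    A <- build_adjacency(coords, cfg$knn_k)
  } else {
    check_adjacency(A, cfg$C)
    if (is.null(coords)) coords <- electrode_coords(cfg$C)
  }
  p <- list()
  C <- cfg$C; D <- cfg$D; m <- cfg$dw_multiplier
  nb <- length(cfg$branch_specs)
  cat_dim <- sum(vapply(cfg$branch_specs, function(b) b[3], 1L))

  for (i in seq_len(nb)) {
    b <- cfg$branch_specs[[i]]
    k <- b[1]; ch <- b[3]
    p[[sprintf("fe.b%d.W", i)]] <- matrix(stats::rnorm(ch * C * k, 0, sqrt(2 / (C * k))), ch, C * k)
    p[[sprintf("fe.b%d.b", i)]] <- numeric(ch)
    if ("spatial" %in% cfg$paths) {
      p[[sprintf("fe.dw%d.w", i)]] <- array(stats::rnorm(C * m * k, 0, sqrt(1 / k)), c(C, m, k))
      p[[sprintf("fe.dw%d.b", i)]] <- matrix(0, C, m)
    }
  }
  p[["fe.proj.W"]] <- matrix(stats::rnorm(D * cat_dim, 0, sqrt(2 / cat_dim)), D, cat_dim)
  p[["fe.proj.b"]] <- numeric(D)
  p[["fe.bn.g"]] <- rep(1, D)
  p[["fe.bn.b"]] <- numeric(D)

  if ("temporal" %in% cfg$paths) {
    Dt <- cfg$D_t
    p[["tp.in.W"]] <- glorot(D, Dt)
    p[["tp.in.b"]] <- numeric(Dt)
    for (l in seq_len(cfg$L_t)) {
      pr <- sprintf("tp.l%d", l)
      p[[paste0(pr, ".ln1.g")]] <- rep(1, Dt); p[[paste0(pr, ".ln1.b")]] <- numeric(Dt)
      for (w in c("Wq", "Wk", "Wv", "Wo")) p[[paste0(pr, ".", w)]] <- glorot(Dt, Dt)
      for (b2 in c("bq", "bk", "bv", "bo")) p[[paste0(pr, ".", b2)]] <- numeric(Dt)
      p[[paste0(pr, ".lnc.g")]] <- rep(1, Dt); p[[paste0(pr, ".lnc.b")]] <- numeric(Dt)
      p[[paste0(pr, ".dw.w")]] <- matrix(stats::rnorm(Dt * cfg$dw_kernel, 0, sqrt(1 / cfg$dw_kernel)), Dt, cfg$dw_kernel)
      p[[paste0(pr, ".dw.b")]] <- numeric(Dt)
      p[[paste0(pr, ".ln2.g")]] <- rep(1, Dt); p[[paste0(pr, ".ln2.b")]] <- numeric(Dt)
      p[[paste0(pr, ".ff1.W")]] <- glorot(Dt, cfg$ffn_dim); p[[paste0(pr, ".ff1.b")]] <- numeric(cfg$ffn_dim)
      p[[paste0(pr, ".ff2.W")]] <- glorot(cfg$ffn_dim, Dt); p[[paste0(pr, ".ff2.b")]] <- numeric(Dt)
    }
    p[["tp.lnf.g"]] <- rep(1, Dt)
    p[["tp.lnf.b"]] <- numeric(Dt)
  }

  if ("spatial" %in% cfg$paths) {
    g_in <- nb * m
    dims <- c(g_in, cfg$g_dims)
    for (l in seq_len(cfg$L_g)) {
      p[[sprintf("sp.gcn%d.W", l)]] <- glorot(dims[l], dims[l + 1L])
      p[[sprintf("sp.gcn%d.b", l)]] <- numeric(dims[l + 1L])
    }
    p[["sp.proj.W"]] <- glorot(dims[length(dims)], cfg$D_s)
    p[["sp.proj.b"]] <- numeric(cfg$D_s)
  }

  Df <- cfg$D_f
  if ("temporal" %in% cfg$paths) {
    p[["fuse.pt.W"]] <- glorot(cfg$D_t, Df); p[["fuse.pt.b"]] <- numeric(Df)
  }
  if ("spatial" %in% cfg$paths) {
    p[["fuse.ps.W"]] <- glorot(cfg$D_s, Df); p[["fuse.ps.b"]] <- numeric(Df)
  }
  if (length(cfg$paths) == 2L) {
    if (cfg$fusion == "gate") {
      p[["fuse.g1.W"]] <- glorot(2L * Df, cfg$gate_hidden)
      p[["fuse.g1.b"]] <- numeric(cfg$gate_hidden)
      p[["fuse.g2.W"]] <- glorot(cfg$gate_hidden, Df)
      p[["fuse.g2.b"]] <- numeric(Df)
    } else if (cfg$fusion == "concat") {
      p[["fuse.cat.W"]] <- glorot(2L * Df, Df)
      p[["fuse.cat.b"]] <- numeric(Df)
    }
  }

  if (cfg$use_tar) {
    p[["tar.emb"]] <- matrix(stats::rnorm(cfg$n_tasks * cfg$D_e, 0, 1), cfg$n_tasks, cfg$D_e)
    p[["tar.Wg"]] <- matrix(0, cfg$D_e, Df)
    p[["tar.bg"]] <- rep(1, Df)
    p[["tar.Wb"]] <- matrix(0, cfg$D_e, Df)
    p[["tar.bb"]] <- numeric(Df)
    p[["tar.down.W"]] <- glorot(Df, cfg$bottleneck_dim)
    p[["tar.down.b"]] <- numeric(cfg$bottleneck_dim)
    p[["tar.up.W"]] <- matrix(0, cfg$bottleneck_dim, Df)   # zero-init: identity start
    p[["tar.up.b"]] <- numeric(Df)
  }

  p[["head.h.W"]] <- glorot(Df, cfg$head_hidden)
  p[["head.h.b"]] <- numeric(cfg$head_hidden)
  p[["head.o.W"]] <- glorot(cfg$head_hidden, 1L)
  p[["head.o.b"]] <- numeric(1L)

  buffers <- list(
    bn.rmean = numeric(D), bn.rvar = rep(1, D),
    pe = if ("temporal" %in% cfg$paths) positional_encoding(cfg$T_prime, cfg$D_t) else NULL,
    A = unclass(A), coords = coords
  )
  model <- list(config = cfg, params = p, buffers = buffers,
                trainable = stats::setNames(rep(TRUE, length(p)), names(p)),
                stage = "untrained")
  class(model) <- "dstage"
  model
}

component_of <- function(nms) {
  comp <- rep(NA_character_, length(nms))
  comp[startsWith(nms, "fe.")] <- "front_end"
  comp[startsWith(nms, "tp.")] <- "temporal_path"
  comp[startsWith(nms, "sp.")] <- "spatial_path"
  comp[startsWith(nms, "fuse.")] <- "st_gate"
  comp[startsWith(nms, "tar.")] <- "tar_block"
  comp[startsWith(nms, "head.")] <- "head"
  comp
}

#' Parameter accounting per architectural component
#'
#' Counts parameters in each component group (front-end, temporal path,
#' spatial path, fusion gate, task-adaptive block, head) and the trainable
#' subset under the model's current freeze state (see
#' [apply_freeze_policy()]). Counts depend only on array shapes, never on
#' weight values.
#'
#' @param model a [dstage()] model.
#' @return An object of class `dstage_param_report`: list with `components`
#'   (named integer vector), `total`, `trainable`, `trainable_fraction_pct`.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "dstage"))
  sizes <- vapply(model$params, length, 1L)
  comp <- component_of(names(sizes))
  groups <- c("front_end", "temporal_path", "spatial_path", "st_gate",
              "tar_block", "head")
  components <- vapply(groups, function(g) sum(sizes[comp == g]), 1L)
  total <- sum(components)
  trainable <- sum(sizes[model$trainable[names(sizes)]])
  rep <- list(components = components, total = total, trainable = trainable,
              trainable_fraction_pct = 100 * trainable / total)
  class(rep) <- "dstage_param_report"
  rep
}

#' @export
print.dstage_param_report <- function(x, ...) {
  cat("Parameter report\n")
  for (g in names(x$components))
    cat(sprintf("  %-14s %10s\n", g, format(x$components[[g]], big.mark = ",")))
  cat(sprintf("  %-14s %10s\n", "total", format(x$total, big.mark = ",")))
  cat(sprintf("  trainable: %s (%.1f%%)\n",
              format(x$trainable, big.mark = ","), x$trainable_fraction_pct))
  invisible(x)
}

#' Trainable parameter percentage
#'
#' @param report a `dstage_param_report` from [count_parameters()].
#' @return List with `pct` (exact percentage) and `pct_1dp` (rounded to one
#'   decimal, the conventional reporting form).
#' @export
trainable_fraction <- function(report) {
  stopifnot(inherits(report, "dstage_param_report"))
  if (report$total == 0) stop("parameter report has total = 0")
  pct <- 100 * report$trainable / report$total
  list(pct = pct, pct_1dp = round(pct, 1))
}

#' @export
print.dstage <- function(x, ...) {
  cat("Dual-path spatio-temporal encoder (stage: ", x$stage, ")\n", sep = "")
  print(x$config)
  print(count_parameters(x))
  invisible(x)
}

check_signal <- function(x, cfg) {
  if (length(dim(x)) != 3L)
    stop("signal must be a channels x frames x epochs array")
  if (dim(x)[1] != cfg$C || dim(x)[2] != cfg$T_in)
    stop("signal is ", dim(x)[1], " x ", dim(x)[2],
         " but the model expects C=", cfg$C, ", T=", cfg$T_in)
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  invisible(x)
}
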