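COHORT_SCHEMA_VERSION <- 1L

#' Write / read a cohort HDF5 file
#'
#' The on-disk layout holds datasets `epochs` (float, channels x frames x
#' epochs), `labels` (float), `subject` (int), `split` (int8: 0 train,
#' 1 val, 2 test; -1 unassigned), `channel_names` (string) and `coords`
#' (float, channels x 3), plus root attributes `fs_hz`, `label_kind` and
#' `schema_version`. Round-trips are lossless for float32 payloads.
#'
#' @param cohort a `dstage_cohort`.
#' @param path file path (`.h5`).
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns the
#'   cohort.
#' @export
write_cohort <- function(cohort, path) {
  check_cohort(cohort)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  h5 <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(h5), add = TRUE)
  rhdf5::h5writeDataset(cohort$epochs, h5, "epochs")
  rhdf5::h5writeDataset(cohort$labels, h5, "labels")
  rhdf5::h5writeDataset(as.integer(cohort$subject), h5, "subject")
  split_code <- if (is.null(cohort$split)) rep(-1L, length(cohort$labels)) else
    c(train = 0L, val = 1L, test = 2L)[cohort$split]
  rhdf5::h5writeDataset(as.integer(unname(split_code)), h5, "split")
  rhdf5::h5writeDataset(cohort$channel_names, h5, "channel_names")
  rhdf5::h5writeDataset(unclass(cohort$coords), h5, "coords")
  rhdf5::h5writeAttribute(cohort$fs_hz, h5, "fs_hz")
  rhdf5::h5writeAttribute(cohort$label_kind, h5, "label_kind")
  rhdf5::h5writeAttribute(COHORT_SCHEMA_VERSION, h5, "schema_version")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such cohort file: ", path)
  need <- c("epochs", "labels", "subject", "split", "channel_names", "coords")
  have <- rhdf5::h5ls(path)$name
  missing <- setdiff(need, have)
  if (length(missing) > 0L)
    stop("cohort file is missing dataset(s): ", paste(missing, collapse = ", "))
  at <- rhdf5::h5readAttributes(path, "/")
  if (is.null(at$schema_version) || at$schema_version != COHORT_SCHEMA_VERSION)
    stop("cohort schema version mismatch (expected ", COHORT_SCHEMA_VERSION, ")")
  if (is.null(at$label_kind)) stop("cohort file lacks the label_kind attribute")
  epochs <- rhdf5::h5read(path, "epochs")
  labels <- as.numeric(rhdf5::h5read(path, "labels"))
  subject <- as.integer(rhdf5::h5read(path, "subject"))
  split_code <- as.integer(rhdf5::h5read(path, "split"))
  N <- dim(epochs)[3]
  if (length(labels) != N)
    stop("dataset 'labels' has length ", length(labels), " but 'epochs' holds ",
         N, " epochs")
  if (length(subject) != N) stop("dataset 'subject' has wrong length")
  split <- if (all(split_code == -1L)) NULL else
    c("train", "val", "test")[split_code + 1L]
  new_cohort(epochs, labels, as.character(at$label_kind), subject,
             split = split, coords = rhdf5::h5read(path, "coords"),
             channel_names = as.character(rhdf5::h5read(path, "channel_names")),
             fs_hz = as.numeric(at$fs_hz))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(unlist(config)), format(unlist(config)), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the weights, the full configuration,
#' buffers (adjacency, normalization statistics), the freeze-policy tag, the
#' stage tag, target rescaling statistics when saved from a fit, and a
#' configuration hash checked on load.
#'
#' @param object a `dstage` model or `dstage_fit`.
#' @param path destination file.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a `dstage` model (with `target_stats` attribute when present).
#' @export
save_checkpoint <- function(object, path) {
  model <- if (inherits(object, "dstage_fit")) object$model else object
  stopifnot(inherits(model, "dstage"))
  ck <- list(params = model$params, config = model$config,
             buffers = model$buffers, trainable = model$trainable,
             stage = model$stage, policy = model$policy,
             target_stats = if (inherits(object, "dstage_fit"))
               object$target_stats else NULL,
             task = if (inherits(object, "dstage_fit")) object$task else NULL,
             config_hash = config_hash(model$config))
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$config_hash, config_hash(ck$config)))
    stop("checkpoint configuration hash mismatch")
  model <- list(config = ck$config, params = ck$params, buffers = ck$buffers,
                trainable = ck$trainable, stage = ck$stage)
  model$policy <- ck$policy
  class(model) <- "dstage"
  attr(model, "target_stats") <- ck$target_stats
  attr(model, "task") <- ck$task
  model
}

# --- TOML configuration -------------------------------------------------------

#' Read a TOML configuration file
#'
#' Sections: `[model]` (arguments of [dstage_config()]; `branch_specs` as an
#' array of `[kernel, dilation, channels]` arrays), `[training]` and
#' `[transfer]` (arguments of [train_config()]; the transfer section holds
#' overrides), `[synthetic]` (arguments of [synthetic_config()]) and
#' `[experiment]` (`variants`, `seeds`). Unknown keys in any section are
#' errors.
#'
#' @param path TOML file.
#' @return List with elements `model` (`dstage_config`), `training`
#'   (`dstage_train_config`), `transfer` (named override list), `synthetic`
#'   (`dstage_synth_config` or `NULL`) and `experiment` (list or `NULL`).
#' @export
read_config_toml <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  tm <- RcppTOML::parseTOML(path)
  known_sections <- c("model", "training", "transfer", "synthetic", "experiment")
  bad <- setdiff(names(tm), known_sections)
  if (length(bad) > 0L)
    stop("unknown config section(s): ", paste(bad, collapse = ", "))
  section_call <- function(sec, fn) {
    if (is.null(tm[[sec]])) return(NULL)
    args <- tm[[sec]]
    unknown <- setdiff(names(args), names(formals(fn)))
    if (length(unknown) > 0L)
      stop("unknown key(s) in [", sec, "]: ", paste(unknown, collapse = ", "))
    args
  }
  marg <- section_call("model", dstage_config)
  if (!is.null(marg) && !is.null(marg$branch_specs))
    marg$branch_specs <- lapply(marg$branch_specs, as.integer)
  targ <- section_call("training", train_config)
  xarg <- section_call("transfer", train_config)
  sarg <- section_call("synthetic", synthetic_config)
  if (!is.null(tm$experiment)) {
    unknown <- setdiff(names(tm$experiment), c("variants", "seeds"))
    if (length(unknown) > 0L)
      stop("unknown key(s) in [experiment]: ", paste(unknown, collapse = ", "))
  }
  list(model = if (is.null(marg)) dstage_config() else do.call(dstage_config, marg),
       training = if (is.null(targ)) train_config() else do.call(train_config, targ),
       transfer = xarg,
       synthetic = if (is.null(sarg)) NULL else do.call(synthetic_config, sarg),
       experiment = tm$experiment)
}

# Training config for the transfer stage: stage-1 config plus [transfer]
# overrides.
transfer_train_config <- function(conf) {
  base <- unclass(conf$training)
  if (!is.null(conf$transfer)) base[names(conf$transfer)] <- conf$transfer
  do.call(train_config, base[names(base) %in% names(formals(train_config))])
}

#' Write a training history as CSV
#'
#' @param fit a `dstage_fit`.
#' @param path destination CSV (columns epoch, train_loss, val_loss, lr).
#' @export
write_history <- function(fit, path) {
  utils::write.csv(fit$history, path, row.names = FALSE)
  invisible(path)
}
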