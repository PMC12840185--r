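#' Construct an epoched EEG cohort
#'
#' A cohort bundles epoched signals with per-epoch labels, subject identity,
#' split assignment and montage metadata. Epochs are stored as a
#' `channels x frames x epochs` array. Splits are subject-grouped: every
#' epoch of a subject carries the same split label.
#'
#' @param epochs `channels x frames x epochs` numeric array.
#' @param labels numeric vector, one value per epoch (trial reaction time in
#'   ms, or the subject's general-psychopathology score repeated over that
#'   subject's epochs).
#' @param label_kind `"rt_ms"` or `"pfactor"`.
#' @param subject integer vector of subject ids, one per epoch.
#' @param split character vector (`"train"`, `"val"`, `"test"`) per epoch, or
#'   `NULL` before assignment.
#' @param coords `channels x 3` electrode coordinates.
#' @param channel_names optional channel labels.
#' @param fs_hz sampling rate in Hz.
#' @param gen_meta optional generator bookkeeping (component variances).
#' @return An object of class `dstage_cohort`.
#' @export
new_cohort <- function(epochs, labels, label_kind, subject, split = NULL,
                       coords = NULL, channel_names = NULL, fs_hz = 100,
                       gen_meta = NULL) {
  co <- list(epochs = epochs, labels = as.numeric(labels),
             label_kind = label_kind, subject = as.integer(subject),
             split = split,
             coords = if (is.null(coords)) electrode_coords(dim(epochs)[1]) else coords,
             channel_names = if (is.null(channel_names))
               sprintf("E%03d", seq_len(dim(epochs)[1])) else channel_names,
             fs_hz = fs_hz, gen_meta = gen_meta)
  class(co) <- "dstage_cohort"
  check_cohort(co)
  co
}

check_cohort <- function(co) {
  stopifnot(inherits(co, "dstage_cohort"))
  N <- dim(co$epochs)[3]
  if (length(co$labels) != N || length(co$subject) != N)
    stop("labels and subject ids must have one entry per epoch")
  if (!co$label_kind %in% c("rt_ms", "pfactor"))
    stop("label_kind must be 'rt_ms' or 'pfactor'")
  if (!all(is.finite(co$epochs))) stop("epochs contain non-finite values")
  if (!all(is.finite(co$labels))) stop("labels contain non-finite values")
  if (!is.null(co$split)) {
    if (length(co$split) != N) stop("split must have one entry per epoch")
    if (!all(co$split %in% c("train", "val", "test")))
      stop("split labels must be train/val/test")
    tab <- unique(data.frame(subject = co$subject, split = co$split))
    if (anyDuplicated(tab$subject))
      stop("subject-grouped splits violated: a subject appears in two splits")
  }
  if (nrow(co$coords) != dim(co$epochs)[1])
    stop("coords must have one row per channel")
  invisible(co)
}

#' @export
print.dstage_cohort <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("EEG cohort: %d epochs x %d channels x %d frames @ %g Hz\n",
              d[3], d[1], d[2], x$fs_hz))
  cat(sprintf("  label: %s (range %.3g..%.3g), %d subjects\n", x$label_kind,
              min(x$labels), max(x$labels), length(unique(x$subject))))
  if (!is.null(x$split)) {
    tb <- table(x$split)[c("train", "val", "test")]
    cat("  split epochs:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Subject-grouped split assignment
#'
#' Permutes subjects with the given seed and assigns whole subjects to
#' train/validation/test by the requested fractions, so no subject
#' contributes epochs to two splits. Subject counts are
#' `floor(fraction * n_subjects)` for train and validation (at least 1 each)
#' and the remainder for test.
#'
#' @param cohort a `dstage_cohort`.
#' @param fractions length-3 vector summing to 1.
#' @param seed integer seed for the subject permutation.
#' @return The cohort with its `split` field assigned.
#' @export
split_by_subject <- function(cohort, fractions = c(0.6, 0.2, 0.2), seed = 0L) {
  check_cohort(cohort)
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  subs <- unique(cohort$subject)
  S <- length(subs)
  n_tr <- max(1L, floor(fractions[1] * S))
  n_va <- max(1L, floor(fractions[2] * S))
  n_te <- S - n_tr - n_va
  if (n_va < 1L || n_te < 1L)
    stop("split would leave an empty validation or test set (", S, " subjects)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  perm <- sample(subs)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  assign_split <- c(rep("train", n_tr), rep("val", n_va), rep("test", n_te))
  map <- stats::setNames(assign_split, perm)
  cohort$split <- unname(map[as.character(cohort$subject)])
  check_cohort(cohort)
  cohort
}
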