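# Minimal EDF (European Data Format) support: enough to ingest continuous
# multichannel recordings written by standard acquisition software. EDF is a
# fixed-layout ASCII header followed by 16-bit little-endian data records;
# values map linearly from digital to physical range per signal.

edf_read_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Read a continuous EDF recording
#'
#' Parses the header and all data records, converting digital values to
#' physical units. All signals must share one sampling rate (epoched ingest
#' has no use for mixed-rate annotations channels).
#'
#' @param path EDF file.
#' @return List with `signals` (channels x samples matrix), `fs_hz`,
#'   `channel_names`, `patient`, `recording`, `duration_s`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- edf_read_ascii(con, 8L)
  patient <- edf_read_ascii(con, 80L)
  recording <- edf_read_ascii(con, 80L)
  edf_read_ascii(con, 16L)                       # start date + time
  edf_read_ascii(con, 8L)                        # header length
  edf_read_ascii(con, 44L)                       # reserved
  n_records <- as.integer(edf_read_ascii(con, 8L))
  rec_dur <- as.numeric(edf_read_ascii(con, 8L))
  ns <- as.integer(edf_read_ascii(con, 4L))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header (signal count)")
  field <- function(w) vapply(seq_len(ns), function(i) edf_read_ascii(con, w), "")
  labels <- field(16L)
  field(80L)                                     # transducer
  field(8L)                                      # physical dimension
  pmin_ <- as.numeric(field(8L)); pmax_ <- as.numeric(field(8L))
  dmin_ <- as.numeric(field(8L)); dmax_ <- as.numeric(field(8L))
  field(80L)                                     # prefilter
  spr <- as.integer(field(8L))                   # samples per record
  field(32L)                                     # reserved
  if (length(unique(spr)) != 1L)
    stop("EDF signals have differing sampling rates; ingest requires one rate")
  fs <- spr[1] / rec_dur
  sig <- matrix(0, ns, n_records * spr[1])
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (r in seq_len(n_records)) {
    block <- readBin(con, "integer", n = ns * spr[1], size = 2L,
                     endian = "little", signed = TRUE)
    M <- matrix(block, spr[1], ns)               # one column per signal
    cols <- (r - 1L) * spr[1] + seq_len(spr[1])
    sig[, cols] <- t(sweep(sweep(M, 2L, dmin_), 2L, scale, "*") +
                       matrix(pmin_, spr[1], ns, byrow = TRUE))
  }
  list(signals = sig, fs_hz = fs, channel_names = labels, patient = patient,
       recording = recording, duration_s = n_records * rec_dur,
       version = version)
}

# Write a minimal EDF file (one sampling rate). Used to build synthetic
# fixtures in tests and examples; physical range is set from the data.
write_edf <- function(signals, fs_hz, path, channel_names = NULL,
                      patient = "X", recording = "synthetic") {
  C <- nrow(signals); n <- ncol(signals)
  if (is.null(channel_names)) channel_names <- sprintf("E%03d", seq_len(C))
  rec_dur <- 1
  spr <- as.integer(fs_hz * rec_dur)
  n_records <- floor(n / spr)
  pmax_ <- max(abs(signals)) * 1.0001 + 1e-6
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) {
    s <- formatC(as.character(x), width = -w)
    writeBin(charToRaw(substr(s, 1, w)), con)
  }
  pad("0", 8); pad(patient, 80); pad(recording, 80)
  pad("01.01.26", 8); pad("00.00.00", 8)
  pad(256L + 256L * C, 8); pad("", 44)
  pad(n_records, 8); pad(format(rec_dur), 8); pad(C, 4)
  for (nm in channel_names) pad(nm, 16)
  for (i in seq_len(C)) pad("synthetic", 80)
  for (i in seq_len(C)) pad("uV", 8)
  for (i in seq_len(C)) pad(format(-pmax_, digits = 6), 8)
  for (i in seq_len(C)) pad(format(pmax_, digits = 6), 8)
  for (i in seq_len(C)) pad(-32768L, 8)
  for (i in seq_len(C)) pad(32767L, 8)
  for (i in seq_len(C)) pad("", 80)
  for (i in seq_len(C)) pad(spr, 8)
  for (i in seq_len(C)) pad("", 32)
  dig <- round((signals + pmax_) / (2 * pmax_) * 65535 - 32768)
  dig <- pmin(pmax(dig, -32768), 32767)
  for (r in seq_len(n_records)) {
    cols <- (r - 1L) * spr + seq_len(spr)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Ingest epoched data from an EDF recording
#'
#' Cuts one epoch per event from a continuous EDF recording, resamples it to
#' the target frame rate by linear interpolation, and pairs it with the
#' event's label. Events whose window exceeds the record are skipped with a
#' warning. The subject id is taken from the EDF patient field when numeric,
#' else assigned as 1.
#'
#' @param path EDF file.
#' @param events data frame with columns `onset_s` (stimulus onset, seconds
#'   from record start) and `label` (numeric).
#' @param epoch_window `c(start, end)` in seconds relative to each onset.
#' @param target_fs output frame rate (Hz); the epoch is resampled to
#'   `(end - start) * target_fs` frames.
#' @param label_kind label tag for the resulting cohort.
#' @return A `dstage_cohort` (without split assignment).
#' @export
ingest_edf <- function(path, events, epoch_window = c(0.5, 2.5),
                       target_fs = 100, label_kind = "rt_ms") {
  rec <- read_edf(path)
  if (nrow(events) == 0L) stop("no events supplied")
  if (!all(c("onset_s", "label") %in% names(events)))
    stop("events must have columns onset_s and label")
  win_len <- epoch_window[2] - epoch_window[1]
  T_out <- as.integer(round(win_len * target_fs))
  C <- nrow(rec$signals)
  n_samp <- ncol(rec$signals)
  keep <- list(); labels <- numeric()
  for (i in seq_len(nrow(events))) {
    a <- events$onset_s[i] + epoch_window[1]
    b <- events$onset_s[i] + epoch_window[2]
    i0 <- floor(a * rec$fs_hz) + 1L
    i1 <- ceiling(b * rec$fs_hz)
    if (i0 < 1L || i1 > n_samp) {
      warning("event ", i, " window exceeds the record; epoch skipped")
      next
    }
    src_t <- (seq(i0, i1) - 1L) / rec$fs_hz
    out_t <- a + (seq_len(T_out) - 0.5) / target_fs
    ep <- matrix(0, C, T_out)
    for (ch in seq_len(C))
      ep[ch, ] <- stats::approx(src_t, rec$signals[ch, i0:i1], xout = out_t,
                                rule = 2)$y
    keep[[length(keep) + 1L]] <- ep
    labels <- c(labels, events$label[i])
  }
  if (length(keep) == 0L) stop("no usable events (all windows out of range)")
  epochs <- array(unlist(keep), c(C, T_out, length(keep)))
  epochs <- standardize_epochs(epochs)
  subj <- suppressWarnings(as.integer(gsub("\\D", "", rec$patient)))
  if (is.na(subj)) subj <- 1L
  new_cohort(epochs, labels, label_kind, rep(subj, length(keep)),
             channel_names = rec$channel_names, fs_hz = target_fs)
}
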