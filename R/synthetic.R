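#' Configuration of the hierarchical synthetic EEG cohort
#'
#' The generator emulates a cognitive-task EEG study in which one latent
#' per-subject efficiency variable drives both behaviour and physiology.
#' Per subject `i`, a latent `z_i ~ N(0,1)` sets the subject's
#' psychopathology score `p_i = -a_p * z_i + noise`; per trial `j`, a trial
#' efficiency `e_ij = z_i + noise` sets the reaction time
#' `RT_ij = mu_rt - beta_rt * e_ij + noise`, floored at 150 ms. Each epoch's
#' signal is the sum of (i) a 10 Hz alpha carrier whose amplitude decreases
#' monotonically with trial efficiency (`base * (1 - 0.5 * tanh(e))`),
#' spread over channels by a smooth posterior topography; (ii) an evoked
#' Gaussian bump centred at the frame corresponding to the trial's reaction
#' time within the 0.5-2.5 s post-stimulus window, with a centro-parietal
#' topography; and (iii) per-channel 1/f (pink) noise. Epochs are shared
#' between the reaction-time and psychopathology cohorts; only the labels
#' differ.
#'
#' @param n_subjects number of subjects (>= 3).
#' @param epochs_per_subject trials per subject (>= 1).
#' @param C,T_len,fs_hz signal geometry: channels, frames, sampling rate;
#'   the epoch is assumed to start 0.5 s post-stimulus.
#' @param mu_rt,beta_rt mean reaction time and latent-to-RT slope (ms per
#'   latent sd).
#' @param rt_noise_sd trial-level RT noise sd (ms).
#' @param trial_latent_sd sd of the trial-level efficiency noise around the
#'   subject latent.
#' @param a_p latent-to-psychopathology slope.
#' @param p_noise_sd subject-level psychopathology noise sd.
#' @param alpha_freq,alpha_base alpha carrier frequency (Hz) and base
#'   amplitude.
#' @param bump_amp,bump_width_s evoked bump amplitude and Gaussian width (s).
#' @param pink_sd pink-noise standard deviation.
#' @param seed cohort seed controlling every random draw.
#' @return An object of class `dstage_synth_config`.
#' @export
synthetic_config <- function(n_subjects = 60L, epochs_per_subject = 50L,
                             C = 16L, T_len = 200L, fs_hz = 100,
                             mu_rt = 600, beta_rt = 150, rt_noise_sd = 100,
                             trial_latent_sd = 0.5,
                             a_p = 0.8, p_noise_sd = 0.45,
                             alpha_freq = 10, alpha_base = 1.5,
                             bump_amp = 2, bump_width_s = 0.05,
                             pink_sd = 1, seed = 0L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              epochs_per_subject = as.integer(epochs_per_subject),
              C = as.integer(C), T_len = as.integer(T_len), fs_hz = fs_hz,
              mu_rt = mu_rt, beta_rt = beta_rt, rt_noise_sd = rt_noise_sd,
              trial_latent_sd = trial_latent_sd, a_p = a_p,
              p_noise_sd = p_noise_sd, alpha_freq = alpha_freq,
              alpha_base = alpha_base, bump_amp = bump_amp,
              bump_width_s = bump_width_s, pink_sd = pink_sd,
              seed = as.integer(seed))
  if (cfg$n_subjects < 3L) stop("need at least 3 subjects")
  if (cfg$epochs_per_subject < 1L) stop("need at least 1 epoch per subject")
  if (any(c(rt_noise_sd, trial_latent_sd, p_noise_sd, pink_sd) < 0))
    stop("noise standard deviations must be nonnegative")
  class(cfg) <- "dstage_synth_config"
  cfg
}

# 1/f-shaped noise: white noise spectrally reweighted by 1/sqrt(f), rescaled
# to unit sd. Columns of the returned T x n matrix are independent.
pink_noise <- function(T_len, n) {
  W <- stats::mvfft(matrix(stats::rnorm(T_len * n), T_len, n))
  k <- seq_len(T_len) - 1L
  f <- pmin(k, T_len - k)         # symmetric frequency index
  s <- ifelse(f == 0, 0, 1 / sqrt(f))
  X <- Re(stats::mvfft(W * s, inverse = TRUE)) / T_len
  sdv <- sqrt(colMeans(X^2))
  sweep(X, 2L, pmax(sdv, 1e-12), "/")
}

smooth_topography <- function(coords, center, tau = 0.5) {
  d2 <- rowSums(sweep(coords, 2L, center / sqrt(sum(center^2)))^2)
  0.25 + 0.75 * exp(-d2 / tau)
}

#' Generate paired synthetic cohorts
#'
#' Draws a full cohort under the hierarchical generative model of
#' [synthetic_config()] and returns the reaction-time view (trial labels, ms)
#' and the psychopathology view (subject labels repeated over epochs) of the
#' same epochs. Both cohorts receive the same subject-grouped train/val/test
#' split (fractions 0.6/0.2/0.2, derived from the cohort seed). Identical
#' configurations produce bitwise-identical cohorts.
#'
#' @param cfg a [synthetic_config()].
#' @return List with `rt` and `pfactor`, both `dstage_cohort`s.
#' @export
generate_cohort <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "dstage_synth_config"))
  set.seed(cfg$seed)
  S <- cfg$n_subjects; E <- cfg$epochs_per_subject
  N <- S * E; C <- cfg$C; T_len <- cfg$T_len
  z <- stats::rnorm(S)
  p <- -cfg$a_p * z + stats::rnorm(S, 0, cfg$p_noise_sd)
  subject <- rep(seq_len(S), each = E)
  e_trial <- z[subject] + stats::rnorm(N, 0, cfg$trial_latent_sd)
  rt <- cfg$mu_rt - cfg$beta_rt * e_trial + stats::rnorm(N, 0, cfg$rt_noise_sd)
  rt <- pmax(rt, 150)

  coords <- electrode_coords(C)
  w_alpha <- smooth_topography(coords, c(0, -0.8, 0.6))
  w_bump <- smooth_topography(coords, c(0, 0.2, 1))
  tt <- (seq_len(T_len) - 1L) / cfg$fs_hz
  amp <- cfg$alpha_base * (1 - 0.5 * tanh(e_trial))
  phase <- stats::runif(N, 0, 2 * pi)
  t0 <- (rt / 1000 - 0.5)                     # epoch starts 0.5 s post-stimulus
  t0 <- pmin(pmax(t0, 0), (T_len - 1L) / cfg$fs_hz)
  sig_w <- cfg$bump_width_s

  epochs <- array(0, c(C, T_len, N))
  comp_var <- matrix(0, N, 3L, dimnames = list(NULL, c("alpha", "bump", "pink")))
  for (n in seq_len(N)) {
    carrier <- amp[n] * sin(2 * pi * cfg$alpha_freq * tt + phase[n])
    bump <- cfg$bump_amp * exp(-(tt - t0[n])^2 / (2 * sig_w^2))
    clean <- outer(w_alpha, carrier) + outer(w_bump, bump)
    epochs[, , n] <- clean
    comp_var[n, "alpha"] <- stats::var(carrier) * mean(w_alpha^2)
    comp_var[n, "bump"] <- stats::var(bump) * mean(w_bump^2)
  }
  if (cfg$pink_sd > 0) {
    for (s in seq_len(S)) {
      idx <- which(subject == s)
      pn <- cfg$pink_sd * pink_noise(T_len, C * length(idx))
      epochs[, , idx] <- epochs[, , idx] +
        aperm(array(pn, c(T_len, C, length(idx))), c(2, 1, 3))
      comp_var[idx, "pink"] <- cfg$pink_sd^2
    }
  }
  meta <- list(config = cfg, component_var = comp_var, latent = z,
               trial_efficiency = e_trial)
  rt_co <- new_cohort(epochs, rt, "rt_ms", subject, coords = coords,
                      fs_hz = cfg$fs_hz, gen_meta = meta)
  pf_co <- new_cohort(epochs, p[subject], "pfactor", subject, coords = coords,
                      fs_hz = cfg$fs_hz, gen_meta = meta)
  rt_co <- split_by_subject(rt_co, c(0.6, 0.2, 0.2), seed = cfg$seed)
  pf_co$split <- rt_co$split
  list(rt = rt_co, pfactor = pf_co)
}

#' Signal-composition and label summary of a cohort
#'
#' Aggregates the generator's per-epoch component variances (alpha carrier,
#' evoked bump, pink noise) into variance shares, and summarizes the label
#' distribution. Available for generated cohorts only (the decomposition
#' requires generator bookkeeping).
#'
#' @param cohort a generated `dstage_cohort`.
#' @return List with `variance_share` (named numeric, sums to 1),
#'   `mean_component_var`, and `label_summary`.
#' @export
snr_report <- function(cohort) {
  check_cohort(cohort)
  if (is.null(cohort$gen_meta))
    stop("snr_report requires a generated cohort (no component bookkeeping)")
  cv <- cohort$gen_meta$component_var
  mean_var <- colMeans(cv)
  share <- mean_var / sum(mean_var)
  list(variance_share = share, mean_component_var = mean_var,
       label_summary = summary(cohort$labels))
}

#' Per-epoch alpha-band log-power features
#'
#' Channel-wise band power in `band` Hz from the periodogram of each epoch;
#' used as a linear-probe sanity floor for cohort learnability.
#'
#' @param cohort a `dstage_cohort`.
#' @param band length-2 frequency band in Hz.
#' @return `epochs x channels` matrix of log band power.
#' @export
alpha_band_power <- function(cohort, band = c(8, 12)) {
  x <- cohort$epochs
  C <- dim(x)[1]; T_len <- dim(x)[2]; N <- dim(x)[3]
  M <- matrix(aperm(x, c(2, 1, 3)), T_len, C * N)
  P <- Mod(stats::mvfft(M))^2 / T_len
  fr <- (seq_len(T_len) - 1L) * cohort$fs_hz / T_len
  sel <- fr >= band[1] & fr <= band[2]
  bp <- colSums(P[sel, , drop = FALSE])
  t(matrix(log(bp + 1e-12), C, N))
}
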