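#' Standard 32-channel montage
#'
#' Channel labels of the 32-electrode 10-20 layout used throughout the
#' package (BioSemi ordering), optionally with the two mastoid reference
#' channels appended.
#'
#' @param with_mastoids Append the two mastoid labels `M1`, `M2`.
#' @return Character vector of channel labels.
#' @export
montage_32 <- function(with_mastoids = TRUE) {
  scalp <- c("Fp1", "AF3", "F7", "F3", "FC1", "FC5", "T7", "C3",
             "CP1", "CP5", "P7", "P3", "Pz", "PO3", "O1", "Oz",
             "O2", "PO4", "P4", "P8", "CP6", "CP2", "C4", "T8",
             "FC6", "FC2", "F4", "F8", "AF4", "Fp2", "Fz", "Cz")
  if (with_mastoids) c(scalp, "M1", "M2") else scalp
}

# named gain map over the 32 scalp channels, peak 1 at `peak`, falling off
# by listed groups; channels not listed get `floor`
.topography <- function(groups, floor = 0.1) {
  g <- setNames(rep(floor, 32), montage_32(FALSE))
  for (i in seq_along(groups)) g[names(groups)[[i]]] <- groups[[i]]
  g
}

.p300_topography <- function() {
  .topography(list(
    "Pz" = 1, "CP1" = 0.9, "CP2" = 0.9, "Cz" = 0.9,
    "P3" = 0.85, "P4" = 0.85, "CP5" = 0.7, "CP6" = 0.7,
    "C3" = 0.7, "C4" = 0.7, "PO3" = 0.6, "PO4" = 0.6,
    "P7" = 0.55, "P8" = 0.55, "O1" = 0.5, "O2" = 0.5, "Oz" = 0.5,
    "FC1" = 0.6, "FC2" = 0.6, "Fz" = 0.6, "FC5" = 0.45, "FC6" = 0.45,
    "F3" = 0.4, "F4" = 0.4, "T7" = 0.35, "T8" = 0.35,
    "F7" = 0.25, "F8" = 0.25, "AF3" = 0.25, "AF4" = 0.25,
    "Fp1" = 0.2, "Fp2" = 0.2), floor = 0.2)
}

.parieto_occipital_topography <- function() {
  .topography(list(
    "PO3" = 1, "PO4" = 1, "O1" = 0.9, "O2" = 0.9, "Oz" = 0.9,
    "P3" = 0.8, "P4" = 0.8, "Pz" = 0.8, "P7" = 0.6, "P8" = 0.6,
    "CP1" = 0.5, "CP2" = 0.5, "CP5" = 0.4, "CP6" = 0.4), floor = 0.1)
}

.ssvep_topography <- function() {
  .topography(list(
    "Oz" = 1, "O1" = 0.85, "O2" = 0.85, "PO3" = 0.7, "PO4" = 0.7,
    "P7" = 0.4, "P8" = 0.4, "Pz" = 0.4, "P3" = 0.35, "P4" = 0.35),
    floor = 0.05)
}

#' Synthetic-subject response profile
#'
#' Parameterizes the evoked responses and background EEG of one simulated
#' subject.  The defaults describe a typical responsive subject of a visual
#' BCI study: a ~5 microvolt P300 with parieto-central maximum around
#' 350 ms, an early parieto-occipital negativity between 100 and 200 ms,
#' photic driving at the flicker frequency and its 2nd/3rd harmonics with
#' an occipital maximum at Oz, and 1/f-shaped background noise.
#'
#' @param p300_amplitude Peak amplitude of the P300 bump, microvolts.
#' @param p300_latency Latency of the P300 peak, seconds after flash onset.
#' @param p300_width Gaussian SD of the P300 bump, seconds.
#' @param early_negativity_amplitude Magnitude (positive number, applied
#'   with negative sign) of the early negativity, microvolts.
#' @param early_negativity_latency Peak latency of the early negativity,
#'   seconds (100--200 ms band).
#' @param early_negativity_width Gaussian SD of the negativity, seconds.
#' @param ssvep_harmonic_amplitudes Amplitudes, microvolts, of the flicker
#'   response at harmonics 1--3 (fundamental, 2f, 3f).  Either a numeric
#'   triplet used for every stimulation frequency, or a named list of
#'   triplets keyed by frequency (names matched via `format(freq)`), which
#'   lets harmonic profiles vary across frequencies as they do across
#'   subjects.
#' @param attention_gain Multiplier (>= 1) on the flicker amplitudes of the
#'   attended panel relative to unattended panels.
#' @param nontarget_erp_scale Fraction of the ERP template evoked by
#'   non-target flashes (exogenous response); 0 by default.
#' @param noise_scale RMS of the background noise per channel, microvolts.
#' @param noise_spectral_exponent Exponent beta of the 1/f^beta noise
#'   spectrum.
#' @param noise_smear Spatial smearing strength in \[0, 1\): 0 gives
#'   channel-independent noise, larger values mix noise across channels,
#'   giving realistic inter-channel correlation.
#' @param artifact_rate Mean rate, per second, of ocular-artifact
#'   square-pulse transients on the frontal channels (default 0: none).
#'   They exist to exercise the peak-to-peak rejection operator.
#' @param artifact_amplitude Amplitude of the artifact pulses, microvolts.
#' @param p300_topography,early_negativity_topography,ssvep_topography
#'   Named per-channel gain vectors in \[0, 1\] over the 32 scalp channels
#'   (at least one channel at 1).
#' @return An object of class `subject_profile`.
#' @examples
#' prof <- subject_profile()                      # typical subject
#' silent <- subject_profile(p300_amplitude = 0,  # no evoked activity
#'                           early_negativity_amplitude = 0,
#'                           ssvep_harmonic_amplitudes = c(0, 0, 0))
#' @export
subject_profile <- function(p300_amplitude = 5,
                            p300_latency = 0.350,
                            p300_width = 0.060,
                            early_negativity_amplitude = 3,
                            early_negativity_latency = 0.150,
                            early_negativity_width = 0.025,
                            ssvep_harmonic_amplitudes = c(1.2, 0.6, 0.3),
                            attention_gain = 1.5,
                            nontarget_erp_scale = 0,
                            noise_scale = 8,
                            noise_spectral_exponent = 1,
                            noise_smear = 0.4,
                            artifact_rate = 0,
                            artifact_amplitude = 100,
                            p300_topography = .p300_topography(),
                            early_negativity_topography = .parieto_occipital_topography(),
                            ssvep_topography = .ssvep_topography()) {
  stopifnot(p300_amplitude >= 0, early_negativity_amplitude >= 0,
            attention_gain >= 1, noise_scale >= 0,
            noise_smear >= 0, noise_smear < 1,
            p300_width > 0, early_negativity_width > 0,
            artifact_rate >= 0, artifact_amplitude >= 0)
  amps <- if (is.list(ssvep_harmonic_amplitudes))
    unlist(ssvep_harmonic_amplitudes) else ssvep_harmonic_amplitudes
  stopifnot(all(amps >= 0))
  for (topo in list(p300_topography, early_negativity_topography,
                    ssvep_topography)) {
    stopifnot(all(topo >= 0), all(topo <= 1), any(topo == 1))
  }
  structure(list(
    p300_amplitude = p300_amplitude,
    p300_latency = p300_latency,
    p300_width = p300_width,
    early_negativity_amplitude = early_negativity_amplitude,
    early_negativity_latency = early_negativity_latency,
    early_negativity_width = early_negativity_width,
    ssvep_harmonic_amplitudes = ssvep_harmonic_amplitudes,
    attention_gain = attention_gain,
    nontarget_erp_scale = nontarget_erp_scale,
    noise_scale = noise_scale,
    noise_spectral_exponent = noise_spectral_exponent,
    noise_smear = noise_smear,
    artifact_rate = artifact_rate,
    artifact_amplitude = artifact_amplitude,
    p300_topography = p300_topography,
    early_negativity_topography = early_negativity_topography,
    ssvep_topography = ssvep_topography
  ), class = "subject_profile")
}

# harmonic amplitude triplet for a given stimulation frequency
.harmonic_amplitudes <- function(profile, freq) {
  a <- profile$ssvep_harmonic_amplitudes
  if (is.list(a)) {
    key <- format(freq)
    if (!key %in% names(a))
      stop("no harmonic amplitudes given for frequency ", key)
    a <- a[[key]]
  }
  stopifnot(length(a) == 3)
  a
}

# one channel of 1/f^beta Gaussian noise, unit RMS, length n
.pink_noise <- function(n, beta) {
  nfft <- stats::nextn(n, c(2, 3))
  x <- stats::rnorm(nfft)
  X <- stats::fft(x)
  i0 <- 0:(nfft - 1)
  d <- pmin(i0, nfft - i0)                 # symmetric bin distance from DC
  d[1] <- 1
  H <- 1 / d ^ (beta / 2)
  H[1] <- 0                                # no DC component
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  y <- y[seq_len(n)]
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

.gauss_bump <- function(t, latency, width) exp(-((t - latency)^2) / (2 * width^2))

#' Simulate a multichannel EEG recording of one run
#'
#' Renders the event schedule into synthetic EEG: spatially smeared
#' 1/f^beta Gaussian background noise on all channels; for every flash of
#' the cued icon (when the oddball stimulation is present) an ERP template
#' -- an early negativity plus a P300 bump, both Gaussian-windowed
#' deflections scaled by their channel topographies -- time-locked to flash
#' onset; and, for every panel with an active flicker, a sum of sinusoids
#' at the stimulation frequency and its 2nd and 3rd harmonics, gated to the
#' interval from flicker onset to trial end, scaled by the occipital
#' topography, with the attended panel's amplitudes multiplied by the
#' attention gain.  The mastoid channels carry noise only.  Generation is
#' bit-reproducible given the seed.
#'
#' @param schedule An `event_log` from [make_schedule()].
#' @param profile A [subject_profile()].
#' @param config The [paradigm_config()] that produced `schedule`.
#' @param seed Integer seed.
#' @return An object of class `recording`: list with `data` (channels x
#'   samples matrix, microvolts), `channel_labels`, `sampling_rate` and
#'   `events` (the schedule).
#' @examples
#' cfg <- paradigm_config(flicker_freq = 12, n_trials_per_run = 6,
#'                        n_repetitions = 2)
#' rec <- simulate_recording(make_schedule(cfg, 1), subject_profile(), cfg, 1)
#' dim(rec$data)
#' @export
simulate_recording <- function(schedule, profile, config, seed) {
  stopifnot(inherits(schedule, "event_log"),
            inherits(profile, "subject_profile"),
            inherits(config, "paradigm_config"))
  fs <- config$sampling_rate
  if (!is.null(config$flicker_freq) &&
      any(3 * config$flicker_freq >= fs / 2))
    stop("third harmonic of a flicker frequency exceeds the Nyquist frequency")

  set.seed(as.integer(seed))
  labels  <- montage_32(TRUE)
  n_scalp <- 32
  n_ch    <- length(labels)
  n <- ceiling((max(schedule$trials$trial_end) + 0.5) * fs)
  tvec <- (seq_len(n) - 1) / fs

  # --- background noise: independent 1/f^beta streams, spatially smeared
  smear_mat <- {
    R <- matrix(stats::rnorm(n_scalp * n_scalp), n_scalp)
    A <- (1 - profile$noise_smear) * diag(n_scalp) +
      profile$noise_smear * R / sqrt(n_scalp)
    A / sqrt(rowSums(A^2))                 # unit-power rows
  }
  data <- matrix(0, n_ch, n, dimnames = list(labels, NULL))
  if (profile$noise_scale > 0) {
    src <- matrix(0, n_scalp, n)
    for (ch in seq_len(n_scalp))
      src[ch, ] <- .pink_noise(n, profile$noise_spectral_exponent)
    data[seq_len(n_scalp), ] <- profile$noise_scale * (smear_mat %*% src)
    for (ch in (n_scalp + 1):n_ch)         # mastoids: noise only, unmixed
      data[ch, ] <- profile$noise_scale *
        .pink_noise(n, profile$noise_spectral_exponent)
  }

  # --- flicker phases: one phase per trial per panel (drawn even when the
  #     flicker is absent, to keep the draw sequence stable across conditions)
  n_trials <- nrow(schedule$trials)
  phases <- matrix(stats::runif(n_trials * config$n_panels, 0, 2 * pi),
                   n_trials, config$n_panels)

  scalp_idx <- seq_len(n_scalp)
  p300_topo <- profile$p300_topography[labels[scalp_idx]]
  neg_topo  <- profile$early_negativity_topography[labels[scalp_idx]]
  ssvep_topo <- profile$ssvep_topography[labels[scalp_idx]]

  # --- ERP templates on target flashes (and scaled exogenous response)
  if (config$oddball_present &&
      (profile$p300_amplitude > 0 || profile$early_negativity_amplitude > 0)) {
    tpl_len <- ceiling(0.8 * fs)           # template support: 0..0.8 s
    tpl_t <- (seq_len(tpl_len) - 1) / fs
    tpl <- profile$p300_amplitude *
      .gauss_bump(tpl_t, profile$p300_latency, profile$p300_width)
    neg <- -profile$early_negativity_amplitude *
      .gauss_bump(tpl_t, profile$early_negativity_latency,
                  profile$early_negativity_width)
    fl <- schedule$flashes
    tr <- schedule$trials
    is_target <- fl$icon == tr$target_icon[fl$trial] &
      fl$panel == tr$target_panel[fl$trial]
    scale <- ifelse(is_target, 1, profile$nontarget_erp_scale)
    keep <- scale > 0
    for (i in which(keep)) {
      s0 <- round(fl$onset[i] * fs) + 1
      idx <- s0:(s0 + tpl_len - 1)
      idx_ok <- idx <= n
      data[scalp_idx, idx[idx_ok]] <- data[scalp_idx, idx[idx_ok]] +
        scale[i] * (outer(p300_topo, tpl[idx_ok]) + outer(neg_topo, neg[idx_ok]))
    }
  }

  # --- steady-state flicker responses, gated per trial
  if (!is.null(config$flicker_freq)) {
    for (tr_i in seq_len(n_trials)) {
      t_row <- schedule$trials[tr_i, ]
      s0 <- round(t_row$flicker_onset * fs) + 1
      s1 <- min(round(t_row$trial_end * fs), n)
      seg_t <- tvec[s0:s1]
      for (p in seq_len(config$n_panels)) {
        f <- config$flicker_freq[p]
        amps <- .harmonic_amplitudes(profile, f)
        gain <- if (p == t_row$target_panel) profile$attention_gain else 1
        wave <- numeric(length(seg_t))
        for (k in 1:3)
          wave <- wave + gain * amps[k] *
            sin(2 * pi * k * f * seg_t + phases[tr_i, p])
        data[scalp_idx, s0:s1] <- data[scalp_idx, s0:s1] +
          outer(ssvep_topo, wave)
      }
    }
  }

  # --- optional ocular artifacts: frontal square pulses at a mean rate
  if (profile$artifact_rate > 0 && profile$artifact_amplitude > 0) {
    frontal <- c(Fp1 = 1, Fp2 = 1, AF3 = 0.8, AF4 = 0.8,
                 F7 = 0.5, F8 = 0.5, F3 = 0.3, F4 = 0.3, Fz = 0.3)
    dur_s <- ceiling(0.2 * fs)
    n_art <- stats::rpois(1, profile$artifact_rate * n / fs)
    if (n_art > 0) {
      onsets <- sort(sample.int(n - dur_s, n_art))
      for (o in onsets) {
        idx <- o:(o + dur_s - 1)
        data[names(frontal), idx] <- data[names(frontal), idx] +
          profile$artifact_amplitude * frontal
      }
    }
  }

  structure(list(data = data, channel_labels = labels,
                 sampling_rate = fs, events = schedule),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  invisible(x)
}

#' Write / read a recording as a self-describing text container
#'
#' Plain-text serialization: a header with the sampling rate and channel
#' labels, followed by one tab-separated row per sample (microvolts).
#' Intended for small recordings and interchange; large runs are better
#' regenerated from their seeds.
#'
#' @param rec A `recording`.
#' @param path Output file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `recording` without an event log.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate_hz\t%.10g", rec$sampling_rate),
               paste(c("# channels", rec$channel_labels), collapse = "\t")),
             con)
  utils::write.table(t(rec$data), con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  hdr <- readLines(path, n = 2)
  fs <- as.numeric(strsplit(hdr[1], "\t")[[1]][2])
  labels <- strsplit(hdr[2], "\t")[[1]][-1]
  mat <- as.matrix(utils::read.table(path, skip = 2, sep = "\t"))
  structure(list(data = t(unname(mat)), channel_labels = labels,
                 sampling_rate = fs, events = NULL),
            class = "recording")
}
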