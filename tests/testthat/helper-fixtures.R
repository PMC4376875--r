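# Shared fixtures for the test suite.  All EEG is generated in code; the
# problem sizes here are deliberately smaller than a full study run (fewer
# trials and flashing-sequence repetitions, reduced decoder line-search
# grids) so the whole suite stays fast, while the generator's response
# profiles keep their defaults.

# a strongly responsive subject, emulating the study's best performers
strong_profile <- function() {
  subject_profile(p300_amplitude = 6,
                  ssvep_harmonic_amplitudes = c(2, 1, 0.5),
                  attention_gain = 2)
}

# a subject with no evoked responses at all (chance-level decoding)
silent_profile <- function() {
  subject_profile(p300_amplitude = 0, early_negativity_amplitude = 0,
                  ssvep_harmonic_amplitudes = c(0, 0, 0))
}

# reduced decoder settings used throughout the tests
test_cost_grid <- function() 10 ^ c(-4, -2, 0)
test_inner_folds <- function() 3

# wrap a bare data matrix as a recording
as_recording <- function(data, fs, labels = NULL, events = NULL) {
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  rownames(data) <- labels
  structure(list(data = data, channel_labels = labels,
                 sampling_rate = fs, events = events),
            class = "recording")
}

# build a small epoch_set directly from an epoch x channel x sample array
as_epoch_set <- function(epochs, labels, index, fs = 128,
                         window = c(0, (dim(epochs)[3] - 1) / fs)) {
  structure(list(epochs = epochs, window = window, labels = labels,
                 index = index, sampling_rate = fs,
                 channel_labels = paste0("ch", seq_len(dim(epochs)[2])),
                 run_id = NA), class = "epoch_set")
}

# simulate one subject's preprocessed P300 classification runs
make_p300_runs <- function(profile, n_runs = 3, seed = 1,
                           flicker = 12, n_trials = 6, n_reps = 5) {
  cfg <- paradigm_config(flicker_freq = flicker,
                         n_trials_per_run = n_trials,
                         n_repetitions = n_reps)
  lapply(seq_len(n_runs), function(r) {
    s <- seed + r
    rec <- simulate_recording(make_schedule(cfg, s), profile, cfg, s)
    rec <- bandpass_zero_phase(reference_to_mastoids(rec))
    resample(extract_epochs(rec, c(0, 0.6), run_id = r), 128)
  })
}

# simulate one subject's preprocessed two-panel SSVEP runs
make_ssvep_recs <- function(profile, n_runs = 1, seed = 1,
                            n_trials = 12, n_reps = 3) {
  cfg <- paradigm_config(n_panels = 2, flicker_freq = c(12, 15),
                         n_trials_per_run = n_trials,
                         n_repetitions = n_reps)
  lapply(seq_len(n_runs), function(r) {
    s <- seed + r
    rec <- simulate_recording(make_schedule(cfg, s), profile, cfg, s)
    resample(highpass_zero_phase(reference_to_mastoids(rec)), 256)
  })
}

# synthetic multichannel segment carrying an SSVEP at `freq` plus spatially
# correlated noise (a dominant common-mode stream mixed with channel noise,
# as in scalp EEG -- the structure the minimum-energy combination exploits),
# for MEC/SNR tests that do not need the full generator
make_ssvep_segment <- function(freq, fs = 256, dur = 2, n_ch = 8,
                               amps = c(1, 0.5, 0.25), noise_sd = 1,
                               phase = 0) {
  n <- round(dur * fs)
  t <- seq_len(n) / fs
  topo <- seq(1, 0.2, length.out = n_ch)
  wave <- numeric(n)
  for (k in seq_along(amps))
    wave <- wave + amps[k] * sin(2 * pi * k * freq * t + phase)
  # correlated noise with a graded spatial eigenspectrum (like scalp EEG):
  # independent source streams of decaying strength mixed through a random
  # orthogonal matrix, so the spatial filter retains several components
  Q <- qr.Q(qr(matrix(rnorm(n_ch * n_ch), n_ch)))
  g <- seq(2, 0.4, length.out = n_ch)
  noise <- noise_sd * (Q %*% (g * matrix(rnorm(n_ch * n), n_ch, n)))
  outer(topo, wave) + noise
}
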