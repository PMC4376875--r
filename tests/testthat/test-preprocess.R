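# Referencing, zero-phase filtering, decimation, epoching, rejection.

test_that("mastoid referencing equals the naive per-sample oracle", {
  set.seed(42)
  dat <- matrix(rnorm(7 * 50), 7, 50)
  rec <- as_recording(dat, 100, labels = c(paste0("ch", 1:5), "M1", "M2"))
  ref <- reference_to_mastoids(rec)
  # brute-force loop oracle
  expected <- dat[1:5, ]
  for (s in 1:50)
    expected[, s] <- dat[1:5, s] - mean(dat[6:7, s])
  expect_equal(unname(ref$data), unname(expected), tolerance = 1e-12)
  expect_equal(ref$channel_labels, paste0("ch", 1:5))

  # zero mastoids leave the scalp unchanged; common mode is removed
  dat0 <- dat; dat0[6:7, ] <- 0
  expect_equal(unname(reference_to_mastoids(
    as_recording(dat0, 100, c(paste0("ch", 1:5), "M1", "M2")))$data),
    unname(dat0[1:5, ]))
  common <- matrix(rep(rnorm(50), each = 7), 7, 50)
  expect_equal(max(abs(reference_to_mastoids(
    as_recording(common, 100, c(paste0("ch", 1:5), "M1", "M2")))$data)), 0)

  expect_error(reference_to_mastoids(as_recording(dat, 100)), "mastoid")
})

test_that("band-pass filtering is zero-phase, attenuates 40 Hz and removes DC", {
  fs <- 256
  n <- 8 * fs
  # symmetric pulse: output maximum must stay at the same sample
  pulse <- exp(-((seq_len(n) - n / 2)^2) / (2 * 20^2))
  rec <- as_recording(rbind(pulse), fs)
  out <- bandpass_zero_phase(rec, 0.5, 20, 3)
  expect_equal(which.max(out$data[1, ]), n %/% 2)

  # 40 Hz sinusoid through 0.5-20 Hz: squared Butterworth magnitude at
  # 40 Hz bounds the residual RMS below 5% of the input RMS
  s40 <- sin(2 * pi * 40 * seq_len(n) / fs)
  out40 <- bandpass_zero_phase(as_recording(rbind(s40), fs), 0.5, 20, 3)
  mid <- (fs + 1):(n - fs)
  expect_lt(sqrt(mean(out40$data[1, mid]^2)) / sqrt(mean(s40[mid]^2)), 0.05)

  # DC offset is rejected
  outdc <- bandpass_zero_phase(as_recording(rbind(rep(2, n)), fs), 0.5, 20, 3)
  expect_lt(abs(mean(outdc$data[1, mid])), 0.02)

  expect_error(bandpass_zero_phase(rec, 20, 0.5), "band edges")
})

test_that("high-pass filtering preserves a 12 Hz carrier and kills constants", {
  fs <- 256
  n <- 30 * fs                       # long window: 0.2 Hz transients decay
  s12 <- sin(2 * pi * 12 * seq_len(n) / fs)
  out <- highpass_zero_phase(as_recording(rbind(s12), fs), 0.2, 4)
  mid <- (10 * fs + 1):(n - 10 * fs)
  expect_equal(sqrt(mean(out$data[1, mid]^2)), sqrt(mean(s12[mid]^2)),
               tolerance = 0.01)
  outc <- highpass_zero_phase(as_recording(rbind(rep(3, n)), fs), 0.2, 4)
  expect_lt(max(abs(outc$data[1, mid])), 0.05)
  out0 <- highpass_zero_phase(as_recording(rbind(rep(0, n)), fs), 0.2, 4)
  expect_equal(max(abs(out0$data)), 0)
})

test_that("decimation keeps the endpoint convention and band-limited content", {
  fs <- 1024
  # 0.6 s epoch at 1024 Hz has 615 samples; at 128 Hz it has 77
  ep <- as_epoch_set(array(rnorm(2 * 3 * 615), c(2, 3, 615)),
                     labels = c(TRUE, FALSE),
                     index = data.frame(trial = 1, panel = 1, icon = 1:2,
                                        repetition = 1),
                     fs = fs, window = c(0, 0.6))
  down <- resample(ep, 128)
  expect_equal(dim(down$epochs)[3], 77)
  expect_identical(resample(ep, 1024)$epochs, ep$epochs)   # factor 1
  expect_error(resample(ep, 100), "integer divisor")

  # a 10 Hz sinusoid survives 1024 -> 256 decimation with its amplitude
  n <- 2 * fs
  s10 <- sin(2 * pi * 10 * seq_len(n) / fs)
  rec <- resample(as_recording(rbind(s10), fs), 256)
  expect_equal(max(abs(rec$data)), 1, tolerance = 0.01)
  expect_equal(narrowband_power(rec$data[1, ], 10, 256), 0.25, tolerance = 0.01)
})

test_that("epoch extraction counts, windows and labels are exact", {
  cfg <- paradigm_config(flicker_freq = NULL)         # full 12-trial run
  sched <- make_schedule(cfg, 31)
  prof <- subject_profile(p300_amplitude = 0, early_negativity_amplitude = 0,
                          ssvep_harmonic_amplitudes = c(0, 0, 0),
                          noise_scale = 0)
  rec <- simulate_recording(sched, prof, cfg, 31)
  ep <- extract_epochs(rec, c(0, 0.05))
  expect_equal(dim(ep$epochs)[1], 720)                # 12 trials x 60 flashes
  # exactly n_repetitions target epochs per trial
  expect_true(all(tapply(ep$labels, ep$index$trial, sum) == 10))

  # the (-0.2, 0.8) window at 1024 Hz counts both endpoint samples
  ep2 <- extract_epochs(rec, c(-0.2, 0.8))
  expect_equal(dim(ep2$epochs)[3], 1025)

  expect_error(extract_epochs(rec, c(-10, 0.1)), "beyond the recording")
})

test_that("noiseless epochs reproduce the injected ERP template exactly", {
  cfg <- paradigm_config(flicker_freq = NULL, n_trials_per_run = 6,
                         n_repetitions = 1)
  sched <- make_schedule(cfg, 13)
  prof <- subject_profile(noise_scale = 0)
  rec <- simulate_recording(sched, prof, cfg, 13)
  ep <- extract_epochs(rec, c(0, 0.6))
  fs <- rec$sampling_rate
  tt <- (0:(dim(ep$epochs)[3] - 1)) / fs
  template <- prof$p300_amplitude * prof$p300_topography["Pz"] *
    exp(-((tt - prof$p300_latency)^2) / (2 * prof$p300_width^2)) -
    prof$early_negativity_amplitude *
    prof$early_negativity_topography["Pz"] *
    exp(-((tt - prof$early_negativity_latency)^2) /
          (2 * prof$early_negativity_width^2))
  pz <- which(ep$channel_labels == "Pz")
  for (i in which(ep$labels))
    expect_equal(ep$epochs[i, pz, ], template, tolerance = 1e-9)
  # non-target flashes evoke nothing by default: epochs far enough from the
  # trial's target flash (whose template spans 0.8 s) are exactly zero
  fl <- sched$flashes
  tgt_onset <- sapply(split(fl, fl$trial), function(d)
    d$onset[d$icon == sched$trials$target_icon[sched$trials$trial == d$trial[1]]])
  far <- !ep$labels &
    (fl$onset >= tgt_onset[fl$trial] + 0.81 |
       fl$onset + 0.61 <= tgt_onset[fl$trial])
  expect_gt(sum(far), 0)
  expect_true(all(abs(ep$epochs[far, pz, ]) < 1e-12))
})

test_that("peak-to-peak rejection removes exactly the top fraction", {
  set.seed(8)
  n <- 10
  epochs <- array(rnorm(n * 2 * 30, sd = 0.1), c(n, 2, 30))
  amp <- seq(1, 10)                                    # known ranking
  for (i in seq_len(n)) epochs[i, 1, 5] <- amp[i]
  es <- as_epoch_set(epochs, labels = rep(c(TRUE, FALSE), 5),
                     index = data.frame(trial = rep(1:5, each = 2), panel = 1,
                                        icon = rep(1:2, 5), repetition = 1))
  kept <- reject_high_amplitude(es, 0.10)              # ceiling(1) = 1 removed
  expect_equal(dim(kept$epochs)[1], 9)
  # the removed epoch is the sort oracle's top-1
  p2p <- apply(es$epochs, 1, function(e) max(apply(e, 1, function(x) diff(range(x)))))
  expect_equal(kept$epochs, es$epochs[-which.max(p2p), , , drop = FALSE])
  expect_identical(reject_high_amplitude(es, 0)$epochs, es$epochs)

  # retained-set maximum is non-increasing in the fraction
  maxima <- sapply(c(0, 0.1, 0.3, 0.5, 0.8), function(f) {
    k <- reject_high_amplitude(es, f)
    max(apply(k$epochs, 1, function(e) max(apply(e, 1, function(x) diff(range(x))))))
  })
  expect_true(all(diff(maxima) <= 1e-12))

  # simulated ocular artifacts are what rejection removes first
  cfg <- paradigm_config(flicker_freq = NULL, n_trials_per_run = 6,
                         n_repetitions = 2)
  prof <- subject_profile(artifact_rate = 0.3, artifact_amplitude = 200)
  rec <- simulate_recording(make_schedule(cfg, 17), prof, cfg, 17)
  epa <- extract_epochs(rec, c(-0.2, 0.8))
  p2pa <- apply(epa$epochs, 1, function(e)
    max(apply(e, 1, function(x) diff(range(x)))))
  kept_a <- reject_high_amplitude(epa, 0.10)
  p2pk <- apply(kept_a$epochs, 1, function(e)
    max(apply(e, 1, function(x) diff(range(x)))))
  expect_lt(max(p2pk), max(p2pa))
  expect_gt(max(p2pa), 200)                            # artifacts present

  # ties: equal scores remove the earlier epoch first
  tied <- array(0, c(4, 1, 10))
  tied[, 1, 1] <- c(5, 5, 1, 1)
  est <- as_epoch_set(tied, labels = rep(FALSE, 4),
                      index = data.frame(trial = 1, panel = 1, icon = 1:4,
                                         repetition = 1))
  kept2 <- reject_high_amplitude(est, 0.25)            # remove 1 of 4
  expect_equal(kept2$index$icon, c(2, 3, 4))
})
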