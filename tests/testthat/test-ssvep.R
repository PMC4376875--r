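# Narrow-band power, spectra, MEC filtering, SNR scoring, detection,
# and the trained harmonic weighting.

test_that("narrow-band power matches its closed form and the DFT oracle", {
  fs <- 256
  n <- 2 * fs
  i <- seq_len(n)
  y <- sin(2 * pi * 12 * i / fs)                       # integer cycles
  expect_equal(narrowband_power(y, 12, fs), 0.25, tolerance = 1e-9)
  expect_equal(narrowband_power(rep(0, n), 12, fs), 0)
  # quadratic amplitude scaling
  expect_equal(narrowband_power(3 * y, 12, fs), 9 * narrowband_power(y, 12, fs),
               tolerance = 1e-12)

  # squared DFT-coefficient oracle at on-bin frequencies: |X_f|^2 / n^2
  set.seed(2)
  z <- rnorm(n)
  X <- fft(z)
  for (f in c(4, 12, 40)) {
    bin <- f * n / fs + 1
    # the DFT indexes samples 0..n-1 while the projection uses 1..n; on-bin
    # phases differ by one sample, leaving the magnitude unchanged
    expect_equal(narrowband_power(z, f, fs), Mod(X[bin])^2 / n^2,
                 tolerance = 1e-9)
  }

  expect_error(narrowband_power(numeric(0), 10, fs), "at least 2")
  expect_error(narrowband_power(y, 200, fs), "Nyquist")
})

test_that("amplitude spectra show the harmonic structure and noise flatness", {
  fs <- 128
  n <- 4 * fs
  t <- seq_len(n) / fs
  y <- 2 * sin(2 * pi * 10 * t) + 1 * sin(2 * pi * 20 * t) +
    0.5 * sin(2 * pi * 30 * t)
  sp <- amplitude_spectrum(y, fs)
  top3 <- sp$freq[order(sp$magnitude, decreasing = TRUE)[1:3]]
  expect_setequal(top3, c(10, 20, 30))
  expect_equal(sp$magnitude[sp$freq == 10], 2, tolerance = 1e-9)

  # white noise: trial-averaged spectrum flat within 20% across 1-40 Hz
  set.seed(9)
  trials <- matrix(rnorm(200 * n), 200, n)
  msp <- amplitude_spectrum(trials, fs)
  band <- msp$magnitude[msp$freq >= 1 & msp$freq <= 40]
  expect_lt((max(band) - min(band)) / mean(band), 0.4)   # +/- 20% around mean
})

test_that("the sinusoid basis has the right size and orthogonality", {
  fs <- 256
  n <- 2 * fs
  expect_equal(ncol(sinusoid_basis(12, 3, n, fs)), 6)
  B <- sinusoid_basis(c(12, 15), 3, n, fs)
  expect_equal(ncol(B), 12)
  G <- crossprod(B) / n
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)) / max(abs(G)), 1e-6)       # integer-cycle window
  expect_error(sinusoid_basis(50, 3, n, fs), "Nyquist")
})

test_that("MEC turns away from noisy channels and minimizes residual variance", {
  set.seed(14)
  fs <- 256
  n <- 2 * fs
  t <- seq_len(n) / fs
  # noise confined to channel 1, SSVEP (plus faint noise) on channel 2
  seg <- rbind(rnorm(n, sd = 2),
               sin(2 * pi * 12 * t) + rnorm(n, sd = 1e-3))
  filt <- fit_mec(seg, 12, fs)
  w1 <- filt$weights[, 1] / sqrt(sum(filt$weights[, 1]^2))
  expect_lt(abs(w1[1]), 0.05)                            # avoids channel 1
  expect_gt(abs(w1[2]), 0.99)

  # the first component achieves (at most) the variance of the best
  # single channel of the SSVEP-free residual
  seg8 <- make_ssvep_segment(12, fs = fs, dur = 2, n_ch = 8)
  f8 <- fit_mec(seg8, c(12, 15), fs)
  B <- sinusoid_basis(c(12, 15), 3, ncol(seg8), fs)
  resid <- qr.resid(qr(B), t(seg8))
  wn <- f8$weights[, 1] / sqrt(sum(f8$weights[, 1]^2))
  expect_lte(stats::var(drop(resid %*% wn)),
             min(apply(resid, 2, stats::var)) + 1e-9)

  # eigenvector weights are orthogonal before the 1/sqrt(eigenvalue) scaling
  wraw <- sweep(f8$weights, 2, sqrt(f8$eigenvalues[seq_len(f8$n_components)]),
                "*")
  G <- crossprod(wraw)
  expect_equal(unname(G), diag(ncol(wraw)), tolerance = 1e-8)

  # spatially white residual noise: near-equal eigenvalues, 1 component
  noise_seg <- matrix(rnorm(8 * n), 8, n)
  fn <- fit_mec(noise_seg, c(12, 15), fs)
  expect_equal(fn$n_components, 1L)
  expect_lt(diff(range(fn$eigenvalues)) / mean(fn$eigenvalues), 0.5)
})

test_that("SNR is large on-signal and near 1 on white noise", {
  set.seed(22)
  fs <- 256
  n <- 2 * fs
  t <- seq_len(n) / fs
  y <- 5 * sin(2 * pi * 12 * t) + rnorm(n)
  expect_gt(snr_at(y, 12, fs), 10)

  # white-noise SNR averages to 1 across draws and target frequencies
  snrs <- replicate(150, snr_at(rnorm(n), 13, fs, exclude = c(12, 15)))
  expect_equal(mean(snrs), 1, tolerance = 0.15)
})

test_that("frequency scoring separates target from foil and is amplitude-monotone", {
  set.seed(31)
  fs <- 256
  wins <- replicate(100, {
    seg <- make_ssvep_segment(12, fs = fs, dur = 2, noise_sd = 0.8)
    s12 <- score_frequency(seg, 12, c(12, 15), fs)
    s15 <- score_frequency(seg, 15, c(12, 15), fs)
    s12 > s15
  })
  expect_gte(mean(wins), 0.95)

  # doubling the amplitude does not decrease the target's score (noise-free)
  seg1 <- make_ssvep_segment(12, fs = fs, dur = 2, noise_sd = 0.5, phase = 1)
  seg2 <- make_ssvep_segment(12, fs = fs, dur = 2, amps = 2 * c(1, 0.5, 0.25),
                             noise_sd = 0.5, phase = 1)
  # same noise realisation is not guaranteed, so compare over the average
  set.seed(40)
  s_lo <- mean(replicate(10, score_frequency(
    make_ssvep_segment(12, fs = fs, dur = 2), 12, c(12, 15), fs)))
  set.seed(40)
  s_hi <- mean(replicate(10, score_frequency(
    make_ssvep_segment(12, fs = fs, dur = 2, amps = 2 * c(1, 0.5, 0.25)),
    12, c(12, 15), fs)))
  expect_gte(s_hi, s_lo)
})

test_that("detection picks the attended frequency and is at chance without signal", {
  set.seed(33)
  fs <- 256
  d <- detect_ssvep(make_ssvep_segment(15, fs = fs, dur = 2, noise_sd = 0.3),
                    c(12, 15), fs, attended = 15)
  expect_equal(d$winner, 15)
  expect_equal(d$correct, 1L)

  # no SSVEP content: winner is a coin flip over many draws
  hits <- replicate(120, {
    seg <- matrix(rnorm(8 * 2 * fs), 8, 2 * fs)
    detect_ssvep(seg, c(12, 15), fs, attended = 12)$correct
  })
  p <- mean(hits)
  expect_gt(p, 0.5 - 2.5 * sqrt(0.25 / 120))
  expect_lt(p, 0.5 + 2.5 * sqrt(0.25 / 120))

  expect_error(detect_ssvep(matrix(rnorm(16), 2), 12, 256), "2 candidate")
})

test_that("harmonic weighting learns which harmonic is informative", {
  set.seed(44)
  n_tr <- 30
  # only harmonic 2 separates attended from unattended candidates
  feat <- rbind(
    cbind(rnorm(n_tr, 1, 0.2), rnorm(n_tr, 5, 0.5), rnorm(n_tr, 1, 0.2)),
    cbind(rnorm(n_tr, 1, 0.2), rnorm(n_tr, 1, 0.2), rnorm(n_tr, 1, 0.2)))
  attended <- rep(c(TRUE, FALSE), each = n_tr)
  m <- train_harmonic_weighting(feat, attended, seed = 1,
                                cost_grid = test_cost_grid())
  expect_gt(abs(m$w[2]), abs(m$w[1]))
  expect_gt(abs(m$w[2]), abs(m$w[3]))
  # model output ranks attended rows above unattended ones
  out <- predict(m, feat)
  expect_gt(mean(out[attended]), mean(out[!attended]))

  # degenerate inputs are rejected
  expect_error(train_harmonic_weighting(feat, rep(TRUE, 2 * n_tr)),
               "attended and unattended")
  expect_error(train_harmonic_weighting(matrix(0, 10, 3),
                                        rep(c(TRUE, FALSE), 5)),
               "zero variance")

  # equal features for both candidates: the weighted winner falls back to
  # the lower frequency
  fe <- data.frame(run = 1, trial = 1, N_r = 1, candidate = c(12, 15),
                   snr1 = 1, snr2 = 1, snr3 = 1,
                   is_attended = c(TRUE, FALSE))
  res <- ssvep_detect_weighted(m, fe)
  expect_equal(res$winner, 12)
})
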