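#' Narrow-band signal power at a frequency of interest
#'
#' Estimates the power of a single-channel EEG segment at frequency `f` as
#' the squared projection onto the sine and cosine at `f`:
#' `P = (mean(y * cos(2*pi*i*f/fs)))^2 + (mean(y * sin(2*pi*i*f/fs)))^2`,
#' `i = 1..n`.  A unit-amplitude sinusoid at `f` over an integer number of
#' cycles gives `P = 0.25` (microvolts squared for microvolt input), and
#' `P` scales quadratically with amplitude.
#'
#' @param y Numeric sample vector (one channel), microvolts.
#' @param f Frequency of interest, Hz (`f < fs / 2`).
#' @param fs Sampling rate, Hz.
#' @return Power at `f`, microvolts squared (non-negative scalar).
#' @examples
#' fs <- 256; i <- 1:fs
#' narrowband_power(sin(2 * pi * 12 * i / fs), 12, fs)   # 0.25
#' @export
narrowband_power <- function(y, f, fs) {
  n <- length(y)
  if (n < 2) stop("signal must contain at least 2 samples")
  if (f >= fs / 2) stop("frequency of interest must be below Nyquist")
  i <- seq_len(n)
  ang <- 2 * pi * i * f / fs
  mean(y * cos(ang))^2 + mean(y * sin(ang))^2
}

#' Amplitude spectrum via the FFT
#'
#' Single-sided amplitude spectrum: an on-bin sinusoid of amplitude A
#' reads approximately A at its bin.  When `y` is a matrix (trials in
#' rows), magnitudes are averaged across trials.
#'
#' @param y Numeric vector, or matrix with one trial per row.
#' @param fs Sampling rate, Hz.
#' @return List with `freq` (Hz) and `magnitude` (same units as `y`),
#'   covering 0 up to the Nyquist frequency.
#' @export
amplitude_spectrum <- function(y, fs) {
  if (is.matrix(y)) {
    specs <- apply(y, 1, function(row) amplitude_spectrum(row, fs)$magnitude)
    f <- amplitude_spectrum(y[1, ], fs)$freq
    return(list(freq = f, magnitude = rowMeans(specs)))
  }
  n <- length(y)
  if (n < 2) stop("signal must contain at least 2 samples")
  mag <- Mod(stats::fft(y)) / n
  half <- seq_len(floor(n / 2) + 1)
  mag <- mag[half]
  mag[-1] <- 2 * mag[-1]                   # fold negative frequencies
  if (n %% 2 == 0) mag[length(mag)] <- mag[length(mag)] / 2
  list(freq = (half - 1) * fs / n, magnitude = mag)
}

#' Sine/cosine design matrix at candidate frequencies and harmonics
#'
#' Columns are `sin(2*pi*k*f*i/fs)` and `cos(2*pi*k*f*i/fs)` for every
#' candidate frequency `f` and harmonic `k = 1..harmonics`, sampled at
#' `i = 1..n_s` (two columns per frequency-harmonic).
#'
#' @param freqs Candidate stimulation frequencies, Hz.
#' @param harmonics Number of harmonics (3 in the standard path).
#' @param n_s Number of samples.
#' @param fs Sampling rate, Hz.
#' @return `n_s` x `2 * length(freqs) * harmonics` matrix.
#' @export
sinusoid_basis <- function(freqs, harmonics, n_s, fs) {
  if (any(harmonics * freqs >= fs / 2))
    stop("a requested harmonic exceeds the Nyquist frequency")
  i <- seq_len(n_s)
  cols <- list()
  for (f in freqs) for (k in seq_len(harmonics)) {
    ang <- 2 * pi * k * f * i / fs
    cols[[length(cols) + 1]] <- sin(ang)
    cols[[length(cols) + 1]] <- cos(ang)
  }
  do.call(cbind, cols)
}

#' Minimum Energy Combination spatial filter
#'
#' Finds channel combinations that minimize the energy of the EEG noise at
#' the candidate stimulation frequencies: (1) the SSVEP subspace (all
#' candidate frequencies and harmonics) is removed from the segment by
#' least-squares projection onto the sinusoid basis; (2) the channel
#' covariance of the residual is eigendecomposed; (3) the filter weights
#' are the eigenvectors of the smallest eigenvalues, each scaled by
#' `1/sqrt(eigenvalue)`; (4) the smallest set of components whose
#' cumulative eigenvalue share of the total residual energy stays within
#' `retain` is kept (at least one).
#'
#' @param segment Channels x samples matrix, microvolts.
#' @param freqs Candidate stimulation frequencies, Hz.
#' @param fs Sampling rate, Hz.
#' @param harmonics Number of harmonics projected out (3).
#' @param retain Retained share of residual noise energy (0.10).
#' @return An object of class `mec_filter`: `weights` (channels x
#'   components), `eigenvalues` (ascending, near-zero ones discarded),
#'   `n_components`, `retained_ratio`, `freqs`, `harmonics`.
#' @export
fit_mec <- function(segment, freqs, fs, harmonics = 3, retain = 0.10) {
  stopifnot(is.matrix(segment), nrow(segment) >= 2)
  n_s <- ncol(segment)
  if (n_s < fs / min(freqs))
    stop("segment shorter than one period of the lowest candidate frequency")
  B <- sinusoid_basis(freqs, harmonics, n_s, fs)
  resid <- qr.resid(qr(B), t(segment))     # n_s x channels
  covm <- crossprod(resid) / n_s
  eg <- eigen(covm, symmetric = TRUE)
  vals <- rev(eg$values)                   # ascending
  vecs <- eg$vectors[, rev(seq_along(eg$values)), drop = FALSE]
  keep <- vals > 1e-12 * max(vals)
  vals <- vals[keep]
  vecs <- vecs[, keep, drop = FALSE]
  total <- sum(vals)
  share <- cumsum(vals) / total
  n_comp <- max(1L, sum(share <= retain))
  w <- vecs[, seq_len(n_comp), drop = FALSE]
  w <- sweep(w, 2, sqrt(vals[seq_len(n_comp)]), "/")
  structure(list(weights = w, eigenvalues = vals,
                 n_components = n_comp,
                 retained_ratio = share[n_comp],
                 freqs = freqs, harmonics = harmonics),
            class = "mec_filter")
}

#' @export
print.mec_filter <- function(x, ...) {
  cat(sprintf(
    "MEC spatial filter: %d component(s) of %d channels (%.1f%% residual energy)\n",
    x$n_components, nrow(x$weights), 100 * x$retained_ratio))
  cat(sprintf("  frequencies projected out: %s Hz (harmonics 1..%d)\n",
              paste(signif(x$freqs, 4), collapse = ", "), x$harmonics))
  invisible(x)
}

#' Apply an MEC filter to a segment
#'
#' @param filter A `mec_filter`.
#' @param segment Channels x samples matrix.
#' @return Components x samples matrix of spatially filtered signals.
#' @export
apply_mec <- function(filter, segment) {
  stopifnot(inherits(filter, "mec_filter"),
            nrow(segment) == nrow(filter$weights))
  crossprod(filter$weights, segment)
}

#' Signal-to-noise ratio at a frequency
#'
#' Signal power is the narrow-band power ([narrowband_power()]) at `f`; noise
#' power is the mean narrow-band power over the 8 nearest off-target
#' frequencies on the segment's frequency grid (spacing `fs / n`),
#' excluding `f` itself and any frequency in `exclude` (other candidate
#' harmonics).
#'
#' @param y Single-component sample vector.
#' @param f Target frequency, Hz.
#' @param fs Sampling rate, Hz.
#' @param exclude Frequencies (Hz) whose bins must not enter the noise
#'   estimate.
#' @param n_noise_bins Number of off-target bins averaged (8).
#' @return Non-negative ratio; `Inf` (with a warning) if the noise
#'   estimate is exactly zero.
#' @export
snr_at <- function(y, f, fs, exclude = numeric(0), n_noise_bins = 8) {
  n <- length(y)
  df <- fs / n
  sig <- narrowband_power(y, f, fs)
  # walk outward in bin steps, skipping excluded neighbourhoods
  offs <- numeric(0)
  m <- 1
  while (length(offs) < n_noise_bins && m < n) {
    for (cand in c(f - m * df, f + m * df)) {
      if (cand <= 0 || cand >= fs / 2) next
      if (any(abs(cand - c(f, exclude)) < df / 2)) next
      offs <- c(offs, cand)
      if (length(offs) >= n_noise_bins) break
    }
    m <- m + 1
  }
  if (length(offs) == 0) stop("no usable noise bins around ", f, " Hz")
  noise <- mean(vapply(offs, function(fr) narrowband_power(y, fr, fs), numeric(1)))
  if (noise == 0) {
    warning("noise power estimate is zero at ", f, " Hz; SNR reported as Inf")
    return(Inf)
  }
  sig / noise
}

#' SNR features of a segment for each candidate frequency
#'
#' Fits the MEC filter once over all candidates, then computes, for every
#' candidate frequency and harmonic 1..3, the SNR averaged over the
#' filtered components.  This is the 3-dimensional feature vector per
#' candidate used both by the unweighted detector (which averages the
#' three values) and by the subject-trained harmonic weighting.
#'
#' @param segment Channels x samples matrix (preprocessed EEG).
#' @param candidates Candidate stimulation frequencies, Hz.
#' @param fs Sampling rate, Hz.
#' @param harmonics Number of harmonics (3).
#' @param retain MEC component retention threshold.
#' @return Matrix `length(candidates)` x `harmonics` of SNR values, with
#'   candidate frequencies as row names.
#' @export
ssvep_snr_features <- function(segment, candidates, fs, harmonics = 3,
                               retain = 0.10) {
  filt <- fit_mec(segment, candidates, fs, harmonics = harmonics,
                  retain = retain)
  comps <- apply_mec(filt, segment)
  all_harm <- as.vector(outer(seq_len(harmonics), candidates))
  snr <- matrix(NA_real_, length(candidates), harmonics,
                dimnames = list(format(candidates), NULL))
  for (ci in seq_along(candidates)) {
    for (k in seq_len(harmonics)) {
      fk <- k * candidates[ci]
      snr[ci, k] <- mean(vapply(seq_len(nrow(comps)), function(cp)
        snr_at(comps[cp, ], fk, fs, exclude = setdiff(all_harm, fk)),
        numeric(1)))
    }
  }
  snr
}

#' Score one candidate frequency
#'
#' Mean of the SNR over components and harmonics 1..3 of the candidate, on
#' the spatially filtered segment.
#'
#' @inheritParams ssvep_snr_features
#' @param f_candidate The candidate to score (must be in `candidates`).
#' @return Scalar score.
#' @export
score_frequency <- function(segment, f_candidate, candidates, fs,
                            harmonics = 3, retain = 0.10) {
  snr <- ssvep_snr_features(segment, candidates, fs, harmonics = harmonics,
                            retain = retain)
  i <- which(abs(candidates - f_candidate) < 1e-9)
  if (length(i) != 1) stop("f_candidate must be one of the candidates")
  mean(snr[i, ])
}

#' Detect the attended flicker frequency
#'
#' Scores every candidate frequency ([score_frequency()]) and identifies
#' the one with the highest score as the winner; exact ties are broken
#' toward the lower frequency and flagged.
#'
#' @inheritParams ssvep_snr_features
#' @param attended Optionally, the actually attended frequency, to report
#'   correctness.
#' @return List of class `ssvep_detection`: `winner`, `scores` (named),
#'   `tie`, and `correct` (0/1, or `NA` when `attended` is missing).
#' @export
detect_ssvep <- function(segment, candidates, fs, harmonics = 3,
                         retain = 0.10, attended = NULL) {
  if (length(candidates) < 2) stop("need at least 2 candidate frequencies")
  snr <- ssvep_snr_features(segment, candidates, fs, harmonics = harmonics,
                            retain = retain)
  scores <- rowMeans(snr)
  top <- which(scores == max(scores))
  tie <- length(top) > 1
  winner <- min(candidates[top])           # tie-break: lower frequency
  structure(list(winner = winner, scores = setNames(scores, format(candidates)),
                 snr = snr, tie = tie,
                 correct = if (is.null(attended)) NA_integer_
                           else as.integer(abs(winner - attended) < 1e-9)),
            class = "ssvep_detection")
}

#' @export
print.ssvep_detection <- function(x, ...) {
  cat(sprintf("SSVEP detection: winner %s Hz%s (scores: %s)\n",
              format(x$winner), if (x$tie) " [tie]" else "",
              paste(sprintf("%s=%.2f", names(x$scores), x$scores),
                    collapse = ", ")))
  invisible(x)
}

#' Train the subject-specific harmonic weighting
#'
#' Instead of averaging the SNRs of the three harmonics with equal weight,
#' fits a linear max-margin model on the 3-dimensional SNR feature space
#' -- one sample per (trial, candidate frequency), labelled by whether the
#' candidate was attended -- with the regularization constant chosen by
#' leave-one-out cross-validated line search.  At test time the candidate
#' whose feature vector yields the highest model output wins.
#'
#' @param features Matrix with one row per (trial, candidate) and 3 SNR
#'   columns (harmonics 1..3).
#' @param attended Logical (or 0/1) vector: was the row's candidate the
#'   attended frequency?
#' @param seed Integer seed.
#' @param cost_grid Regularization grid for the line search.
#' @return An object of class `harmonic_weighting` with `w` (3 weights),
#'   `b`, `cost` and the line-search table.
#' @export
train_harmonic_weighting <- function(features, attended, seed = 1,
                                     cost_grid = 10 ^ seq(-5, 2,
                                                          length.out = 15)) {
  features <- as.matrix(features)
  stopifnot(ncol(features) == 3, nrow(features) == length(attended))
  attended <- as.logical(attended)
  if (length(unique(attended)) < 2)
    stop("training data must contain attended and unattended samples")
  if (all(apply(features, 2, stats::var) == 0))
    stop("SNR features have zero variance; nothing to train on")
  y <- factor(ifelse(attended, "target", "nontarget"),
              levels = c("nontarget", "target"))
  fit <- .train_linear_svm(features, y, seed = seed, cost_grid = cost_grid,
                           inner_folds = nrow(features))   # leave-one-out
  structure(list(w = fit$w, b = fit$b, cost = fit$cost, cv = fit$cv,
                 n_train = fit$n_train),
            class = "harmonic_weighting")
}

#' @export
print.harmonic_weighting <- function(x, ...) {
  cat(sprintf(
    "Harmonic-weighting model: w = (%.3g, %.3g, %.3g), b = %.3g, C = %g\n",
    x$w[1], x$w[2], x$w[3], x$b, x$cost))
  invisible(x)
}

#' @export
coef.harmonic_weighting <- function(object, ...) c(object$w, bias = object$b)

#' Decision values of the harmonic-weighting model
#'
#' @param object A `harmonic_weighting` model.
#' @param newdata Matrix of 3-dimensional SNR features (one row per
#'   candidate).
#' @param ... Unused.
#' @return Numeric vector of model outputs; the candidate with the
#'   highest output is the winner.
#' @export
predict.harmonic_weighting <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$w) + object$b
}
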