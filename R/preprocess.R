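#' Re-reference scalp channels to the mastoid mean
#'
#' Subtracts, sample-wise, the mean of the two mastoid channels from every
#' scalp channel, and drops the mastoid channels from the output.
#'
#' @param raw A `recording` containing channels `M1` and `M2`.
#' @return A `recording` with 32 referenced scalp channels.
#' @export
reference_to_mastoids <- function(raw) {
  stopifnot(inherits(raw, "recording"))
  m <- match(c("M1", "M2"), raw$channel_labels)
  if (anyNA(m)) stop("recording is missing a mastoid channel (M1/M2)")
  ref <- colMeans(raw$data[m, , drop = FALSE])
  keep <- setdiff(seq_along(raw$channel_labels), m)
  out <- raw
  out$data <- sweep(raw$data[keep, , drop = FALSE], 2, ref, "-")
  out$channel_labels <- raw$channel_labels[keep]
  out
}

# forward-backward recursive filtering with reflective (odd-symmetric) edge
# padding of 3x the filter length, applied to one numeric vector
.filtfilt_refpad <- function(filt, x) {
  b <- filt$b
  a <- filt$a
  npad <- 3 * max(length(a), length(b))
  n <- length(x)
  if (npad >= n) npad <- n - 1
  front <- 2 * x[1] - x[(npad + 1):2]
  back  <- 2 * x[n] - x[(n - 1):(n - npad)]
  y <- c(front, x, back)
  y <- as.numeric(signal::filter(b, a, y))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(npad + 1):(npad + n)]
}

.apply_filter_rec <- function(rec, filt) {
  out <- rec
  for (ch in seq_len(nrow(rec$data)))
    out$data[ch, ] <- .filtfilt_refpad(filt, rec$data[ch, ])
  out
}

#' Zero-phase Butterworth filtering
#'
#' Designs a Butterworth filter and applies it forward and backward
#' (squaring the magnitude response and cancelling the phase), with
#' reflective edge padding of three filter lengths.  `bandpass_zero_phase`
#' with the defaults reproduces the ERP path (0.5--20 Hz, 3rd order);
#' `highpass_zero_phase` with the defaults reproduces the SSVEP path
#' (0.2 Hz, 4th order).
#'
#' @param rec A `recording`.
#' @param low,high Band edges in Hz, `0 < low < high < Nyquist`.
#' @param order Butterworth design order.
#' @return A filtered `recording` of the same shape and rate.
#' @export
bandpass_zero_phase <- function(rec, low = 0.5, high = 20, order = 3) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("band edges must satisfy 0 < low < high < Nyquist")
  filt <- signal::butter(order, c(low, high) / nyq, type = "pass")
  .apply_filter_rec(rec, filt)
}

#' @rdname bandpass_zero_phase
#' @param cutoff High-pass cutoff in Hz.
#' @export
highpass_zero_phase <- function(rec, cutoff = 0.2, order = 4) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$sampling_rate / 2
  if (!(cutoff > 0 && cutoff < nyq))
    stop("cutoff must lie strictly between 0 and the Nyquist frequency")
  filt <- signal::butter(order, cutoff / nyq, type = "high")
  .apply_filter_rec(rec, filt)
}

#' Integer-factor downsampling
#'
#' Decimates a recording or epoch set by keeping every `factor`-th sample,
#' where `factor = source rate / target_rate` must be a whole number
#' (1024 to 128 Hz is factor 8; 1024 to 256 Hz is factor 4).  The data are
#' expected to be band-limited already (the standard paths filter first);
#' event times are expressed in seconds and need no rescaling.
#'
#' @param x A `recording` or `epoch_set`.
#' @param target_rate Target sampling rate in Hz.
#' @return Object of the same class at the new rate.
#' @export
resample <- function(x, target_rate) UseMethod("resample")

.decim_factor <- function(fs, target) {
  factor <- fs / target
  if (abs(factor - round(factor)) > 1e-9 || factor < 1)
    stop(sprintf("target rate %g Hz is not an integer divisor of %g Hz",
                 target, fs))
  as.integer(round(factor))
}

#' @export
resample.recording <- function(x, target_rate) {
  k <- .decim_factor(x$sampling_rate, target_rate)
  if (k == 1L) return(x)
  x$data <- x$data[, seq(1, ncol(x$data), by = k), drop = FALSE]
  x$sampling_rate <- target_rate
  x
}

#' @export
resample.epoch_set <- function(x, target_rate) {
  k <- .decim_factor(x$sampling_rate, target_rate)
  if (k == 1L) return(x)
  idx <- seq(1, dim(x$epochs)[3], by = k)
  x$epochs <- x$epochs[, , idx, drop = FALSE]
  x$sampling_rate <- target_rate
  x
}

# sample count of an epoch window at rate fs (both endpoint samples counted)
.epoch_n_samples <- function(window, fs)
  floor((window[2] - window[1]) * fs + 1e-9) + 1L

#' Extract stimulus-locked epochs
#'
#' Cuts one epoch per flash (per panel) from a recording, time-locked to
#' flash onset.  The window `(t_start, t_end)` is inclusive of both
#' endpoint samples at the current rate, so `(-0.2, 0.8)` s at 1024 Hz
#' yields 1025 samples and `(0, 0.6)` s at 128 Hz yields 77.  Epochs are
#' labelled target when their icon and panel match the cued icon and panel
#' of their trial.
#'
#' @param rec A `recording` whose event log is attached.
#' @param window Numeric `(t_start, t_end)` in seconds relative to flash
#'   onset.
#' @param run_id Optional identifier carried through to the epoch set.
#' @return An object of class `epoch_set`: list with `epochs` (epoch x
#'   channel x sample array), `window`, `labels` (logical, target),
#'   `index` (data.frame trial/panel/icon/repetition), `sampling_rate`,
#'   `channel_labels`, `run_id`.
#' @export
extract_epochs <- function(rec, window, run_id = NA) {
  stopifnot(inherits(rec, "recording"), length(window) == 2,
            window[1] < window[2])
  if (is.null(rec$events)) stop("recording carries no event log")
  fs <- rec$sampling_rate
  fl <- rec$events$flashes
  tr <- rec$events$trials
  n_samp <- .epoch_n_samples(window, fs)
  off0 <- round(window[1] * fs)
  n_ch <- nrow(rec$data)
  n_total <- ncol(rec$data)

  onset_smp <- round(fl$onset * fs)
  starts <- onset_smp + off0 + 1
  if (any(starts < 1) || any(starts + n_samp - 1 > n_total))
    stop("epoch window extends beyond the recording for at least one flash")

  epochs <- array(NA_real_, c(nrow(fl), n_ch, n_samp))
  for (i in seq_len(nrow(fl)))
    epochs[i, , ] <- rec$data[, starts[i]:(starts[i] + n_samp - 1)]

  labels <- fl$icon == tr$target_icon[fl$trial] &
    fl$panel == tr$target_panel[fl$trial]
  structure(list(
    epochs = epochs,
    window = window,
    labels = labels,
    index = data.frame(trial = fl$trial, panel = fl$panel,
                       icon = fl$icon, repetition = fl$repetition),
    sampling_rate = fs,
    channel_labels = rec$channel_labels,
    run_id = run_id
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf(
    "Epoch set: %d epochs (%d target) x %d channels x %d samples @ %g Hz, window [%g, %g] s\n",
    d[1], sum(x$labels), d[2], d[3], x$sampling_rate,
    x$window[1], x$window[2]))
  invisible(x)
}

# row subset of an epoch set
.epoch_subset <- function(es, idx) {
  es$epochs <- es$epochs[idx, , , drop = FALSE]
  es$labels <- es$labels[idx]
  es$index <- es$index[idx, , drop = FALSE]
  rownames(es$index) <- NULL
  es
}

#' Peak-to-peak artifact rejection
#'
#' Scores every epoch by its maximum peak-to-peak amplitude across
#' channels and removes the `ceiling(fraction * n)` highest-scoring epochs
#' of the set (one experimental run), ties broken by removing the earlier
#' epoch first.  With the default fraction this drops the 10% of epochs
#' most likely to carry ocular artifacts.
#'
#' @param epochs An `epoch_set` (one run).
#' @param fraction Fraction of epochs to reject, in `[0, 1)`.
#' @return The reduced `epoch_set`.
#' @export
reject_high_amplitude <- function(epochs, fraction = 0.10) {
  stopifnot(inherits(epochs, "epoch_set"), fraction >= 0, fraction < 1)
  n <- dim(epochs$epochs)[1]
  m <- ceiling(fraction * n)
  if (m == 0) return(epochs)
  score <- apply(epochs$epochs, 1, function(e)
    max(apply(e, 1, function(ch) max(ch) - min(ch))))
  drop_idx <- order(score, decreasing = TRUE)[seq_len(m)]
  .epoch_subset(epochs, setdiff(seq_len(n), drop_idx))
}
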