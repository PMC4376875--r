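#' Average the target epochs of one condition
#'
#' Sample-wise mean over target-labelled epochs only, giving the average
#' event-related response of one experimental condition.
#'
#' @param epochs An `epoch_set` (typically filtered 0.5--20 Hz, window
#'   (-0.2, 0.8) s, artifact-rejected).
#' @param condition Condition label, e.g. `"oddball"` or `"hybrid-12"`.
#' @return An object of class `erp_average`: list with `waveform`
#'   (channel x sample matrix, microvolts), `n_epochs_used`, `condition`,
#'   `window`, `sampling_rate`, `channel_labels`.
#' @export
average_target_erp <- function(epochs, condition = "unknown") {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- which(epochs$labels)
  if (length(idx) == 0) stop("no target epochs to average")
  wf <- apply(epochs$epochs[idx, , , drop = FALSE], c(2, 3), mean)
  rownames(wf) <- epochs$channel_labels
  structure(list(waveform = wf, n_epochs_used = length(idx),
                 condition = condition, window = epochs$window,
                 sampling_rate = epochs$sampling_rate,
                 channel_labels = epochs$channel_labels),
            class = "erp_average")
}

#' @export
print.erp_average <- function(x, ...) {
  cat(sprintf("Average ERP (%s): %d channels, window [%g, %g] s, %d epochs\n",
              x$condition, nrow(x$waveform), x$window[1], x$window[2],
              x$n_epochs_used))
  invisible(x)
}

#' Per-channel correlations between condition-pair average ERPs
#'
#' For every pair of conditions, computes the Pearson correlation across
#' time samples between the two average waveforms, separately per channel.
#' Pairs are classed as `oddball-hybrid` when exactly one member is the
#' pure-oddball condition and `hybrid-hybrid` otherwise; with the study's
#' five conditions this gives 10 pairs, 4 oddball-hybrid and 6
#' hybrid-hybrid.
#'
#' @param erps A named list of `erp_average` objects (names are condition
#'   labels; the pure-oddball condition must be named `"oddball"`), all
#'   sharing window, rate and channel set.
#' @return A data.frame with columns `channel`, `cond_a`, `cond_b`,
#'   `pair`, `pair_class`, `r`.  A zero-variance waveform on a channel
#'   yields `NA` (correlation undefined) rather than 0.
#' @export
condition_pair_correlations <- function(erps) {
  stopifnot(is.list(erps), length(erps) >= 2, !is.null(names(erps)))
  for (e in erps) stopifnot(inherits(e, "erp_average"))
  ref <- erps[[1]]
  for (e in erps[-1]) {
    if (!identical(dim(e$waveform), dim(ref$waveform)) ||
        !isTRUE(all.equal(e$window, ref$window)) ||
        e$sampling_rate != ref$sampling_rate)
      stop("all ERP averages must share window, rate and channel set")
  }
  conds <- names(erps)
  pairs <- utils::combn(conds, 2)
  channels <- ref$channel_labels
  out <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    wa <- erps[[a]]$waveform
    wb <- erps[[b]]$waveform
    r <- vapply(seq_along(channels), function(ch) {
      xa <- wa[ch, ]; xb <- wb[ch, ]
      if (stats::sd(xa) == 0 || stats::sd(xb) == 0) return(NA_real_)
      stats::cor(xa, xb)
    }, numeric(1))
    n_odd <- sum(c(a, b) == "oddball")
    out[[j]] <- data.frame(
      channel = channels, cond_a = a, cond_b = b,
      pair = paste(a, b, sep = "/"),
      pair_class = if (n_odd == 1) "oddball-hybrid" else "hybrid-hybrid",
      r = r)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
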