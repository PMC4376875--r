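#' @export
plot.erp_average <- function(x, channels = c("Fz", "Cz", "Pz", "Oz"), ...) {
  channels <- intersect(channels, rownames(x$waveform))
  if (length(channels) == 0) stop("none of the requested channels present")
  tt <- seq(x$window[1], by = 1 / x$sampling_rate,
            length.out = ncol(x$waveform))
  old <- graphics::par(mfrow = c(length(channels), 1),
                       mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (ch in channels) {
    graphics::plot(tt, x$waveform[ch, ], type = "l",
                   xlab = "", ylab = paste0(ch, " (uV)"), ...)
    graphics::abline(v = 0, lty = 3)
  }
  invisible(x)
}

#' @export
plot.detection_table <- function(x, ...) {
  mods <- c("p300", "ssvep", "hybrid")
  curves <- lapply(mods, function(m) accuracy_itr_curves(x, m))
  nrs <- sort(unique(x$N_r))
  graphics::plot(range(nrs), c(0, 1), type = "n",
                 xlab = "number of repetitions",
                 ylab = "detection accuracy", ...)
  for (i in seq_along(mods))
    graphics::lines(curves[[i]]$N_r, curves[[i]]$p, type = "b",
                    pch = i, lty = i)
  graphics::legend("bottomright", legend = mods, pch = seq_along(mods),
                   lty = seq_along(mods), bty = "n")
  invisible(x)
}
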