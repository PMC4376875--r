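#' Stimulation paradigm configuration
#'
#' Describes one experimental run of the hybrid oddball/flicker paradigm: a
#' run is a series of trials, each starting with a 2 s cue and a 1 s pause,
#' after which a background rectangle starts to flicker and the oddball
#' stimulation begins 500 ms later.  The oddball stimulation consists of
#' `n_repetitions` flashing sequences in which each of the
#' `n_icons_per_panel` icons is flashed once, in random order, for a duration
#' drawn uniformly from `flash_duration_range`; flashes follow each other
#' back-to-back.  A 1 s pause ends the trial.
#'
#' Three designs are covered: a single panel with an optional flickering
#' background at one of 60/7 (~8.57), 10, 12 or 15 Hz (screen refresh of
#' 60 Hz divided by 7, 6, 5, 4), and a two-panel design whose panels flicker
#' at 12 and 15 Hz simultaneously, with independent flash orderings.
#'
#' @param n_panels Number of stimulation panels (1 or 2).
#' @param flicker_freq Flicker frequency in Hz per panel (`NULL` for a pure
#'   oddball run without flicker).  Length must equal `n_panels`;
#'   frequencies must be distinct across panels.
#' @param oddball_present Logical; `FALSE` gives a pure-flicker run in which
#'   flashes are still scheduled (the timeline is identical) but no
#'   event-related response is attached to them by the simulator.
#' @param n_icons_per_panel Icons per panel (6).
#' @param n_repetitions Flashing sequences per trial (10).
#' @param flash_duration_range Uniform range, in seconds, of single-flash
#'   durations (0.200--0.300 s).
#' @param cue_duration,pre_flicker_pause,flicker_lead,post_pause Timing
#'   constants in seconds: cue presentation, pause before flicker onset,
#'   lead of the flicker before the oddball stimulation starts, pause after
#'   the stimulation.
#' @param n_trials_per_run Trials per run (12); must allow every selectable
#'   icon to be cued a whole number of times.
#' @param sampling_rate Acquisition rate in Hz (1024).
#' @param sync_panels Logical; if `TRUE`, the two panels of a two-panel
#'   design share flash onsets and durations (by default each panel has its
#'   own independent onset/duration stream).
#' @return An object of class `paradigm_config`.
#' @examples
#' cfg <- paradigm_config(flicker_freq = 12)            # hybrid, one panel
#' cfg3 <- paradigm_config(n_panels = 2, flicker_freq = c(12, 15))
#' @export
paradigm_config <- function(n_panels = 1,
                            flicker_freq = NULL,
                            oddball_present = TRUE,
                            n_icons_per_panel = 6,
                            n_repetitions = 10,
                            flash_duration_range = c(0.200, 0.300),
                            cue_duration = 2.0,
                            pre_flicker_pause = 1.0,
                            flicker_lead = 0.5,
                            post_pause = 1.0,
                            n_trials_per_run = 12,
                            sampling_rate = 1024,
                            sync_panels = FALSE) {
  stopifnot(n_panels >= 1, n_icons_per_panel >= 2, n_repetitions >= 1,
            length(flash_duration_range) == 2,
            n_trials_per_run >= 1, sampling_rate > 0)
  if (!(flash_duration_range[1] > 0 &&
        flash_duration_range[1] < flash_duration_range[2]))
    stop("flash_duration_range must satisfy 0 < low < high")
  if (!is.null(flicker_freq)) {
    if (length(flicker_freq) != n_panels)
      stop("flicker_freq must have one frequency per panel")
    if (anyDuplicated(flicker_freq))
      stop("flicker frequencies must be distinct across panels")
    if (any(flicker_freq <= 0)) stop("flicker frequencies must be positive")
  }
  n_icons <- n_panels * n_icons_per_panel
  if (n_trials_per_run %% n_icons != 0)
    stop(sprintf(
      "n_trials_per_run (%d) must cue each of the %d selectable icons a whole number of times",
      n_trials_per_run, n_icons))
  structure(list(
    n_panels = n_panels,
    flicker_freq = flicker_freq,
    oddball_present = oddball_present,
    n_icons_per_panel = n_icons_per_panel,
    n_repetitions = n_repetitions,
    flash_duration_range = flash_duration_range,
    cue_duration = cue_duration,
    pre_flicker_pause = pre_flicker_pause,
    flicker_lead = flicker_lead,
    post_pause = post_pause,
    n_trials_per_run = n_trials_per_run,
    sampling_rate = sampling_rate,
    sync_panels = sync_panels
  ), class = "paradigm_config")
}

#' @export
print.paradigm_config <- function(x, ...) {
  cat("Stimulation paradigm configuration\n")
  cat(sprintf("  panels: %d x %d icons; flicker: %s; oddball: %s\n",
              x$n_panels, x$n_icons_per_panel,
              if (is.null(x$flicker_freq)) "none"
              else paste(signif(x$flicker_freq, 4), "Hz", collapse = ", "),
              if (x$oddball_present) "present" else "absent"))
  cat(sprintf("  %d trials/run, %d repetitions/trial, flashes U(%.0f, %.0f) ms\n",
              x$n_trials_per_run, x$n_repetitions,
              1000 * x$flash_duration_range[1], 1000 * x$flash_duration_range[2]))
  cat(sprintf("  sampling rate %g Hz\n", x$sampling_rate))
  invisible(x)
}

#' Generate the stimulation timeline of one experimental run
#'
#' Draws the randomized cue order, per-panel flash orders and flash
#' durations for a full run and lays out all events on a common clock
#' starting at 0 s.  Within every trial and panel each icon is flashed
#' exactly once per flashing sequence, flashes are back-to-back, and the
#' oddball stimulation starts `flicker_lead` seconds after flicker onset.
#' Each selectable icon is cued `n_trials_per_run / (n_panels *
#' n_icons_per_panel)` times, in randomized order.
#'
#' @param config A [paradigm_config()].
#' @param seed Integer seed fixing all randomness (cue order, flash orders,
#'   flash durations).
#' @return An object of class `event_log`: a list with
#'   \describe{
#'     \item{trials}{data.frame with one row per trial: `trial`,
#'       `target_icon`, `target_panel`, `cue_onset`, `flicker_onset`,
#'       `oddball_onset`, `stim_end`, `trial_end` (seconds).}
#'     \item{flashes}{data.frame with one row per flash: `onset`,
#'       `duration`, `icon`, `panel`, `repetition`, `trial`.}
#'   }
#' @examples
#' log <- make_schedule(paradigm_config(flicker_freq = 12), seed = 1)
#' table(log$trials$target_icon)   # each icon cued twice
#' @export
make_schedule <- function(config, seed) {
  stopifnot(inherits(config, "paradigm_config"))
  set.seed(as.integer(seed))
  np  <- config$n_panels
  ni  <- config$n_icons_per_panel
  nr  <- config$n_repetitions
  ntr <- config$n_trials_per_run

  # cue order: every (panel, icon) pair cued equally often, shuffled
  n_cues_each <- ntr %/% (np * ni)
  cues <- expand.grid(icon = seq_len(ni), panel = seq_len(np))
  cues <- cues[rep(seq_len(nrow(cues)), n_cues_each), , drop = FALSE]
  cues <- cues[sample.int(nrow(cues)), , drop = FALSE]

  trials  <- vector("list", ntr)
  flashes <- vector("list", ntr)
  t0 <- 0
  for (tr in seq_len(ntr)) {
    cue_onset     <- t0
    flicker_onset <- cue_onset + config$cue_duration + config$pre_flicker_pause
    oddball_onset <- flicker_onset + config$flicker_lead

    panel_flashes <- vector("list", np)
    for (p in seq_len(np)) {
      if (config$sync_panels && p > 1) {
        f <- panel_flashes[[1]]
        # shared onsets/durations, independent icon order
        for (r in seq_len(nr))
          f$icon[f$repetition == r] <- sample.int(ni)
        f$panel <- p
        panel_flashes[[p]] <- f
        next
      }
      icons <- unlist(lapply(seq_len(nr), function(r) sample.int(ni)))
      durs  <- stats::runif(ni * nr, config$flash_duration_range[1],
                            config$flash_duration_range[2])
      onsets <- oddball_onset + cumsum(c(0, durs[-length(durs)]))
      panel_flashes[[p]] <- data.frame(
        onset = onsets, duration = durs, icon = icons,
        panel = p, repetition = rep(seq_len(nr), each = ni), trial = tr)
    }
    fl <- do.call(rbind, panel_flashes)
    stim_end  <- max(fl$onset + fl$duration)
    trial_end <- stim_end + config$post_pause

    trials[[tr]] <- data.frame(
      trial = tr, target_icon = cues$icon[tr], target_panel = cues$panel[tr],
      cue_onset = cue_onset, flicker_onset = flicker_onset,
      oddball_onset = oddball_onset, stim_end = stim_end,
      trial_end = trial_end)
    flashes[[tr]] <- fl
    t0 <- trial_end
  }
  structure(list(trials = do.call(rbind, trials),
                 flashes = do.call(rbind, flashes),
                 config = config),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("Event log: %d trials, %d flashes, run duration %.1f s\n",
              nrow(x$trials), nrow(x$flashes), max(x$trials$trial_end)))
  invisible(x)
}

#' Write / read an event log as tab-separated text
#'
#' Serializes the flash table and the trial table to two TSV files sharing
#' a common path stem (`<stem>_flashes.tsv`, `<stem>_trials.tsv`).
#'
#' @param log An `event_log`.
#' @param stem Path stem (no extension).
#' @return `write_event_log` returns `stem` invisibly; `read_event_log`
#'   returns an `event_log` (without the originating config).
#' @export
write_event_log <- function(log, stem) {
  stopifnot(inherits(log, "event_log"))
  utils::write.table(log$flashes, paste0(stem, "_flashes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(log$trials, paste0(stem, "_trials.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(stem)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(stem) {
  structure(list(
    trials  = utils::read.delim(paste0(stem, "_trials.tsv")),
    flashes = utils::read.delim(paste0(stem, "_flashes.tsv")),
    config  = NULL), class = "event_log")
}
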