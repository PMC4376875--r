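#' Fuse P300 and SSVEP correctness into icon correctness
#'
#' The hybrid interface identifies an icon only when both the P300 decoder
#' (which of the 6 icons) and the SSVEP detector (which panel) are
#' simultaneously correct: a logical AND.
#'
#' @param p300_correct,ssvep_correct 0/1 (or logical) vectors referring to
#'   the same trials and repetition counts.
#' @return Integer 0/1 vector of icon correctness.
#' @export
fuse <- function(p300_correct, ssvep_correct) {
  if (length(p300_correct) != length(ssvep_correct))
    stop("correctness vectors must refer to the same trials")
  as.integer(as.logical(p300_correct) & as.logical(ssvep_correct))
}

#' Bits per symbol of a noisy N-ary selection
#'
#' `B = log2(N) + p*log2(p) + (1 - p)*log2((1 - p) / (N - 1))`, the
#' bitrate per symbol of a selection among `N` equiprobable symbols
#' identified with accuracy `p` (errors spread uniformly).  The limits
#' `p -> 0` and `p -> 1` are evaluated by continuity (`x*log2(x) -> 0`).
#' The formula is convex in `p` with its minimum of 0 exactly at chance
#' (`p = 1/N`) and rises again below chance -- a well-known artifact of
#' this bitrate definition; below-chance accuracies are reported as-is
#' with a warning.
#'
#' @param p Classification accuracy in `[0, 1]`.
#' @param N Number of selectable symbols (>= 2).
#' @return Bits per symbol.
#' @examples
#' bitrate(1, 12)        # log2(12) ~ 3.585
#' bitrate(1 / 6, 6)     # 0
#' @export
bitrate <- function(p, N) {
  stopifnot(length(p) == 1, length(N) == 1)
  if (N < 2) stop("N must be at least 2")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  xlog2 <- function(x) if (x <= 0) 0 else x * log2(x)
  B <- log2(N) + xlog2(p) +
    (if (p >= 1) 0 else (1 - p) * log2((1 - p) / (N - 1)))
  if (p < 1 / N - 1e-12) warning(sprintf(
    "accuracy %.3f is below chance 1/%d; bitrate %.3f bits/symbol reported as-is",
    p, N, B))
  B
}

#' Information transfer rate in bits per minute
#'
#' `I = B(p, N) * N_c / sum(t_i) * 60` where `N_c` symbols were
#' communicated in `t_i` seconds each.
#'
#' @inheritParams bitrate
#' @param times Seconds needed to communicate each symbol (length `N_c`).
#' @return Bits per minute.
#' @examples
#' itr(1, 12, rep(3, 10))   # ~71.7 bits/min
#' @export
itr <- function(p, N, times) {
  if (length(times) == 0) stop("times must contain at least one symbol")
  if (any(times <= 0)) stop("all communication times must be positive")
  bitrate(p, N) * length(times) / sum(times) * 60
}

#' Assemble the per-trial detection table
#'
#' Joins P300 and SSVEP correctness by (run, trial, N_r) and fuses them
#' into icon correctness.
#'
#' @param p300 Data.frame from [crossvalidate_runs()] (columns `run`,
#'   `trial`, `N_r`, `correct`).
#' @param ssvep Data.frame with columns `run`, `trial`, `N_r`, `correct`.
#' @return A data.frame of class `detection_table` with columns `run`,
#'   `trial`, `N_r`, `p300_correct`, `ssvep_correct`, `icon_correct` and
#'   `stim_time` (1.5 * N_r seconds).
#' @export
detection_table <- function(p300, ssvep) {
  a <- p300[, c("run", "trial", "N_r", "correct")]
  names(a)[4] <- "p300_correct"
  b <- ssvep[, c("run", "trial", "N_r", "correct")]
  names(b)[4] <- "ssvep_correct"
  tab <- merge(a, b, by = c("run", "trial", "N_r"))
  if (nrow(tab) != nrow(a) || nrow(tab) != nrow(b))
    stop("P300 and SSVEP tables do not cover the same (run, trial, N_r) cells")
  tab$icon_correct <- fuse(tab$p300_correct, tab$ssvep_correct)
  tab$stim_time <- 1.5 * tab$N_r
  tab <- tab[order(tab$run, tab$trial, tab$N_r), ]
  rownames(tab) <- NULL
  class(tab) <- c("detection_table", "data.frame")
  tab
}

#' Accuracy and ITR versus number of repetitions
#'
#' Per repetition count `N_r`, the accuracy `p` is the fraction of correct
#' detections for the requested modality and the ITR uses the modality's
#' symbol count (`N` = 6 for P300 among the panel's icons, 2 for the SSVEP
#' panel choice, 12 for the fused hybrid selection) and a stimulation time
#' of `1.5 * N_r` seconds per trial.
#'
#' @param table A [detection_table()] (the P300-only and SSVEP-only paths
#'   accept any data.frame with the matching correctness column).
#' @param modality One of `"p300"`, `"ssvep"`, `"hybrid"`.
#' @return Data.frame with columns `modality`, `N_r`, `n`, `p`, `B`
#'   (bits/symbol) and `itr` (bits/min).
#' @export
accuracy_itr_curves <- function(table, modality = c("hybrid", "p300", "ssvep")) {
  modality <- match.arg(modality)
  col <- switch(modality, p300 = "p300_correct", ssvep = "ssvep_correct",
                hybrid = "icon_correct")
  N <- switch(modality, p300 = 6, ssvep = 2, hybrid = 12)
  if (!col %in% names(table)) stop("table lacks column ", col)
  nrs <- sort(unique(table$N_r))
  rows <- lapply(nrs, function(nr) {
    sub <- table[table$N_r == nr, ]
    p <- mean(sub[[col]])
    B <- suppressWarnings(bitrate(p, N))
    data.frame(modality = modality, N_r = nr, n = nrow(sub), p = p, B = B,
               itr = B * 60 / (1.5 * nr))
  })
  do.call(rbind, rows)
}

# 1.5*N_r-second analysis segment of one trial, anchored at oddball onset
.trial_segment <- function(rec, trial, N_r) {
  tr <- rec$events$trials
  fs <- rec$sampling_rate
  s0 <- round(tr$oddball_onset[tr$trial == trial] * fs) + 1
  n <- round(1.5 * N_r * fs)
  if (s0 + n - 1 > ncol(rec$data))
    stop("segment for trial ", trial, " extends beyond the recording")
  rec$data[, s0:(s0 + n - 1), drop = FALSE]
}

#' Per-trial SSVEP detection across runs
#'
#' For every trial of every (preprocessed) run and every repetition count,
#' extracts the `1.5 * N_r` second segment starting at oddball onset,
#' computes the MEC/SNR features and detects the winner frequency.
#'
#' @param recs List of preprocessed `recording`s with event logs attached
#'   (referenced, high-pass filtered, decimated).
#' @param candidates Candidate frequencies, Hz (panel order: candidate
#'   `i` is panel `i`'s flicker).
#' @param N_r_values Repetition counts to evaluate.
#' @param harmonics,retain Passed to the MEC/SNR machinery.
#' @param keep_features Also return the per-(trial, candidate) harmonic
#'   SNR features (for training the harmonic weighting).
#' @return Data.frame `run`, `trial`, `N_r`, `winner`, `attended`,
#'   `correct`, `tie`; with `keep_features = TRUE`, a list with elements
#'   `detections` and `features` (adds columns `candidate`,
#'   `snr1..snr3`, `is_attended`).
#' @export
ssvep_detect_runs <- function(recs, candidates, N_r_values = 1:10,
                              harmonics = 3, retain = 0.10,
                              keep_features = FALSE) {
  det <- list(); feats <- list()
  for (ri in seq_along(recs)) {
    rec <- recs[[ri]]
    tr <- rec$events$trials
    for (t_i in tr$trial) {
      attended <- candidates[tr$target_panel[tr$trial == t_i]]
      for (nr in N_r_values) {
        seg <- .trial_segment(rec, t_i, nr)
        snr <- ssvep_snr_features(seg, candidates, rec$sampling_rate,
                                  harmonics = harmonics, retain = retain)
        scores <- rowMeans(snr)
        top <- which(scores == max(scores))
        winner <- min(candidates[top])
        det[[length(det) + 1]] <- data.frame(
          run = ri, trial = t_i, N_r = nr, winner = winner,
          attended = attended,
          correct = as.integer(abs(winner - attended) < 1e-9),
          tie = length(top) > 1)
        if (keep_features)
          feats[[length(feats) + 1]] <- data.frame(
            run = ri, trial = t_i, N_r = nr, candidate = candidates,
            snr1 = snr[, 1], snr2 = snr[, 2], snr3 = snr[, 3],
            is_attended = abs(candidates - attended) < 1e-9)
      }
    }
  }
  det <- do.call(rbind, det)
  rownames(det) <- NULL
  if (!keep_features) return(det)
  feats <- do.call(rbind, feats)
  rownames(feats) <- NULL
  list(detections = det, features = feats)
}

#' Winner frequencies under a trained harmonic weighting
#'
#' Applies a [train_harmonic_weighting()] model to a feature table from
#' [ssvep_detect_runs()] `(keep_features = TRUE)`: per (run, trial, N_r),
#' the candidate with the highest model output wins.
#'
#' @param model A `harmonic_weighting` model.
#' @param features Feature data.frame (columns `run`, `trial`, `N_r`,
#'   `candidate`, `snr1..3`, `is_attended`).
#' @return Data.frame `run`, `trial`, `N_r`, `winner`, `correct`.
#' @export
ssvep_detect_weighted <- function(model, features) {
  out <- features
  out$score <- predict(model, as.matrix(features[, c("snr1", "snr2", "snr3")]))
  keys <- unique(out[, c("run", "trial", "N_r")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- out[out$run == keys$run[i] & out$trial == keys$trial[i] &
                 out$N_r == keys$N_r[i], ]
    top <- which(sub$score == max(sub$score))
    winner <- min(sub$candidate[top])
    attended <- sub$candidate[sub$is_attended][1]
    data.frame(run = keys$run[i], trial = keys$trial[i], N_r = keys$N_r[i],
               winner = winner,
               correct = as.integer(abs(winner - attended) < 1e-9))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# default five experimental conditions of the ERP comparison design
.exp1_conditions <- function() {
  list("oddball" = NULL, "hybrid-8.57" = 60 / 7, "hybrid-10" = 10,
       "hybrid-12" = 12, "hybrid-15" = 15)
}

#' Run a full experiment design end-to-end on synthetic data
#'
#' Drives the three study designs on one simulated subject, from event
#' scheduling and EEG synthesis through preprocessing, decoding and
#' evaluation.  All randomness is derived from `seed`; identical seeds
#' give byte-identical result tables.
#'
#' Design 1 (ERP comparison): per condition (pure oddball plus hybrid at
#' 60/7, 10, 12, 15 Hz), simulates `n_runs` runs, computes the
#' artifact-rejected target-ERP average (0.5--20 Hz, window (-0.2, 0.8) s)
#' and the 3-fold run-level P300 detection accuracy (0--600 ms epochs at
#' 128 Hz), and the condition-pair ERP correlations.
#'
#' Design 2 (flicker response): one run per (frequency, stimulation type)
#' cell -- 4 frequencies by pure-flicker/hybrid -- and per-trial power at
#' the first three harmonics of the stimulation frequency at Oz over the
#' full stimulation segment.
#'
#' Design 3 (hybrid decoding): `n_runs` two-panel runs (12 and 15 Hz);
#' P300 decoding trained on the first 2 runs and tested on the rest,
#' SSVEP detection per trial and repetition count, fused icon correctness
#' and accuracy/ITR curves for the three modalities.
#'
#' @param design 1, 2 or 3.
#' @param profile A [subject_profile()].
#' @param seed Integer master seed.
#' @param n_runs Runs per condition (design 1, default 3) or in total
#'   (design 3, default 8; design 2 is fixed at one run per cell).
#' @param n_trials_per_run,n_repetitions Paradigm scale (defaults 12, 10).
#' @param N_r_values Repetition counts evaluated (default
#'   `1:n_repetitions`).
#' @param conditions Design-1 condition list (named flicker frequencies,
#'   `NULL` entry = pure oddball).
#' @param cost_grid,inner_folds Decoder line-search parameters.
#' @param reject_fraction Artifact-rejection fraction of the ERP path.
#' @param retain MEC component retention threshold.
#' @return A list of result tables; see Details.
#' @export
run_experiment <- function(design, profile = subject_profile(), seed = 1,
                           n_runs = NULL,
                           n_trials_per_run = 12, n_repetitions = 10,
                           N_r_values = NULL,
                           conditions = .exp1_conditions(),
                           cost_grid = 10 ^ seq(-5, 2, length.out = 15),
                           inner_folds = 10,
                           reject_fraction = 0.10, retain = 0.10) {
  stopifnot(design %in% 1:3)
  if (is.null(N_r_values)) N_r_values <- seq_len(n_repetitions)
  seed <- as.integer(seed)

  if (design == 1) {
    if (is.null(n_runs)) n_runs <- 3
    erps <- list(); acc <- list()
    for (ci in seq_along(conditions)) {
      cname <- names(conditions)[ci]
      cfg <- paradigm_config(
        flicker_freq = conditions[[ci]],
        n_trials_per_run = n_trials_per_run, n_repetitions = n_repetitions)
      cls_runs <- vector("list", n_runs)
      wf_sum <- NULL; wf_n <- 0
      for (r in seq_len(n_runs)) {
        run_seed <- seed + 7919L * ((ci - 1L) * n_runs + r)
        sched <- make_schedule(cfg, run_seed)
        rec <- simulate_recording(sched, profile, cfg, run_seed)
        rec <- bandpass_zero_phase(reference_to_mastoids(rec), 0.5, 20, 3)
        erp_ep <- reject_high_amplitude(
          extract_epochs(rec, c(-0.2, 0.8), run_id = r), reject_fraction)
        tgt <- which(erp_ep$labels)
        wf <- apply(erp_ep$epochs[tgt, , , drop = FALSE], c(2, 3), sum)
        wf_sum <- if (is.null(wf_sum)) wf else wf_sum + wf
        wf_n <- wf_n + length(tgt)
        cls_runs[[r]] <- resample(
          extract_epochs(rec, c(0, 0.6), run_id = r), 128)
      }
      wf <- wf_sum / wf_n
      rownames(wf) <- cls_runs[[1]]$channel_labels
      erps[[cname]] <- structure(list(
        waveform = wf, n_epochs_used = wf_n, condition = cname,
        window = c(-0.2, 0.8), sampling_rate = cfg$sampling_rate,
        channel_labels = rownames(wf)), class = "erp_average")
      a <- crossvalidate_runs(cls_runs, "3-fold-by-run", seed = seed,
                              N_r_values = N_r_values,
                              cost_grid = cost_grid,
                              inner_folds = inner_folds)
      a$condition <- cname
      acc[[cname]] <- a
    }
    acc <- do.call(rbind, acc)
    rownames(acc) <- NULL
    return(list(design = 1, erps = erps,
                correlations = condition_pair_correlations(erps),
                p300 = acc))
  }

  if (design == 2) {
    freqs <- c(60 / 7, 10, 12, 15)
    cells <- expand.grid(frequency = freqs, type = c("pure", "hybrid"),
                         stringsAsFactors = FALSE)
    powers <- list()
    for (ri in seq_len(nrow(cells))) {
      f <- cells$frequency[ri]
      cfg <- paradigm_config(
        flicker_freq = f, oddball_present = cells$type[ri] == "hybrid",
        n_trials_per_run = n_trials_per_run, n_repetitions = n_repetitions)
      run_seed <- seed + 7919L * ri
      sched <- make_schedule(cfg, run_seed)
      rec <- reference_to_mastoids(
        simulate_recording(sched, profile, cfg, run_seed))
      oz <- which(rec$channel_labels == "Oz")
      for (t_i in sched$trials$trial) {
        seg <- .trial_segment(rec, t_i, n_repetitions)[oz, ]
        for (k in 1:3)
          powers[[length(powers) + 1]] <- data.frame(
            frequency = f, type = cells$type[ri], run = ri, trial = t_i,
            harmonic = k, P = narrowband_power(seg, k * f, rec$sampling_rate))
      }
    }
    powers <- do.call(rbind, powers)
    rownames(powers) <- NULL
    return(list(design = 2, powers = powers))
  }

  # design 3
  if (is.null(n_runs)) n_runs <- 8
  if (n_runs < 3) stop("design 3 needs at least 3 runs (2 train + tests)")
  candidates <- c(12, 15)
  cfg <- paradigm_config(
    n_panels = 2, flicker_freq = candidates,
    n_trials_per_run = n_trials_per_run, n_repetitions = n_repetitions)
  p300_runs <- vector("list", n_runs)
  ssvep_recs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- seed + 7919L * r
    sched <- make_schedule(cfg, run_seed)
    rec <- simulate_recording(sched, profile, cfg, run_seed)
    rec_ref <- reference_to_mastoids(rec)
    p300_runs[[r]] <- resample(
      extract_epochs(bandpass_zero_phase(rec_ref, 0.5, 20, 3),
                     c(0, 0.6), run_id = r), 128)
    ssvep_recs[[r]] <- resample(highpass_zero_phase(rec_ref, 0.2, 4), 256)
  }
  train_idx <- 1:2
  test_idx <- setdiff(seq_len(n_runs), train_idx)
  p300 <- if (n_runs == 8) {
    crossvalidate_runs(p300_runs, "train-2-test-6", seed = seed,
                       N_r_values = N_r_values, cost_grid = cost_grid,
                       inner_folds = inner_folds)
  } else {
    model <- train_decoder(.epoch_bind(p300_runs[train_idx]), seed = seed,
                           cost_grid = cost_grid, inner_folds = inner_folds)
    do.call(rbind, lapply(test_idx, function(te)
      .score_run(model, p300_runs[[te]], N_r_values, run_label = te)))
  }
  p300$run <- match(p300$run, test_idx)    # renumber test runs 1..n_test
  ssvep <- ssvep_detect_runs(ssvep_recs[test_idx], candidates,
                             N_r_values = N_r_values, retain = retain,
                             keep_features = TRUE)
  ssvep_train <- ssvep_detect_runs(ssvep_recs[train_idx], candidates,
                                   N_r_values = N_r_values, retain = retain,
                                   keep_features = TRUE)
  tab <- detection_table(p300, ssvep$detections)
  curves <- rbind(accuracy_itr_curves(tab, "p300"),
                  accuracy_itr_curves(tab, "ssvep"),
                  accuracy_itr_curves(tab, "hybrid"))
  list(design = 3, table = tab, curves = curves,
       p300 = p300, ssvep = ssvep$detections,
       features_test = ssvep$features, features_train = ssvep_train$features)
}
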