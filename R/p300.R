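#' Flatten epochs into classifier feature vectors
#'
#' Concatenates each channel's sample sequence in fixed channel order, so
#' an epoch of `n_ch` channels by `n_samp` samples becomes a vector of
#' length `n_ch * n_samp` (2464 for 32 channels at 77 samples, the
#' 0--600 ms window at 128 Hz).
#'
#' @param epochs An `epoch_set`.
#' @return Matrix of `n_epochs` rows by `n_ch * n_samp` feature columns.
#' @export
featurize <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$epochs)
  X <- matrix(NA_real_, d[1], d[2] * d[3])
  for (i in seq_len(d[1]))
    X[i, ] <- as.vector(t(epochs$epochs[i, , ]))   # channel-major blocks
  X
}

# fold assignment stratified by label, seeded
.stratified_folds <- function(y, k, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (lev in unique(y)) {
    idx <- which(y == lev)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# train a linear max-margin classifier on a feature matrix, with the
# regularization constant chosen by an inner cross-validated line search
# over a logarithmic grid; uses a precomputed linear Gram matrix so the
# grid search does not recompute feature dot products.  The Gram is
# normalized to unit mean diagonal (a global feature rescale that the
# logarithmic C grid absorbs) to keep the SMO solver well conditioned on
# microvolt-scale inputs.
.train_linear_svm <- function(X, y, seed = 1,
                              cost_grid = 10 ^ seq(-5, 2, length.out = 15),
                              inner_folds = 10, tol = 0.01) {
  y <- factor(y)
  if (nlevels(y) != 2) stop("training set must contain both classes")
  n <- nrow(X)
  K <- tcrossprod(X)
  kscale <- mean(diag(K))
  if (kscale <= 0) kscale <- 1
  K <- K / kscale
  fold <- if (inner_folds >= n) seq_len(n)       # leave-one-out
          else .stratified_folds(y, inner_folds, seed)
  n_folds <- max(fold)
  cv_acc <- vapply(cost_grid, function(cost) {
    acc <- vapply(seq_len(n_folds), function(f) {
      tr <- which(fold != f); te <- which(fold == f)
      if (length(te) == 0 || length(unique(y[tr])) < 2) return(NA_real_)
      m <- kernlab::ksvm(kernlab::as.kernelMatrix(K[tr, tr, drop = FALSE]),
                         y[tr], C = cost, type = "C-svc", tol = tol)
      sv <- tr[kernlab::SVindex(m)]
      p <- kernlab::predict(m,
        kernlab::as.kernelMatrix(K[te, sv, drop = FALSE]))
      mean(p == y[te])
    }, numeric(1))
    mean(acc, na.rm = TRUE)
  }, numeric(1))
  best <- which(cv_acc == max(cv_acc))[1]   # tie-break: smallest cost
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y,
                     C = cost_grid[best], type = "C-svc", tol = tol)
  sv <- kernlab::SVindex(m)
  alpha <- kernlab::coef(m)[[1]]
  w <- drop(crossprod(X[sv, , drop = FALSE], alpha)) / kscale
  b <- -kernlab::b(m)
  # orient so larger decision values mean "target"
  scores <- drop(X %*% w) + b
  if (mean(scores[y == "target"]) < mean(scores[y != "target"])) {
    w <- -w; b <- -b
  }
  list(w = w, b = b, cost = cost_grid[best],
       cv = data.frame(cost = cost_grid, accuracy = cv_acc),
       inner_folds = inner_folds, seed = seed, n_train = n)
}

#' Train the linear P300 decoder
#'
#' Fits a linear support-vector machine discriminating target from
#' non-target epochs.  The regularization constant is chosen by an inner
#' stratified cross-validated line search over a logarithmic grid
#' (maximizing inner-CV accuracy; ties go to the smaller constant), after
#' which the model is refit on the full training set.  The decision
#' function is affine in the flattened epoch, `f(x) = w.x + b`, oriented
#' so larger values indicate a target response.  Deterministic given
#' `seed`.
#'
#' @param train_epochs An `epoch_set` with both target and non-target
#'   epochs, window (0, 0.6) s at 128 Hz in the standard path.
#' @param seed Integer seed for the inner fold assignment.
#' @param cost_grid Regularization grid for the line search.
#' @param inner_folds Number of inner cross-validation folds (10 in the
#'   standard path).
#' @return An object of class `p300_decoder` with elements `w` (weight
#'   vector of length channels x samples), `b`, `cost`, `cv` (the line
#'   search table) and training metadata.
#' @export
train_decoder <- function(train_epochs, seed = 1,
                          cost_grid = 10 ^ seq(-5, 2, length.out = 15),
                          inner_folds = 10) {
  stopifnot(inherits(train_epochs, "epoch_set"))
  X <- featurize(train_epochs)
  y <- factor(ifelse(train_epochs$labels, "target", "nontarget"),
              levels = c("nontarget", "target"))
  fit <- .train_linear_svm(X, y, seed = seed, cost_grid = cost_grid,
                           inner_folds = inner_folds)
  fit$n_channels <- dim(train_epochs$epochs)[2]
  fit$n_samples <- dim(train_epochs$epochs)[3]
  fit$sampling_rate <- train_epochs$sampling_rate
  fit$window <- train_epochs$window
  class(fit) <- "p300_decoder"
  fit
}

#' @export
print.p300_decoder <- function(x, ...) {
  cat(sprintf(
    "Linear P300 decoder: %d features (%d ch x %d samples @ %g Hz)\n",
    length(x$w), x$n_channels, x$n_samples, x$sampling_rate))
  cat(sprintf("  C = %g (inner %d-fold CV accuracy %.3f), %d training epochs\n",
              x$cost, x$inner_folds,
              x$cv$accuracy[which(x$cv$cost == x$cost)[1]], x$n_train))
  invisible(x)
}

#' @export
coef.p300_decoder <- function(object, ...) c(object$w, bias = object$b)

#' Decision values of the P300 decoder
#'
#' @param object A `p300_decoder`.
#' @param newdata An `epoch_set` or a feature matrix from [featurize()].
#' @param ... Unused.
#' @return Numeric vector of decision values (larger = more target-like).
#' @export
predict.p300_decoder <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "epoch_set")) featurize(newdata) else newdata
  if (ncol(X) != length(object$w))
    stop("feature length does not match the decoder's training window/rate")
  drop(X %*% object$w) + object$b
}

# cued (icon, panel) of one trial, read off the target labels
.cued_of_trial <- function(epochs, trial) {
  i <- which(epochs$labels & epochs$index$trial == trial)[1]
  if (is.na(i)) stop("trial ", trial, " has no target-labelled epoch")
  list(icon = epochs$index$icon[i], panel = epochs$index$panel[i])
}

#' Score one trial and detect its target icon
#'
#' For each icon of the scored panel, averages that icon's epochs over the
#' first `N_r` repetitions, applies the decoder's decision function, and
#' detects the icon with the highest score (ties broken deterministically
#' toward the lowest icon id and flagged).
#'
#' @param model A `p300_decoder`.
#' @param epochs An `epoch_set` containing the trial's epochs.
#' @param trial Trial index within `epochs`.
#' @param N_r Number of initial repetitions to average (1..10).
#' @param panel Panel to score; defaults to the trial's cued panel.
#' @return A list of class `trial_score`: `trial`, `N_r`, `scores` (one
#'   per icon), `detected`, `cued`, `correct` (0/1), `tie` (logical).
#' @export
score_trial <- function(model, epochs, trial, N_r, panel = NULL) {
  stopifnot(inherits(model, "p300_decoder"), inherits(epochs, "epoch_set"))
  cued <- .cued_of_trial(epochs, trial)
  if (is.null(panel)) panel <- cued$panel
  sel <- epochs$index$trial == trial & epochs$index$panel == panel &
    epochs$index$repetition <= N_r
  if (!any(sel)) stop("no epochs for trial ", trial, " at N_r = ", N_r)
  idx <- epochs$index[sel, ]
  X <- featurize(.epoch_subset(epochs, which(sel)))
  icons <- sort(unique(idx$icon))
  scores <- vapply(icons, function(ic) {
    rows <- which(idx$icon == ic)
    if (length(rows) < 1) stop("missing epochs for icon ", ic)
    mean(drop(X[rows, , drop = FALSE] %*% model$w) + model$b)
  }, numeric(1))
  names(scores) <- icons
  top <- which(scores == max(scores))
  tie <- length(top) > 1
  detected <- icons[min(top)]
  correct <- as.integer(detected == cued$icon && panel == cued$panel)
  structure(list(trial = trial, N_r = N_r, scores = scores,
                 detected = detected, cued = cued$icon,
                 panel = panel, correct = correct, tie = tie),
            class = "trial_score")
}

#' @export
print.trial_score <- function(x, ...) {
  cat(sprintf("Trial %d (N_r = %d): detected icon %d, cued %d -> %s%s\n",
              x$trial, x$N_r, x$detected, x$cued,
              if (x$correct == 1) "correct" else "incorrect",
              if (x$tie) " (tie)" else ""))
  invisible(x)
}

# score every trial of a test epoch set at every N_r; returns a data.frame
.score_run <- function(model, epochs, N_r_values, run_label = NA) {
  trials <- sort(unique(epochs$index$trial))
  out <- vector("list", length(trials) * length(N_r_values))
  k <- 1
  for (tr in trials) {
    for (nr in N_r_values) {
      s <- score_trial(model, epochs, tr, nr)
      out[[k]] <- data.frame(run = run_label, trial = tr, N_r = nr,
                             detected = s$detected, cued = s$cued,
                             correct = s$correct, tie = s$tie)
      k <- k + 1
    }
  }
  do.call(rbind, out)
}

# concatenate epoch sets (same window/rate/channels) for training
.epoch_bind <- function(sets) {
  ref <- sets[[1]]
  n <- vapply(sets, function(s) dim(s$epochs)[1], integer(1))
  epochs <- array(NA_real_, c(sum(n), dim(ref$epochs)[2], dim(ref$epochs)[3]))
  at <- 0
  for (s in sets) {
    epochs[at + seq_len(dim(s$epochs)[1]), , ] <- s$epochs
    at <- at + dim(s$epochs)[1]
  }
  structure(list(
    epochs = epochs, window = ref$window,
    labels = unlist(lapply(sets, `[[`, "labels")),
    index = do.call(rbind, lapply(sets, `[[`, "index")),
    sampling_rate = ref$sampling_rate,
    channel_labels = ref$channel_labels,
    run_id = NA), class = "epoch_set")
}

#' Run-level cross-validated P300 detection
#'
#' Evaluates P300 target detection across experimental runs under one of
#' two schemes: `"3-fold-by-run"` trains on 2 of 3 runs and tests on every
#' trial of the held-out run (rotating; 36 correctness values per `N_r`
#' with 12-trial runs), or `"train-2-test-6"` trains on the first 2 of 8
#' runs and tests on the remaining 6 (72 values per `N_r`).
#'
#' @param runs List of `epoch_set`s, one per run, sharing window and rate.
#' @param scheme Cross-validation scheme (see above).
#' @param seed Integer seed (inner fold assignment).
#' @param N_r_values Repetition counts at which to score (default 1..10).
#' @param cost_grid,inner_folds Passed to [train_decoder()].
#' @return A data.frame with one row per (test run, trial, N_r):
#'   columns `run`, `trial`, `N_r`, `detected`, `cued`, `correct`, `tie`.
#' @export
crossvalidate_runs <- function(runs,
                               scheme = c("3-fold-by-run", "train-2-test-6"),
                               seed = 1, N_r_values = 1:10,
                               cost_grid = 10 ^ seq(-5, 2, length.out = 15),
                               inner_folds = 10) {
  scheme <- match.arg(scheme)
  need <- if (scheme == "3-fold-by-run") 3L else 8L
  if (length(runs) != need)
    stop(sprintf("scheme '%s' requires exactly %d runs, got %d",
                 scheme, need, length(runs)))
  splits <- if (scheme == "3-fold-by-run") {
    lapply(1:3, function(i) list(train = setdiff(1:3, i), test = i))
  } else {
    list(list(train = 1:2, test = 3:8))
  }
  out <- list()
  for (sp in splits) {
    model <- train_decoder(.epoch_bind(runs[sp$train]), seed = seed,
                           cost_grid = cost_grid, inner_folds = inner_folds)
    for (te in sp$test)
      out[[length(out) + 1]] <-
        .score_run(model, runs[[te]], N_r_values, run_label = te)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
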