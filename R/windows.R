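#' Slide fixed-length windows over epochs
#'
#' Cuts each trial into `windows_per_epoch` windows of `window` seconds,
#' starts evenly spaced from 0 to `epoch_length - window` (for 3 s epochs
#' and 4 windows this is a 2/3 s stride).  Each window inherits its source
#' trial's label; the source trial index is retained so train/test splits
#' can keep a trial's windows together.
#'
#' @param epochs An `mi_epochs`.
#' @param window Window length in seconds.
#' @param windows_per_epoch Windows per trial.
#' @return A windowed `mi_epochs` with `source_trial` and `offsets_s`
#'   fields.
#' @export
sliding_windows <- function(epochs, window = 1.0, windows_per_epoch = 4) {
  stopifnot(inherits(epochs, "mi_epochs"))
  n_tr <- n_epochs(epochs); n_ch <- dim(epochs$epochs)[2]
  len <- dim(epochs$epochs)[3]
  wlen <- round(window * epochs$fs)
  if (wlen > len)
    stop_mibci("epoch (%d samples) shorter than window (%d samples)",
               len, wlen)
  starts <- if (windows_per_epoch == 1) 0 else
    round(seq(0, len - wlen, length.out = windows_per_epoch))
  n_win <- n_tr * windows_per_epoch
  out <- array(0, c(n_win, n_ch, wlen))
  k <- 0L
  for (tr in seq_len(n_tr)) {
    for (s in starts) {
      k <- k + 1L
      out[k, , ] <- epochs$epochs[tr, , (s + 1):(s + wlen)]
    }
  }
  src <- rep(seq_len(n_tr), each = windows_per_epoch)
  res <- epoch_set(out, epochs$labels[src], epochs$onsets[src],
                   0, window, epochs$fs, epochs$channel_names,
                   epochs$session_ids[src], epochs$normalization_stats)
  res$source_trial <- src
  res$offsets_s <- rep(starts / epochs$fs, times = n_tr)
  res
}

#' Stack Morlet planes and CSP features into one tensor
#'
#' Flattens per-window Morlet power (channels x freqs) into feature
#' channels and appends the window's CSP log-variance values as extra
#' feature channels tiled along the decimated time axis, so both feature
#' families share one windows x feature_channels x time tensor.  Either
#' part may be omitted (ablation paths).
#'
#' @param morlet Windows x channels x freqs x time array from
#'   [morlet_power()], or `NULL` for the CSP-only path.
#' @param csp Windows x components matrix from [csp_features()], or `NULL`
#'   for the Morlet-only path.
#' @param labels Class label per window.
#' @param source_trial Source trial index per window (for split grouping).
#' @return An object of class `mi_features` with fields `x` (windows x
#'   feature_channels x time), `labels`, `source_trial`.
#' @export
stack_features <- function(morlet = NULL, csp = NULL, labels,
                           source_trial = NULL) {
  if (is.null(morlet) && is.null(csp))
    stop_mibci("at least one feature family required")
  if (!is.null(morlet)) {
    n_win <- dim(morlet)[1]
    n_t <- dim(morlet)[4]
    planes <- array(aperm(morlet, c(1, 3, 2, 4)),
                    c(n_win, dim(morlet)[2] * dim(morlet)[3], n_t))
  }
  if (!is.null(csp)) {
    if (!is.null(morlet) && nrow(csp) != n_win)
      stop_mibci("window-count mismatch: %d Morlet vs %d CSP",
                 n_win, nrow(csp))
    if (is.null(morlet)) {
      n_win <- nrow(csp)
      n_t <- 1L
    }
    tiled <- array(rep(csp, times = n_t), c(n_win, ncol(csp), n_t))
  }
  x <- if (is.null(csp)) planes else if (is.null(morlet)) tiled else {
    out <- array(0, c(n_win, dim(planes)[2] + dim(tiled)[2], n_t))
    out[, seq_len(dim(planes)[2]), ] <- planes
    out[, dim(planes)[2] + seq_len(dim(tiled)[2]), ] <- tiled
    out
  }
  if (length(labels) != n_win)
    stop_mibci("labels length != window count")
  structure(list(x = x, labels = labels,
                 source_trial = source_trial %||% seq_len(n_win)),
            class = "mi_features")
}

#' @export
print.mi_features <- function(x, ...) {
  cat(sprintf("<mi_features> %d windows x %d feature channels x %d time\n",
              dim(x$x)[1], dim(x$x)[2], dim(x$x)[3]))
  print(table(x$labels))
  invisible(x)
}

#' Stratified train/test split without trial leakage
#'
#' Splits at the source-trial level, per class, so windows cut from the
#' same trial never straddle the split; within each class
#' `round(train_fraction * n_trials)` trials go to training.
#'
#' @param features An `mi_features` (or any list with `labels` and
#'   `source_trial`).
#' @param train_fraction Fraction of each class's trials used for training.
#' @param seed Integer seed; a fixed seed reproduces the split.
#' @return A list with window index vectors `train` and `test`.
#' @export
stratified_split <- function(features, train_fraction = 0.8, seed = 1) {
  if (!(train_fraction > 0 && train_fraction < 1))
    stop_mibci("train_fraction must lie in (0, 1)")
  labels <- features$labels
  src <- features$source_trial
  if (length(unique(labels)) < 2)
    stop_mibci("cannot stratify: a single class is present")
  counts <- table(labels)
  if (any(counts < 5))
    stop_mibci("class '%s' has only %d windows (need >= 5)",
               names(counts)[which.min(counts)], min(counts))
  with_seed(seed, {
    train <- integer(0)
    for (cl in sort(unique(labels))) {
      trials <- unique(src[labels == cl])
      n_train <- round(train_fraction * length(trials))
      n_train <- min(max(n_train, 1L), length(trials) - 1L)
      chosen <- sample(trials, n_train)
      train <- c(train, which(src %in% chosen & labels == cl))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}
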