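#' Remove the start of a recording
#'
#' Drops the first `seconds` of signal to discard filter initialization and
#' adaptation transients.  Marker onsets are shifted accordingly; markers
#' that fall inside the cropped region are dropped.
#'
#' @param rec An `mi_recording`.
#' @param seconds Crop length (default 10 s).
#' @return The cropped `mi_recording`.
#' @export
crop_head <- function(rec, seconds = 10) {
  stopifnot(inherits(rec, "mi_recording"))
  n_drop <- round(seconds * rec$fs)
  if (n_drop >= ncol(rec$data))
    stop_mibci("recording (%.2f s) shorter than crop (%g s): unusable",
               recording_duration(rec), seconds)
  rec$data <- rec$data[, -seq_len(n_drop), drop = FALSE]
  if (nrow(rec$markers)) {
    rec$markers$onset <- rec$markers$onset - seconds
    rec$markers <- rec$markers[rec$markers$onset >= 0, , drop = FALSE]
    rownames(rec$markers) <- NULL
  }
  rec
}

#' Channel-rejection rules
#'
#' Thresholds for the three artifact categories screened before
#' re-referencing: flat channels, channels with excessive broadband noise,
#' and channels carrying non-physiological spikes.
#'
#' @param flatline_sd_floor Minimum admissible channel SD in microvolts.
#' @param noise_ratio_cap Maximum robust SD as a multiple of the median
#'   robust SD across channels.
#' @param spike_amplitude_cap Maximum admissible absolute amplitude in
#'   microvolts.
#' @return An object of class `mi_reject_rules`.
#' @export
channel_reject_rules <- function(flatline_sd_floor = 0.1,
                                 noise_ratio_cap = 5,
                                 spike_amplitude_cap = 500) {
  if (any(c(flatline_sd_floor, noise_ratio_cap, spike_amplitude_cap) <= 0))
    stop_mibci("all rejection thresholds must be > 0")
  structure(list(flatline_sd_floor = flatline_sd_floor,
                 noise_ratio_cap = noise_ratio_cap,
                 spike_amplitude_cap = spike_amplitude_cap),
            class = "mi_reject_rules")
}

#' Reject channels with extreme artifacts
#'
#' @param rec An `mi_recording` with at least 2 channels.
#' @param rules An `mi_reject_rules`.
#' @return A list with the `recording` restricted to surviving channels (in
#'   original order) and the `rejected` channel names.
#' @export
reject_channels <- function(rec, rules = channel_reject_rules()) {
  stopifnot(inherits(rec, "mi_recording"))
  if (nrow(rec$data) < 2) stop_mibci("need >= 2 channels")
  sds <- apply(rec$data, 1, stats::sd)
  robust <- apply(rec$data, 1, stats::mad)
  peak <- apply(abs(rec$data), 1, max)
  bad <- sds < rules$flatline_sd_floor |
    robust > rules$noise_ratio_cap * stats::median(robust) |
    peak > rules$spike_amplitude_cap
  if (all(bad)) stop_mibci("all channels rejected: recording unusable")
  rejected <- rec$channel_names[bad]
  rec$data <- rec$data[!bad, , drop = FALSE]
  rec$channel_names <- rec$channel_names[!bad]
  list(recording = rec, rejected = rejected)
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the cross-channel mean is zero at every sample.  Applied after artifact
#' subspace reconstruction so that ASR sees full-rank data.
#'
#' @param x Channels x samples matrix or an `mi_recording`.
#' @return Same type as the input, re-referenced.
#' @export
common_average_reference <- function(x) {
  if (inherits(x, "mi_recording")) {
    x$data <- common_average_reference(x$data)
    return(x)
  }
  if (nrow(x) < 2) stop_mibci("common average reference needs >= 2 channels")
  sweep(x, 2, colMeans(x))
}

#' Construct an epoch-set object
#' @keywords internal
epoch_set <- function(epochs, labels, onsets, tmin, tmax, fs, channel_names,
                      session_ids, normalization_stats = NULL) {
  stopifnot(length(labels) == dim(epochs)[1], tmax > tmin)
  structure(list(epochs = epochs, labels = labels, onsets = onsets,
                 tmin = tmin, tmax = tmax, fs = fs,
                 channel_names = channel_names, session_ids = session_ids,
                 normalization_stats = normalization_stats),
            class = "mi_epochs")
}

#' @export
print.mi_epochs <- function(x, ...) {
  cat(sprintf("<mi_epochs> %d trials x %d ch x %d samples [%g, %g) s @ %g Hz\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3],
              x$tmin, x$tmax, x$fs))
  print(table(x$labels))
  invisible(x)
}

n_epochs <- function(ep) dim(ep$epochs)[1]

#' Segment a recording into task-locked epochs
#'
#' Extracts one epoch per task-onset marker (labels suffixed `"/task"`),
#' time-locked to task onset, over the half-open window `[tmin, tmax)`.
#' The `mapping` gives cue-label to class correspondence; task markers whose
#' cue label is not mapped are ignored and counted.  Trials whose window
#' exceeds the recording are dropped and counted.
#'
#' @param rec An `mi_recording`.
#' @param mapping Named character vector: cue marker label -> class name.
#' @param tmin,tmax Window bounds in seconds relative to task onset.
#' @return An `mi_epochs`; attribute `report` holds `n_dropped` and
#'   `n_unmapped`.
#' @export
epoch <- function(rec, mapping, tmin = 0.0, tmax = 3.0) {
  stopifnot(inherits(rec, "mi_recording"))
  if (!nrow(rec$markers)) stop_mibci("recording has no markers")
  is_task <- grepl("/task$", rec$markers$label)
  cue_lab <- sub("/task$", "", rec$markers$label[is_task])
  onset <- rec$markers$onset[is_task]
  mapped <- cue_lab %in% names(mapping)
  n_unmapped <- sum(!mapped)
  cue_lab <- cue_lab[mapped]; onset <- onset[mapped]
  if (!length(onset)) stop_mibci("no mappable task markers in recording")
  len <- round((tmax - tmin) * rec$fs)
  i0 <- round(onset * rec$fs) + round(tmin * rec$fs) + 1L
  ok <- i0 >= 1L & (i0 + len - 1L) <= ncol(rec$data)
  n_dropped <- sum(!ok)
  if (n_dropped) warning(sprintf("%d trial(s) dropped: window out of range",
                                 n_dropped))
  i0 <- i0[ok]; cue_lab <- cue_lab[ok]; onset <- onset[ok]
  ep <- array(0, c(length(i0), nrow(rec$data), len))
  for (k in seq_along(i0)) {
    ep[k, , ] <- rec$data[, i0[k]:(i0[k] + len - 1L)]
  }
  out <- epoch_set(ep, unname(mapping[cue_lab]), onset, tmin, tmax, rec$fs,
                   rec$channel_names, rep(rec$session_id, length(i0)))
  attr(out, "report") <- list(n_dropped = n_dropped, n_unmapped = n_unmapped)
  out
}

#' Baseline-correct epochs against the pre-cue interval
#'
#' Subtracts, per trial and channel, the mean of the continuous signal over
#' a baseline interval expressed relative to cue onset (cue onset =
#' task onset - `cue_lead`).  The source recording is required because the
#' default baseline `[-1, 0)` s before the cue lies outside the task epoch.
#' Trials whose baseline interval is not covered by the recording are
#' dropped with a warning.
#'
#' @param epochs An `mi_epochs` produced by [epoch()].
#' @param rec The source `mi_recording`.
#' @param baseline `(t0, t1)` in seconds relative to cue onset.
#' @param cue_lead Seconds from cue onset to task onset (cue duration).
#' @return The corrected `mi_epochs`.
#' @export
baseline_correct <- function(epochs, rec, baseline = c(-1, 0), cue_lead = 1) {
  stopifnot(inherits(epochs, "mi_epochs"), inherits(rec, "mi_recording"))
  t0 <- epochs$onsets - cue_lead + baseline[1]
  t1 <- epochs$onsets - cue_lead + baseline[2]
  ok <- t0 >= 0 & t1 <= recording_duration(rec)
  if (any(!ok)) warning(sprintf("%d trial(s) dropped: baseline out of range",
                                sum(!ok)))
  keep <- which(ok)
  out <- epochs
  out$epochs <- epochs$epochs[keep, , , drop = FALSE]
  out$labels <- epochs$labels[keep]
  out$onsets <- epochs$onsets[keep]
  out$session_ids <- epochs$session_ids[keep]
  for (k in seq_along(keep)) {
    a <- floor(t0[keep[k]] * rec$fs) + 1L
    b <- max(a, ceiling(t1[keep[k]] * rec$fs) - 1L)
    mu <- rowMeans(rec$data[, a:b, drop = FALSE])
    out$epochs[k, , ] <- out$epochs[k, , ] - mu
  }
  out
}

#' Normalize epochs per session and channel
#'
#' Z-scores every `(session, channel)` pair over that session's pooled epoch
#' samples.  The statistics are stored on the result (and reusable online
#' via [apply_normalization()]); a constant channel gets an SD floor of
#' 1e-12 and is flagged.
#'
#' @param epochs An `mi_epochs`.
#' @return The normalized `mi_epochs` with `normalization_stats` populated.
#' @export
normalize_sessions <- function(epochs) {
  stopifnot(inherits(epochs, "mi_epochs"))
  stats_by_session <- list()
  for (s in unique(epochs$session_ids)) {
    idx <- which(epochs$session_ids == s)
    x <- epochs$epochs[idx, , , drop = FALSE]
    mu <- apply(x, 2, mean)
    sdv <- apply(x, 2, stats::sd)
    flagged <- sdv < 1e-12
    sdv[flagged] <- 1e-12
    stats_by_session[[s]] <- list(mean = mu, sd = sdv, flagged = flagged)
  }
  epochs$normalization_stats <- stats_by_session
  apply_normalization(epochs, stats_by_session)
}

#' Apply stored normalization statistics
#'
#' @param epochs An `mi_epochs`.
#' @param stats Per-session statistics as stored by [normalize_sessions()];
#'   sessions not present fall back to the first entry (the online path
#'   reuses training statistics).
#' @return The normalized `mi_epochs`.
#' @export
apply_normalization <- function(epochs, stats) {
  out <- epochs
  out$normalization_stats <- stats
  for (k in seq_len(n_epochs(epochs))) {
    st <- stats[[epochs$session_ids[k]]] %||% stats[[1]]
    out$epochs[k, , ] <- (epochs$epochs[k, , ] - st$mean) / st$sd
  }
  out
}
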