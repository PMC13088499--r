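#' Cue-paradigm description
#'
#' Timing and class bookkeeping of the arrow-cue trial paradigm: each trial is
#' a break (cross on screen), a cue (arrow/circle) and a task period in which
#' the imagery or rest task is performed.  Task onset is defined as cue
#' offset: imagery starts once the cue disappears.
#'
#' @param cue_duration Cue display time in seconds.
#' @param task_duration Imagery/rest period in seconds.
#' @param break_duration Inter-trial break in seconds.
#' @param class_labels Ordered character vector of task names (>= 2).
#' @param trials_per_class Number of trials per class.
#' @param marker_vocabulary Named character vector mapping class label to the
#'   cue marker string written into the recording.  Task-onset markers carry
#'   the same string suffixed with `"/task"`.
#' @return An object of class `mi_paradigm`.
#' @export
paradigm_spec <- function(cue_duration = 1.0, task_duration = 3.0,
                          break_duration = 3.0,
                          class_labels = c("rest", "left_mi", "right_mi"),
                          trials_per_class = 10,
                          marker_vocabulary = NULL) {
  if (any(c(cue_duration, task_duration, break_duration) <= 0))
    stop_mibci("all paradigm durations must be > 0")
  if (length(class_labels) < 2) stop_mibci("need at least 2 classes")
  if (trials_per_class < 1) stop_mibci("trials_per_class must be >= 1")
  if (is.null(marker_vocabulary)) {
    marker_vocabulary <- stats::setNames(paste0("cue_", class_labels), class_labels)
  }
  if (!all(class_labels %in% names(marker_vocabulary)))
    stop_mibci("marker_vocabulary must cover every class label")
  structure(list(
    cue_duration = cue_duration, task_duration = task_duration,
    break_duration = break_duration, class_labels = class_labels,
    trials_per_class = as.integer(trials_per_class),
    marker_vocabulary = marker_vocabulary
  ), class = "mi_paradigm")
}

#' Canonical event-related-desynchronization layout
#'
#' The default study condition for the three-class paradigm: imagery of one
#' hand attenuates the mu/beta rhythm over the contralateral motor cortex,
#' strongest at the C3/C4 electrode and spread at half depth to its
#' frontocentral and centroparietal neighbours; rest carries no
#' modulation.
#'
#' @param depth Peak attenuation fraction at the focal electrode.
#' @return A named list suitable for the `erd_depth` field of
#'   [sim_config()].
#' @export
default_erd_depth <- function(depth = 0.6) {
  list(left_mi  = c(C4 = depth, FC6 = depth / 2, CP6 = depth / 2),
       right_mi = c(C3 = depth, FC5 = depth / 2, CP5 = depth / 2))
}

#' Task-onset marker label for a class
#' @param paradigm An `mi_paradigm`.
#' @param class Class label.
#' @return The marker string attached to task onsets of that class.
#' @export
task_marker <- function(paradigm, class) {
  paste0(paradigm$marker_vocabulary[[class]], "/task")
}

#' Synthetic-EEG generator configuration
#'
#' Defines the statistical structure of the simulated recordings: 1/f
#' background activity, alpha (10 Hz) and beta (20 Hz) sensorimotor
#' oscillations whose amplitude is attenuated during task periods
#' (event-related desynchronization), plus stereotyped eye-blink transients,
#' high-frequency muscle bursts and 50 Hz line interference.
#'
#' `erd_depth` is a list mapping class label to a named numeric vector of
#' per-channel attenuation fractions in [0, 1): during a task period of class
#' `c`, the oscillation amplitude at channel `ch` is multiplied by
#' `1 - erd_depth[[c]][ch]`, so band power scales as `(1 - d)^2`.
#'
#' @param n_channels Number of EEG channels.
#' @param fs Sampling rate in Hz (must exceed 72 Hz so the beta band is
#'   resolvable).
#' @param channel_names Channel labels; defaults to the 24-channel 10-20
#'   montage of [default_montage()].
#' @param background_exponent Spectral slope of the 1/f background (power
#'   falls as `f^-exponent`).
#' @param background_amp Background RMS amplitude per channel in microvolts
#'   (0 disables the noise floor).
#' @param alpha_amp,beta_amp Oscillation amplitudes in microvolts; either a
#'   scalar applied to all channels or a named per-channel vector.  The
#'   defaults give the sensorimotor strip (frontocentral to centroparietal
#'   rows) a prominent mu/beta rhythm (10 and 5 uV) over a 4/2 uV
#'   background rhythm elsewhere, the regime in which event-related
#'   desynchronization is visible at the single-trial level.
#' @param erd_depth List of per-class named channel vectors, values in [0,1).
#' @param blink_rate,muscle_rate Artifact event rates in events per minute.
#' @param blink_amp Blink peak amplitude in microvolts at the frontal pole.
#' @param line_amp 50 Hz line-interference amplitude in microvolts.
#' @param seed Integer seed; identical configurations produce bit-identical
#'   recordings.
#' @return An object of class `mi_simconfig`.
#' @export
sim_config <- function(n_channels = 24, fs = 250, channel_names = NULL,
                       background_exponent = 1.0, background_amp = 8,
                       alpha_amp = NULL, beta_amp = NULL,
                       erd_depth = list(), blink_rate = 8, muscle_rate = 2,
                       blink_amp = 150, line_amp = 1, seed = 1) {
  if (fs <= 2 * 36) stop_mibci("fs = %g Hz too low: need fs > 72 Hz for the beta band", fs)
  montage <- default_montage()
  if (is.null(channel_names)) channel_names <- montage$name[seq_len(n_channels)]
  if (length(channel_names) != n_channels)
    stop_mibci("channel_names length != n_channels")
  central <- intersect(c("FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4",
                         "T8", "CP5", "CP1", "CP2", "CP6"), channel_names)
  if (is.null(alpha_amp)) {
    alpha_amp <- stats::setNames(rep(4, n_channels), channel_names)
    alpha_amp[central] <- 10
  }
  if (is.null(beta_amp)) {
    beta_amp <- stats::setNames(rep(2, n_channels), channel_names)
    beta_amp[central] <- 5
  }
  expand <- function(a) {
    if (length(a) == 1 && is.null(names(a)))
      return(stats::setNames(rep(as.numeric(a), n_channels), channel_names))
    out <- stats::setNames(numeric(n_channels), channel_names)
    out[names(a)] <- a
    out
  }
  alpha_amp <- expand(alpha_amp); beta_amp <- expand(beta_amp)
  if (any(alpha_amp < 0) || any(beta_amp < 0) || background_amp < 0 ||
      blink_amp < 0 || line_amp < 0)
    stop_mibci("amplitudes must be >= 0")
  for (cls in names(erd_depth)) {
    d <- erd_depth[[cls]]
    if (any(d < 0) || any(d >= 1))
      stop_mibci("erd_depth values must lie in [0, 1); got %s for class %s",
                 paste(d, collapse = ","), cls)
    if (!all(names(d) %in% channel_names))
      stop_mibci("erd_depth for class %s names unknown channels", cls)
  }
  structure(list(
    n_channels = as.integer(n_channels), fs = fs,
    channel_names = channel_names,
    background_exponent = background_exponent, background_amp = background_amp,
    alpha_amp = alpha_amp, beta_amp = beta_amp, erd_depth = erd_depth,
    blink_rate = blink_rate, muscle_rate = muscle_rate, blink_amp = blink_amp,
    line_amp = line_amp, seed = as.integer(seed),
    montage = montage[match(channel_names, montage$name), , drop = FALSE]
  ), class = "mi_simconfig")
}

#' Construct a raw-recording object
#'
#' Continuous multichannel EEG in microvolts with event markers.
#'
#' @param data Channels x samples numeric matrix (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one per row of `data`.
#' @param markers data.frame with columns `onset` (seconds) and `label`.
#' @param session_id Free-form session identifier.
#' @return An object of class `mi_recording`.
#' @export
raw_recording <- function(data, fs, channel_names,
                          markers = data.frame(onset = numeric(0),
                                               label = character(0)),
                          session_id = "S1") {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop_mibci("recording data must be finite")
  if (nrow(data) != length(channel_names))
    stop_mibci("channel_names length (%d) != channel count (%d)",
               length(channel_names), nrow(data))
  dur <- ncol(data) / fs
  if (nrow(markers)) {
    markers <- markers[order(markers$onset), , drop = FALSE]
    rownames(markers) <- NULL
    if (any(markers$onset < 0) || any(markers$onset > dur))
      stop_mibci("marker onsets must lie within [0, duration]")
  }
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 markers = markers, session_id = session_id),
            class = "mi_recording")
}

#' @export
print.mi_recording <- function(x, ...) {
  cat(sprintf("<mi_recording> %d ch x %d samples @ %g Hz (%.1f s), %d markers, session %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$markers), x$session_id))
  invisible(x)
}

recording_duration <- function(rec) ncol(rec$data) / rec$fs

# 1/f-shaped Gaussian noise, target RMS `amp`, via spectral amplitude shaping.
shaped_noise <- function(n, fs, exponent, amp) {
  if (amp == 0) return(numeric(n))
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]          # mirror to two-sided frequencies
  shape <- c(0, pmax(f[-1], f[2])^(-exponent / 2))
  x <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
  x * amp / stats::sd(x)
}

# Smooth biphasic pulse of unit peak height and duration `dur` seconds.
blink_pulse <- function(dur, fs) {
  n <- max(4L, round(dur * fs))
  u <- seq(0, 1, length.out = n)
  p <- sin(pi * u)^2 * sin(2 * pi * u)
  p / max(abs(p))
}

# Band-limited (> f_lo Hz) noise burst with a Hann envelope, unit RMS.
muscle_burst <- function(dur, fs, f_lo = 30) {
  n <- max(8L, round(dur * fs))
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  spec[f < f_lo] <- 0
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x <- x * (0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n)))
  if (stats::sd(x) > 0) x <- x / stats::sd(x)
  x
}

add_event <- function(data, channel_weights, onset_sample, pulse) {
  n <- ncol(data)
  idx <- onset_sample + seq_along(pulse) - 1L
  keep <- idx >= 1L & idx <= n
  if (!any(keep)) return(data)
  data[, idx[keep]] <- data[, idx[keep]] +
    outer(channel_weights, pulse[keep])
  data
}

#' Generate a synthetic cue-paradigm recording
#'
#' Simulates a full arrow-cue session: per trial a break, a cue and a task
#' period, with class order randomized by the seed.  During each task period
#' the alpha/beta oscillation amplitude at the channels configured in
#' `erd_depth` is attenuated by `1 - depth` (event-related
#' desynchronization).  Eye blinks (frontal-weighted ~300 ms biphasic
#' transients), muscle bursts (>30 Hz, ~500 ms, temporal-weighted) and a
#' 50 Hz line component are superimposed at the configured rates.  Markers
#' record both cue onsets (class cue label) and task onsets (cue offset,
#' label suffixed `"/task"`).
#'
#' @param sim An `mi_simconfig`.
#' @param paradigm An `mi_paradigm`.
#' @param session_id Session identifier stored on the recording.
#' @return An `mi_recording`.
#' @export
#' @examples
#' rec <- generate_recording(sim_config(seed = 7), paradigm_spec(trials_per_class = 2))
#' rec
generate_recording <- function(sim, paradigm, session_id = "S1") {
  stopifnot(inherits(sim, "mi_simconfig"), inherits(paradigm, "mi_paradigm"))
  with_seed(sim$seed, {
    trial_len <- paradigm$break_duration + paradigm$cue_duration +
      paradigm$task_duration
    n_trials <- paradigm$trials_per_class * length(paradigm$class_labels)
    duration <- n_trials * trial_len + 1.0   # 1 s tail after the last task
    n <- round(duration * sim$fs)
    classes <- sample(rep(paradigm$class_labels, paradigm$trials_per_class))

    cue_on <- (seq_len(n_trials) - 1) * trial_len + paradigm$break_duration
    task_on <- cue_on + paradigm$cue_duration
    markers <- data.frame(
      onset = c(cue_on, task_on),
      label = c(paradigm$marker_vocabulary[classes],
                paste0(paradigm$marker_vocabulary[classes], "/task")),
      stringsAsFactors = FALSE
    )

    t <- (seq_len(n) - 1) / sim$fs
    # per-channel oscillation envelope: 1 outside tasks, (1 - depth) inside
    env <- matrix(1, sim$n_channels, n, dimnames = list(sim$channel_names, NULL))
    for (k in seq_len(n_trials)) {
      depths <- sim$erd_depth[[classes[k]]]
      if (is.null(depths) || !length(depths)) next
      span <- which(t >= task_on[k] & t < task_on[k] + paradigm$task_duration)
      env[names(depths), span] <- 1 - depths
    }

    data <- matrix(0, sim$n_channels, n, dimnames = list(sim$channel_names, NULL))
    for (ch in seq_len(sim$n_channels)) {
      phase_a <- stats::runif(1, 0, 2 * pi)
      phase_b <- stats::runif(1, 0, 2 * pi)
      data[ch, ] <- shaped_noise(n, sim$fs, sim$background_exponent,
                                 sim$background_amp) +
        sim$alpha_amp[ch] * env[ch, ] * sin(2 * pi * 10 * t + phase_a) +
        sim$beta_amp[ch]  * env[ch, ] * sin(2 * pi * 20 * t + phase_b)
    }
    if (sim$line_amp > 0)
      data <- data + matrix(sim$line_amp * sin(2 * pi * 50 * t),
                            sim$n_channels, n, byrow = TRUE)

    mont <- sim$montage
    if (sim$blink_rate > 0) {
      n_blinks <- stats::rpois(1, sim$blink_rate * duration / 60)
      w <- sim$blink_amp * exp(-sqrt(mont$x^2 + (mont$y - 0.95)^2) / 0.45)
      for (tt in stats::runif(n_blinks, 0, duration - 0.35)) {
        data <- add_event(data, w, round(tt * sim$fs) + 1L,
                          blink_pulse(0.3, sim$fs))
      }
    }
    if (sim$muscle_rate > 0) {
      n_bursts <- stats::rpois(1, sim$muscle_rate * duration / 60)
      amp <- 5 * max(sim$background_amp, 1)
      for (tt in stats::runif(n_bursts, 0, duration - 0.55)) {
        side <- if (stats::runif(1) < 0.5) "T7" else "T8"
        w <- amp * exp(-montage_distance(mont, side) / 0.3)
        data <- add_event(data, w, round(tt * sim$fs) + 1L,
                          muscle_burst(0.5, sim$fs))
      }
    }
    rec <- raw_recording(data, sim$fs, sim$channel_names, markers, session_id)
    attr(rec, "classes") <- classes
    attr(rec, "paradigm") <- paradigm
    rec
  })
}

#' Generate a clean calibration segment
#'
#' One artifact-free resting minute: background and oscillations only, no
#' task structure, no blinks/muscle/line events.  Used to estimate the clean
#' statistics that artifact subspace reconstruction needs.
#'
#' @param sim An `mi_simconfig` (artifact rates are ignored/forced to zero).
#' @param duration Segment length in seconds.
#' @param session_id Session identifier.
#' @return An `mi_recording` with no markers.
#' @export
generate_calibration <- function(sim, duration = 60, session_id = "calib") {
  stopifnot(inherits(sim, "mi_simconfig"))
  if (duration <= 0) stop_mibci("duration must be > 0")
  with_seed(sim$seed + 1L, {
    n <- round(duration * sim$fs)
    t <- (seq_len(n) - 1) / sim$fs
    data <- matrix(0, sim$n_channels, n,
                   dimnames = list(sim$channel_names, NULL))
    for (ch in seq_len(sim$n_channels)) {
      phase_a <- stats::runif(1, 0, 2 * pi)
      phase_b <- stats::runif(1, 0, 2 * pi)
      data[ch, ] <- shaped_noise(n, sim$fs, sim$background_exponent,
                                 sim$background_amp) +
        sim$alpha_amp[ch] * sin(2 * pi * 10 * t + phase_a) +
        sim$beta_amp[ch]  * sin(2 * pi * 20 * t + phase_b)
    }
    raw_recording(data, sim$fs, sim$channel_names, session_id = session_id)
  })
}

#' Integrated band power of a recording interval
#'
#' Periodogram power of one channel integrated over a frequency band, in
#' microvolts squared.  Validation helper for event-related
#' desynchronization checks: for a pure sinusoid of amplitude `a` inside the
#' band it returns approximately `a^2 / 2`.
#'
#' @param rec An `mi_recording`.
#' @param channel Channel name.
#' @param band Numeric `(f_lo, f_hi)` in Hz, inside `(0, fs/2)`.
#' @param interval Numeric `(t0, t1)` in seconds; defaults to the whole
#'   recording.
#' @return Non-negative scalar power in microvolts squared.
#' @export
band_power <- function(rec, channel, band, interval = NULL) {
  stopifnot(inherits(rec, "mi_recording"))
  i <- match(channel, rec$channel_names)
  if (is.na(i)) stop_mibci("unknown channel '%s'", channel)
  dur <- recording_duration(rec)
  if (is.null(interval)) interval <- c(0, dur)
  if (!(interval[1] >= 0 && interval[1] < interval[2] && interval[2] <= dur + 1e-9))
    stop_mibci("invalid interval [%g, %g] for a %.3f s recording",
               interval[1], interval[2], dur)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < rec$fs / 2))
    stop_mibci("band must lie within (0, fs/2)")
  a <- floor(interval[1] * rec$fs) + 1L
  b <- min(ncol(rec$data), ceiling(interval[2] * rec$fs))
  x <- rec$data[i, a:b]
  x <- x - mean(x)
  n <- length(x)
  if (n < 4) stop_mibci("interval too short")
  spec <- stats::fft(x)
  f <- (seq_len(n) - 1) * rec$fs / n
  half <- which(f > 0 & f <= rec$fs / 2)
  p <- 2 * Mod(spec[half])^2 / n^2              # one-sided power per bin
  sum(p[f[half] >= band[1] & f[half] <= band[2]])
}
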