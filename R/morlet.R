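#' Morlet time-frequency specification
#'
#' Single-trial spectro-temporal power on a fixed frequency grid.  Two
#' cycles per frequency gives deliberately coarse spectral resolution with
#' good temporal resolution; every third time sample of the output is kept
#' (temporal decimation by 3).
#'
#' @param freqs Analysis frequencies in Hz (default 8-30 Hz in 2 Hz steps).
#' @param n_cycles Wavelet cycles per frequency (>= 1).
#' @param decim Temporal decimation factor (>= 1).
#' @return An object of class `mi_morletspec`.
#' @export
morlet_spec <- function(freqs = seq(8, 30, by = 2), n_cycles = 2, decim = 3) {
  if (n_cycles < 1) stop_mibci("n_cycles must be >= 1")
  if (decim < 1) stop_mibci("decim must be >= 1")
  if (any(freqs <= 0)) stop_mibci("freqs must be > 0")
  structure(list(freqs = freqs, n_cycles = n_cycles,
                 decim = as.integer(decim)),
            class = "mi_morletspec")
}

# Complex Morlet wavelet, L1-normalized envelope (matched-frequency response
# is then amplitude/2 regardless of frequency), truncated at +/- 5 sigma.
morlet_wavelet <- function(f, fs, n_cycles) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(5 * sigma_t * fs)
  t <- (-half:half) / fs
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sum(Mod(w))
}

#' Single-trial Morlet power
#'
#' Convolves every trial and channel with complex Morlet wavelets and
#' returns the squared magnitude, decimated in time.  No trial averaging is
#' performed.
#'
#' @param epochs An `mi_epochs` (trials x channels x samples), or a plain
#'   channels x samples matrix with `fs` supplied.
#' @param spec An `mi_morletspec`.
#' @param fs Sampling rate for matrix input.
#' @return Array trials x channels x freqs x time (time decimated); for a
#'   matrix input the trial dimension is 1.  Attributes `freqs` and `fs`.
#' @export
morlet_power <- function(epochs, spec = morlet_spec(), fs = NULL) {
  if (inherits(epochs, "mi_epochs")) {
    x <- epochs$epochs
    fs <- epochs$fs
  } else {
    if (is.null(fs)) stop_mibci("fs required for matrix input")
    x <- array(epochs, c(1, dim(epochs)))
  }
  n_tr <- dim(x)[1]; n_ch <- dim(x)[2]; n <- dim(x)[3]
  wavelets <- lapply(spec$freqs, morlet_wavelet, fs = fs,
                     n_cycles = spec$n_cycles)
  max_nw <- max(vapply(wavelets, length, 0L))
  if (n < max_nw)
    stop_mibci(paste0("epoch too short: %d samples < %d-sample wavelet ",
                      "support at %g Hz"),
               n, max_nw, spec$freqs[which.max(vapply(wavelets, length, 0L))])
  n2 <- stats::nextn(n + max_nw, 2)
  keep <- seq(1L, n, by = spec$decim)
  out <- array(0, c(n_tr, n_ch, length(spec$freqs), length(keep)))

  # FFT the zero-padded trials once per channel, reuse across frequencies
  wf <- lapply(wavelets, function(w) {
    half <- (length(w) - 1L) / 2L
    wp <- complex(n2)
    wp[c(n2 - half + seq_len(half) - 1L + 1L, seq_len(half + 1L))] <-
      w  # circular shift: wavelet center at index 1
    stats::fft(wp)
  })
  for (ch in seq_len(n_ch)) {
    xp <- matrix(0, n2, n_tr)
    xp[seq_len(n), ] <- t(matrix(x[, ch, ], n_tr, n))
    Xf <- stats::mvfft(xp)
    for (fi in seq_along(spec$freqs)) {
      y <- stats::mvfft(Xf * wf[[fi]], inverse = TRUE) / n2
      out[, ch, fi, ] <- t(Mod(y[keep, , drop = FALSE])^2)
    }
  }
  attr(out, "freqs") <- spec$freqs
  attr(out, "fs") <- fs
  attr(out, "decim") <- spec$decim
  out
}

#' Event-related (de)synchronization map
#'
#' Percentage band-power change relative to a within-epoch baseline
#' interval: `100 * (P(t, f) - P_baseline(f)) / P_baseline(f)`, computed on
#' trial-averaged Morlet power per channel.  Negative values are
#' desynchronization (power loss during the task), positive values
#' synchronization.
#'
#' @param epochs An `mi_epochs`; epoch with a negative `tmin` so the
#'   baseline interval is inside the epoch.
#' @param baseline `(t0, t1)` in epoch time (seconds relative to task
#'   onset).
#' @param spec An `mi_morletspec`.
#' @param classes Optional subset of class labels to average over.
#' @return Array channels x freqs x time (percent); cells with
#'   non-positive baseline power are `NA`.  Attributes `freqs`, `times`.
#' @export
erds <- function(epochs, baseline, spec = morlet_spec(), classes = NULL) {
  stopifnot(inherits(epochs, "mi_epochs"))
  if (!(baseline[1] >= epochs$tmin && baseline[2] <= epochs$tmax &&
        baseline[1] < baseline[2]))
    stop_mibci("baseline [%g, %g) must lie inside the epoch [%g, %g)",
               baseline[1], baseline[2], epochs$tmin, epochs$tmax)
  if (!is.null(classes)) {
    keep <- epochs$labels %in% classes
    epochs$epochs <- epochs$epochs[keep, , , drop = FALSE]
    epochs$labels <- epochs$labels[keep]
    epochs$onsets <- epochs$onsets[keep]
    epochs$session_ids <- epochs$session_ids[keep]
  }
  pw <- morlet_power(epochs, spec)
  p_mean <- apply(pw, c(2, 3, 4), mean)           # channels x freqs x time
  times <- epochs$tmin + (seq_len(dim(p_mean)[3]) - 1) * spec$decim / epochs$fs
  in_base <- times >= baseline[1] & times < baseline[2]
  if (!any(in_base)) stop_mibci("baseline interval contains no samples")
  p_base <- apply(p_mean[, , in_base, drop = FALSE], c(1, 2), mean)
  out <- array(NA_real_, dim(p_mean))
  for (ti in seq_len(dim(p_mean)[3])) {
    ratio <- 100 * (p_mean[, , ti] - p_base) / p_base
    ratio[p_base <= 0] <- NA
    out[, , ti] <- ratio
  }
  attr(out, "freqs") <- spec$freqs
  attr(out, "times") <- times
  out
}
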