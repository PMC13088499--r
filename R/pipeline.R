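#' Train a full decoder from a recording and a calibration segment
#'
#' The complete offline chain: band-pass filtering, head-cropping, channel
#' rejection, ASR fitted on the clean calibration minute, common average
#' reference, task-locked epoching with pre-cue baseline correction,
#' per-session normalization, sliding-window augmentation, a leakage-free
#' stratified split, CSP fitted on training windows only, stacked
#' Morlet+CSP features, and S4D training with early stopping.
#'
#' @param rec Task `mi_recording`.
#' @param calibration Artifact-free calibration `mi_recording` (>= 40 s
#'   before cropping).
#' @param mapping Named character vector: cue marker label -> class.
#' @param fspec Filter specification.
#' @param mspec Morlet specification.
#' @param config S4D architecture configuration.
#' @param tcfg Training configuration.
#' @param crop_s Seconds cropped from the head of both recordings.
#' @param window,windows_per_epoch Sliding-window parameters.
#' @param train_fraction,split_seed Stratified-split parameters.
#' @param reject Apply channel rejection.
#' @return A list (`mi_decoder`): trained `model`, `csp`, `asr`, `filt`,
#'   `mspec`, `norm_stats`, `features`, `split`, `windows`, test
#'   `accuracy` and `confusion` matrix.
#' @export
train_decoder <- function(rec, calibration, mapping,
                          fspec = filter_spec(),
                          mspec = morlet_spec(),
                          config = s4d_config(),
                          tcfg = train_config(),
                          crop_s = 10, window = 1.0, windows_per_epoch = 4,
                          train_fraction = 0.8, split_seed = 1,
                          reject = TRUE) {
  filt <- design_filter(fspec)
  rec_f <- crop_head(filter_recording(rec, filt), crop_s)
  cal_f <- crop_head(filter_recording(calibration, filt), crop_s)

  if (reject) {
    rj <- reject_channels(rec_f)
    rec_f <- rj$recording
    if (length(rj$rejected)) {
      keep <- match(rec_f$channel_names, cal_f$channel_names)
      cal_f$data <- cal_f$data[keep, , drop = FALSE]
      cal_f$channel_names <- rec_f$channel_names
    }
  }

  asr <- fit_asr(cal_f)
  rec_f <- apply_asr(rec_f, asr)
  rec_f <- common_average_reference(rec_f)

  eps <- epoch(rec_f, mapping)
  eps <- baseline_correct(eps, rec_f)
  eps <- normalize_sessions(eps)
  windows <- sliding_windows(eps, window = window,
                             windows_per_epoch = windows_per_epoch)

  split <- stratified_split(windows, train_fraction = train_fraction,
                            seed = split_seed)
  train_eps <- windows$epochs[split$train, , , drop = FALSE]
  csp <- fit_csp(train_eps, windows$labels[split$train],
                 rank_deficient = "subspace")

  pw <- morlet_power(windows, mspec)
  cf <- csp_features(windows, csp)
  feats <- stack_features(pw, cf, windows$labels, windows$source_trial)

  model <- s4d_init(config, n_features = dim(feats$x)[2], seed = tcfg$seed)
  model$feature_hash <- feature_spec_hash(mspec, csp,
                                          length(rec_f$channel_names),
                                          window, rec_f$fs)
  xtr <- aperm(feats$x[split$train, , , drop = FALSE], c(2, 3, 1))
  xte <- aperm(feats$x[split$test, , , drop = FALSE], c(2, 3, 1))
  model <- s4d_train(model, xtr, feats$labels[split$train],
                     xte, feats$labels[split$test], tcfg)

  pred <- s4d_predict(model, xte)
  confusion <- table(truth = feats$labels[split$test], predicted = pred$class)
  structure(list(model = model, csp = csp, asr = asr, filt = filt,
                 mspec = mspec, norm_stats = eps$normalization_stats,
                 features = feats, split = split, windows = windows,
                 accuracy = mean(pred$class == feats$labels[split$test]),
                 confusion = confusion),
            class = "mi_decoder")
}

#' @export
print.mi_decoder <- function(x, ...) {
  cat(sprintf("<mi_decoder> test accuracy %.3f over %d test windows\n",
              x$accuracy, length(x$split$test)))
  print(x$confusion)
  invisible(x)
}

#' Online configuration from a trained decoder
#'
#' @param decoder An `mi_decoder` from [train_decoder()].
#' @param transfer An `mi_transfer`.
#' @param stride Online window stride in seconds.
#' @return An `mi_onlinecfg` ready for [run_pipeline()].
#' @export
decoder_online_config <- function(decoder, transfer = transfer_config(),
                                  stride = 0.5) {
  online_config(decoder$filt, decoder$asr, decoder$mspec, decoder$csp,
                decoder$model, norm_stats = decoder$norm_stats,
                window = decoder$windows$tmax, stride = stride,
                transfer = transfer)
}
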