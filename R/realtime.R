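# Replay-driven online runtime: bounded drop-oldest queues between
# cooperative pipeline stages, a rolling-buffer transfer function mapping
# class probabilities to control signals, and stage-level latency stamps.

#' Split a recording into an ordered chunk stream
#'
#' Contiguous, gapless chunks covering the whole recording, standing in for
#' a live acquisition stream during testing and replay.
#'
#' @param rec An `mi_recording`.
#' @param chunk_ms Chunk length in milliseconds (> 0).
#' @return List of `mi_chunk` objects with `samples` (channels x n),
#'   `first_sample_time` (s), `fs`.
#' @export
replay <- function(rec, chunk_ms = 100) {
  stopifnot(inherits(rec, "mi_recording"))
  if (chunk_ms <= 0) stop_mibci("chunk_ms must be > 0")
  step <- max(1L, round(chunk_ms / 1000 * rec$fs))
  starts <- seq(1L, ncol(rec$data), by = step)
  lapply(starts, function(s) {
    e <- min(ncol(rec$data), s + step - 1L)
    structure(list(samples = rec$data[, s:e, drop = FALSE],
                   first_sample_time = (s - 1) / rec$fs, fs = rec$fs),
              class = "mi_chunk")
  })
}

# Bounded FIFO queue; on overflow the OLDEST entry is dropped and counted.
queue_new <- function(capacity = 64L) {
  list(items = list(), capacity = as.integer(capacity), dropped = 0L)
}
queue_push <- function(q, item) {
  q$items[[length(q$items) + 1]] <- item
  if (length(q$items) > q$capacity) {
    q$items <- q$items[-1]
    q$dropped <- q$dropped + 1L
  }
  q
}
queue_pop <- function(q) {
  if (!length(q$items)) return(list(queue = q, item = NULL))
  item <- q$items[[1]]
  q$items <- q$items[-1]
  list(queue = q, item = item)
}

#' Transfer-function configuration
#'
#' The smoothing stage between classifier and effector: a rolling buffer of
#' the last `buffer_len` probability vectors is averaged; the most probable
#' class is emitted when its mean probability clears its threshold,
#' otherwise an explicit neutral token.  Class-to-control mapping supports
#' two continuous axes and two binary accumulators (up to five signals);
#' the defaults map rest to neutral and left/right imagery to the x axis.
#'
#' @param classes Ordered class labels (tie-breaks favour the earliest).
#' @param buffer_len Rolling-buffer length in classifications.
#' @param class_thresholds Scalar or per-class named mean-probability
#'   thresholds in (0, 1].
#' @param mapping Named list: class -> list with optional `x`, `y` in
#'   [-1, 1] and optional `binary` ("a" or "b").
#' @param binary_fill_rate,binary_decay_rate Accumulator units per tick.
#' @return An object of class `mi_transfer`.
#' @export
transfer_config <- function(classes = c("rest", "left_mi", "right_mi"),
                            buffer_len = 10, class_thresholds = 0.5,
                            mapping = NULL,
                            binary_fill_rate = 0.25,
                            binary_decay_rate = 0.25) {
  if (buffer_len < 1) stop_mibci("buffer_len must be >= 1")
  th <- if (length(class_thresholds) == 1)
    stats::setNames(rep(class_thresholds, length(classes)), classes) else
      class_thresholds[classes]
  if (any(is.na(th)) || any(th <= 0) || any(th > 1))
    stop_mibci("class thresholds must lie in (0, 1] and cover all classes")
  if (is.null(mapping)) {
    mapping <- stats::setNames(vector("list", length(classes)), classes)
    mapping[[1]] <- list()
    if (length(classes) >= 2) mapping[[2]] <- list(x = -1)
    if (length(classes) >= 3) mapping[[3]] <- list(x = 1)
  }
  structure(list(classes = classes, buffer_len = as.integer(buffer_len),
                 class_thresholds = th, mapping = mapping,
                 binary_fill_rate = binary_fill_rate,
                 binary_decay_rate = binary_decay_rate),
            class = "mi_transfer")
}

#' Initialize transfer-function state
#' @param cfg An `mi_transfer`.
#' @return State holding the empty rolling buffer and zero accumulators.
#' @export
transfer_state <- function(cfg) {
  list(cfg = cfg, buffer = matrix(0, 0, length(cfg$classes)),
       fills = c(a = 0, b = 0), tick = 0L)
}

#' One transfer-function update
#'
#' Pushes a probability vector into the rolling buffer and decides: the
#' argmax class of the buffer mean if that mean clears the class threshold,
#' else `"neutral"`.  Ties break toward the earliest class in the
#' configured order.
#'
#' @param state State from [transfer_state()].
#' @param probs Per-class probabilities summing to 1 (+/- 1e-3).
#' @return A list with the updated `state`, the `decision`, and the buffer
#'   `mean` per class.
#' @export
transfer_update <- function(state, probs) {
  cfg <- state$cfg
  probs <- as.numeric(probs)
  if (length(probs) != length(cfg$classes) || any(!is.finite(probs)) ||
      abs(sum(probs) - 1) > 1e-3)
    stop_mibci("malformed probability vector")
  state$buffer <- rbind(state$buffer, probs)
  if (nrow(state$buffer) > cfg$buffer_len)
    state$buffer <- state$buffer[-1, , drop = FALSE]
  m <- colMeans(state$buffer)
  best <- which.max(m)                       # first max: lowest-index tie-break
  decision <- if (m[best] >= cfg$class_thresholds[best])
    cfg$classes[best] else "neutral"
  list(state = state, decision = decision, mean = m)
}

#' Map a decision to a control frame
#'
#' Continuous axes are set from the class mapping (neutral gives 0, 0).
#' Each binary accumulator rises by `binary_fill_rate` on ticks whose
#' decision maps to it and decays by `binary_decay_rate` otherwise, clamped
#' to [0, 1]; on reaching 1 the signal fires for one tick and the
#' accumulator resets.
#'
#' @param decision A class label or `"neutral"`.
#' @param state Transfer state.
#' @return A list with `frame` (`tick`, `x`, `y`, `a`, `b`) and the updated
#'   `state`.
#' @export
map_controls <- function(decision, state) {
  cfg <- state$cfg
  if (!(decision %in% c(cfg$classes, "neutral")))
    stop_mibci("unmapped decision '%s'", decision)
  map <- if (decision == "neutral") list() else cfg$mapping[[decision]] %||% list()
  x <- map$x %||% 0; y <- map$y %||% 0
  fired <- c(a = 0, b = 0)
  for (sig in c("a", "b")) {
    if (!is.null(map$binary) && identical(map$binary, sig)) {
      state$fills[sig] <- state$fills[sig] + cfg$binary_fill_rate
    } else {
      state$fills[sig] <- state$fills[sig] - cfg$binary_decay_rate
    }
    state$fills[sig] <- clamp(state$fills[sig], 0, 1)
    if (state$fills[sig] >= 1) {
      fired[sig] <- 1
      state$fills[sig] <- 0
    }
  }
  state$tick <- state$tick + 1L
  list(frame = list(tick = state$tick, x = x, y = y,
                    a = unname(fired["a"]), b = unname(fired["b"])),
       state = state)
}

#' Online pipeline configuration
#'
#' Everything the streaming decoder needs: the stateful preprocessing
#' models, the feature configuration, the trained classifier and the
#' transfer function.  `run_pipeline` refuses to start when the model's
#' stored feature hash does not match this configuration.
#'
#' @param filt An `mi_filter`.
#' @param asr A fitted `mi_asr`.
#' @param morlet An `mi_morletspec`.
#' @param csp A fitted `mi_csp`.
#' @param model A trained `mi_s4d`.
#' @param norm_stats Normalization statistics from [normalize_sessions()]
#'   (the first session's statistics are reused online), or `NULL`.
#' @param window Decoder window length in seconds.
#' @param stride Window stride in seconds.
#' @param transfer An `mi_transfer`.
#' @param queue_capacity Bounded-queue capacity between stages.
#' @return An object of class `mi_onlinecfg`.
#' @export
online_config <- function(filt, asr, morlet, csp, model, norm_stats = NULL,
                          window = 1.0, stride = 0.5,
                          transfer = transfer_config(),
                          queue_capacity = 256L) {
  structure(list(filt = filt, asr = asr, morlet = morlet, csp = csp,
                 model = model, norm_stats = norm_stats, window = window,
                 stride = stride, transfer = transfer,
                 queue_capacity = as.integer(queue_capacity)),
            class = "mi_onlinecfg")
}

monotonic_clock <- function() proc.time()[["elapsed"]]

# Featurize one post-preprocessing window (shared by the batch and online
# decoders so the equivalence between them rests on the stateful stages).
featurize_window <- function(xw, cfg) {
  if (!is.null(cfg$norm_stats)) {
    st <- cfg$norm_stats[[1]]
    xw <- (xw - st$mean) / st$sd
  }
  pw <- morlet_power(xw, cfg$morlet, fs = cfg$filt$fs)
  cf <- csp_features(xw, cfg$csp)
  stack_features(pw, cf, labels = "?")$x[1, , , drop = FALSE]
}

#' Run the replay-driven online pipeline
#'
#' Four cooperative stages (acquisition, preprocessing, classification,
#' transfer) connected by order-preserving bounded queues that drop the
#' oldest entry on overflow.  The preprocessing stage carries filter and
#' ASR state across chunks and emits fixed-length decoder windows at the
#' configured stride; every control frame carries its full stage-stamp
#' lineage.  A feedback-state stream (smoothed probabilities, thresholds,
#' accumulator fills) is produced alongside the control frames.
#'
#' @param chunks Chunk list from [replay()] (or any `mi_chunk` stream).
#' @param cfg An `mi_onlinecfg`.
#' @param clock Monotonic time source (injectable for tests).
#' @return A list: `controls` (data.frame tick/x/y/a/b), `latency`
#'   (data.frame of per-window stage stamps), `feedback` (list of per-tick
#'   states), `probs` (windows x classes), `window_starts` (s),
#'   `dropped_chunks`.
#' @export
run_pipeline <- function(chunks, cfg, clock = monotonic_clock) {
  stopifnot(inherits(cfg, "mi_onlinecfg"))
  expected <- feature_spec_hash(cfg$morlet, cfg$csp, cfg$asr$n_channels,
                                cfg$window, cfg$filt$fs)
  if (!is.null(cfg$model$feature_hash) &&
      !identical(cfg$model$feature_hash, expected))
    stop_mibci("feature-spec hash mismatch: model was trained on '%s', pipeline provides '%s'",
               cfg$model$feature_hash, expected)

  fs <- cfg$filt$fs
  wlen <- round(cfg$window * fs)
  stride <- round(cfg$stride * fs)
  fstate <- filter_state(cfg$filt, cfg$asr$n_channels)
  astate <- asr_state(cfg$asr)
  tstate <- transfer_state(cfg$transfer)
  buf <- matrix(0, cfg$asr$n_channels, 0)
  buf_offset <- 0L                      # global index of buf[, 1] (0-based)
  next_start <- 0L                      # global sample index of next window

  q_pre <- queue_new(cfg$queue_capacity)
  q_cls <- queue_new(cfg$queue_capacity)
  q_tr <- queue_new(cfg$queue_capacity)

  controls <- list(); latency <- list(); feedback <- list()
  probs_out <- list(); window_starts <- numeric(0)

  for (ch in chunks) {
    q_pre <- queue_push(q_pre, list(chunk = ch, acquisition_t = clock()))
    # preprocessing stage
    repeat {
      pp <- queue_pop(q_pre); q_pre <- pp$queue
      if (is.null(pp$item)) break
      fr <- filter_chunk(pp$item$chunk$samples, fstate)
      fstate <- fr$state
      ar <- asr_chunk(fr$chunk, astate)
      astate <- ar$state
      if (ncol(ar$chunk)) {
        buf <- cbind(buf, common_average_reference(ar$chunk))
      }
      while (next_start + wlen <= buf_offset + ncol(buf)) {
        local <- next_start - buf_offset
        xw <- buf[, local + seq_len(wlen), drop = FALSE]
        q_cls <- queue_push(q_cls, list(
          features = featurize_window(xw, cfg),
          start_s = next_start / fs,
          acquisition_t = pp$item$acquisition_t, preprocess_t = clock()))
        next_start <- next_start + stride
      }
      # discard buffer samples no future window can need
      drop_n <- next_start - buf_offset
      if (drop_n > 0) {
        drop_n <- min(drop_n, ncol(buf))
        buf <- buf[, seq.int(drop_n + 1, length.out = ncol(buf) - drop_n),
                   drop = FALSE]
        buf_offset <- buf_offset + drop_n
      }
    }
    # classification stage
    repeat {
      cp <- queue_pop(q_cls); q_cls <- cp$queue
      if (is.null(cp$item)) break
      x <- array(cp$item$features[1, , ], dim(cp$item$features)[2:3])
      pr <- s4d_predict(cfg$model, x)$probs[, 1]
      q_tr <- queue_push(q_tr, c(cp$item["start_s"],
                                 list(probs = pr,
                                      acquisition_t = cp$item$acquisition_t,
                                      preprocess_t = cp$item$preprocess_t,
                                      classify_t = clock())))
    }
    # transfer stage
    repeat {
      tp <- queue_pop(q_tr); q_tr <- tp$queue
      if (is.null(tp$item)) break
      tu <- transfer_update(tstate, tp$item$probs)
      mc <- map_controls(tu$decision, tu$state)
      tstate <- mc$state
      transfer_t <- clock()
      controls[[length(controls) + 1]] <- mc$frame
      latency[[length(latency) + 1]] <- list(
        acquisition_t = tp$item$acquisition_t,
        preprocess_t = tp$item$preprocess_t,
        classify_t = tp$item$classify_t, transfer_t = transfer_t)
      feedback[[length(feedback) + 1]] <- list(
        tick = mc$frame$tick, probs = tu$mean,
        thresholds = cfg$transfer$class_thresholds,
        fills = tstate$fills, decision = tu$decision)
      probs_out[[length(probs_out) + 1]] <- tp$item$probs
      window_starts <- c(window_starts, tp$item$start_s)
    }
  }
  list(
    controls = do.call(rbind, lapply(controls, as.data.frame)),
    latency = do.call(rbind, lapply(latency, as.data.frame)),
    feedback = feedback,
    probs = if (length(probs_out)) do.call(rbind, probs_out) else NULL,
    window_starts = window_starts,
    dropped_chunks = q_pre$dropped + q_cls$dropped + q_tr$dropped
  )
}

#' Batch decoder over a continuous recording
#'
#' The offline counterpart of [run_pipeline()]: the identical stateful
#' preprocessing (filter, ASR, common average reference) applied to the
#' whole recording in one call, then the same per-window featurization and
#' classifier.  Used to verify that chunked streaming reproduces batch
#' probabilities.
#'
#' @param rec An `mi_recording`.
#' @param cfg An `mi_onlinecfg`.
#' @return A list with `probs` (windows x classes) and `window_starts`.
#' @export
decode_batch <- function(rec, cfg) {
  fs <- cfg$filt$fs
  wlen <- round(cfg$window * fs)
  stride <- round(cfg$stride * fs)
  fstate <- filter_state(cfg$filt, nrow(rec$data))
  xf <- filter_chunk(rec$data, fstate)$chunk
  ar <- asr_chunk(xf, asr_state(cfg$asr))      # no flush: match streaming
  xc <- common_average_reference(ar$chunk)
  starts <- seq(0L, ncol(xc) - wlen, by = stride)
  probs <- NULL
  for (s in starts) {
    xw <- xc[, s + seq_len(wlen), drop = FALSE]
    feats <- featurize_window(xw, cfg)
    x <- array(feats[1, , ], dim(feats)[2:3])
    probs <- rbind(probs, s4d_predict(cfg$model, x)$probs[, 1])
  }
  list(probs = probs, window_starts = starts / fs)
}
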