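# Closed-loop training game: QuickTime events in which the decoder must
# match a cued imagery class to fill a bar before the window expires.

#' QuickTime-event specification
#'
#' During an event the character pauses before an obstacle, a cue appears,
#' and decoder decisions drive a bar: matching decisions raise it by
#' `fill_rate`, mismatches let it decay by `decay_rate` (clamped at 0).
#' Reaching `threshold` within the window triggers the jump.
#'
#' @param window Event window in seconds.
#' @param threshold Bar units required for success.
#' @param fill_rate Units added per matching decision.
#' @param decay_rate Units removed per non-matching decision.
#' @param tick_interval Seconds between decisions.
#' @return An object of class `mi_quicktime`.
#' @export
quicktime_spec <- function(window = 3.0, threshold = 5, fill_rate = 1,
                           decay_rate = 0.5, tick_interval = 0.1) {
  vals <- c(window, threshold, fill_rate, decay_rate, tick_interval)
  if (any(vals <= 0)) stop_mibci("all QuickTime parameters must be > 0")
  if (threshold < fill_rate)
    stop_mibci("threshold must be >= fill_rate")
  structure(list(window = window, threshold = threshold,
                 fill_rate = fill_rate, decay_rate = decay_rate,
                 tick_interval = tick_interval),
            class = "mi_quicktime")
}

#' Run one QuickTime trial
#'
#' @param decisions Ordered decision stream (class labels / `"neutral"`),
#'   at least one per tick of the window.
#' @param cue_class The cued class.
#' @param spec An `mi_quicktime`.
#' @return A list (`mi_trial`): `cue_class`, `success`, `bar_trajectory`
#'   (bar value after each tick), `ticks_used`.
#' @export
run_trial <- function(decisions, cue_class, spec = quicktime_spec()) {
  if (!length(decisions)) stop_mibci("empty decision stream")
  n_ticks <- min(length(decisions), floor(spec$window / spec$tick_interval))
  bar <- 0
  traj <- numeric(0)
  success <- FALSE
  ticks_used <- n_ticks
  for (k in seq_len(n_ticks)) {
    bar <- if (decisions[k] == cue_class) bar + spec$fill_rate else
      max(0, bar - spec$decay_rate)
    traj <- c(traj, bar)
    if (bar >= spec$threshold) {
      success <- TRUE
      ticks_used <- k
      break
    }
  }
  structure(list(cue_class = cue_class, success = success,
                 bar_trajectory = traj, ticks_used = ticks_used),
            class = "mi_trial")
}

#' Scripted decision source
#'
#' Emits the cued class with probability `accuracy`, otherwise a uniformly
#' random other class; used for decoder-free testing of the game loop.
#'
#' @param accuracy Per-tick probability of matching the cue.
#' @param classes Class universe.
#' @return A function `(cue_class, n_ticks) -> decisions` (seed it by
#'   wrapping the session call in a seeded context).
#' @export
scripted_decoder <- function(accuracy, classes = c("rest", "left_mi",
                                                   "right_mi")) {
  function(cue_class, n_ticks) {
    hit <- stats::runif(n_ticks) < accuracy
    other <- setdiff(classes, cue_class)
    alt <- sample(other, n_ticks, replace = TRUE)
    ifelse(hit, cue_class, alt)
  }
}

#' Run a full game session
#'
#' Runs one QuickTime trial per cue, aggregates per-class and overall
#' success rates, and tracks remaining health (one point lost per failed
#' jump).  Deterministic for a scripted decision source under a fixed
#' seed.
#'
#' @param decision_source Function `(cue_class, n_ticks) -> decisions`,
#'   e.g. [scripted_decoder()].
#' @param cue_schedule Character vector of cued classes, one per trial.
#' @param spec An `mi_quicktime`.
#' @param initial_health Starting health points.
#' @param seed Seed applied around the whole session.
#' @return A list (`mi_session`): `trials`, `per_class` (data.frame with
#'   counts and rates), `overall_rate`, `health_remaining`.
#' @export
run_session <- function(decision_source, cue_schedule,
                        spec = quicktime_spec(), initial_health = 3,
                        seed = 1) {
  if (!length(cue_schedule)) stop_mibci("empty cue schedule")
  with_seed(seed, {
    n_ticks <- floor(spec$window / spec$tick_interval)
    trials <- lapply(cue_schedule, function(cue)
      run_trial(decision_source(cue, n_ticks), cue, spec))
    succ <- vapply(trials, `[[`, TRUE, "success")
    per_class <- do.call(rbind, lapply(sort(unique(cue_schedule)),
                                       function(cl) {
      idx <- cue_schedule == cl
      data.frame(class = cl, trials = sum(idx), successes = sum(succ[idx]),
                 rate = mean(succ[idx]))
    }))
    rownames(per_class) <- NULL
    structure(list(trials = trials, per_class = per_class,
                   overall_rate = mean(succ),
                   successes = sum(succ), n_trials = length(succ),
                   health_remaining = initial_health - sum(!succ)),
              class = "mi_session")
  })
}

#' @export
print.mi_session <- function(x, ...) {
  cat(sprintf("<mi_session> %d/%d successful (%.1f%%), health %d\n",
              x$successes, x$n_trials, 100 * x$overall_rate,
              x$health_remaining))
  print(x$per_class)
  invisible(x)
}
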