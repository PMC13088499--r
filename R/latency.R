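#' Per-stage and total latency summary
#'
#' Stage deltas (preprocess - acquisition, classify - preprocess,
#' transfer - classify) and the total (transfer - acquisition), summarized
#' by median, p95 and p99 using the nearest-rank definition (the
#' `ceiling(p * n)`-th order statistic), in milliseconds.
#'
#' @param log A data.frame with columns `acquisition_t`, `preprocess_t`,
#'   `classify_t`, `transfer_t` (seconds on a monotonic clock), e.g. the
#'   `latency` element of [run_pipeline()].
#' @return A data.frame with one row per stage (and `total`) and columns
#'   `median_ms`, `p95_ms`, `p99_ms`, `n`.
#' @export
latency_summary <- function(log) {
  if (is.null(log) || !nrow(log)) stop_mibci("empty latency log")
  stages <- list(
    preprocess = log$preprocess_t - log$acquisition_t,
    classify = log$classify_t - log$preprocess_t,
    transfer = log$transfer_t - log$classify_t,
    total = log$transfer_t - log$acquisition_t
  )
  out <- do.call(rbind, lapply(names(stages), function(nm) {
    d <- stages[[nm]] * 1000
    data.frame(stage = nm,
               median_ms = nearest_rank(d, 0.5),
               p95_ms = nearest_rank(d, 0.95),
               p99_ms = nearest_rank(d, 0.99),
               n = length(d))
  }))
  rownames(out) <- NULL
  out
}

#' Wolpaw information transfer rate
#'
#' Bits per selection `B = log2(N) + P log2(P) +
#' (1 - P) log2((1 - P)/(N - 1))` with the convention `0 log2 0 = 0`,
#' scaled to bits per minute by the selection time.
#'
#' @param n_classes Number of classes `N` (>= 2).
#' @param accuracy Classification accuracy `P` in [0, 1].
#' @param seconds Time per selection `T` in seconds (> 0).
#' @return Bits per minute.
#' @export
#' @examples
#' compute_itr(3, 0.73, 1.617)   # ~17.6 bits/min
compute_itr <- function(n_classes, accuracy, seconds) {
  if (n_classes < 2) stop_mibci("n_classes must be >= 2")
  if (accuracy < 0 || accuracy > 1) stop_mibci("accuracy must lie in [0, 1]")
  if (seconds <= 0) stop_mibci("seconds must be > 0")
  xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)
  bits <- log2(n_classes) + xlog2(accuracy) +
    (1 - accuracy) * (if (accuracy < 1) log2((1 - accuracy) / (n_classes - 1))
                      else 0)
  bits * 60 / seconds
}

#' Write / summarize latency logs as JSON lines
#'
#' @param log Latency data.frame.
#' @param path Output path (`.jsonl`: one object per lineage).
#' @return `path` invisibly.
#' @export
write_latency_log <- function(log, path) {
  con <- file(path, "w"); on.exit(close(con), add = TRUE)
  for (i in seq_len(nrow(log))) {
    writeLines(jsonlite::toJSON(as.list(log[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_latency_log
#' @export
read_latency_log <- function(path) {
  rows <- lapply(readLines(path), function(l)
    as.data.frame(jsonlite::fromJSON(l)))
  do.call(rbind, rows)
}
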