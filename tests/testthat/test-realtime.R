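test_that("replay chunks are contiguous, gapless and exact", {
  rec <- generate_calibration(quiet_sim(3), 60)
  chunks <- replay(rec, chunk_ms = 100)
  expect_length(chunks, 600)
  expect_true(all(vapply(chunks, function(c) ncol(c$samples), 0L) == 25))
  glued <- do.call(cbind, lapply(chunks, `[[`, "samples"))
  expect_identical(unname(glued), unname(rec$data))
  expect_equal(chunks[[2]]$first_sample_time, 0.1)
  expect_error(replay(rec, chunk_ms = 0), "> 0")
})

test_that("bounded queues preserve order and drop the oldest on overflow", {
  q <- mibci:::queue_new(3)
  for (i in 1:5) q <- mibci:::queue_push(q, i)
  expect_equal(q$dropped, 2L)
  got <- c()
  repeat {
    r <- mibci:::queue_pop(q); q <- r$queue
    if (is.null(r$item)) break
    got <- c(got, r$item)
  }
  expect_equal(got, 3:5)
})

test_that("the rolling-buffer decision rule follows the stated update", {
  cfg <- transfer_config(buffer_len = 4)
  st <- transfer_state(cfg)
  # buffer full of one-hot class-1 vectors
  for (i in 1:4) { r <- transfer_update(st, c(1, 0, 0)); st <- r$state }
  expect_equal(r$decision, "rest")
  # uniform probabilities stay below the 0.5 thresholds
  st <- transfer_state(cfg)
  r <- transfer_update(st, rep(1 / 3, 3))
  expect_equal(r$decision, "neutral")
  # enumerated tie: two of class 1 then two of class 2 -> mean (.5, .5, 0),
  # tie broken toward the earliest class
  st <- transfer_state(cfg)
  for (p in list(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 1, 0))) {
    r <- transfer_update(st, p); st <- r$state
  }
  expect_equal(unname(r$mean), c(0.5, 0.5, 0))
  expect_equal(r$decision, "rest")
  # rolling: two more class-2 pushes evict the class-1 entries
  for (p in list(c(0, 1, 0), c(0, 1, 0))) { r <- transfer_update(st, p); st <- r$state }
  expect_equal(r$decision, "left_mi")
  expect_error(transfer_update(st, c(0.8, 0.1, 0.3)), "malformed")
  expect_error(transfer_update(st, c(0.5, 0.5)), "malformed")
})

test_that("binary accumulators fill, decay, clamp and fire", {
  cfg <- transfer_config(
    mapping = list(rest = list(), left_mi = list(x = -1, binary = "a"),
                   right_mi = list(x = 1)),
    binary_fill_rate = 0.25, binary_decay_rate = 0.25)
  st <- transfer_state(cfg)
  fired_at <- integer(0)
  for (i in 1:4) {
    r <- map_controls("left_mi", st); st <- r$state
    if (r$frame$a == 1) fired_at <- c(fired_at, i)
  }
  expect_equal(fired_at, 4L)                  # 4 x 0.25 -> fires on tick 4
  expect_equal(st$fills[["a"]], 0)            # reset after firing
  expect_equal(r$frame$x, -1)

  # alternating mapped/unmapped never fires
  st <- transfer_state(cfg)
  fired <- FALSE
  for (i in 1:40) {
    d <- if (i %% 2) "left_mi" else "rest"
    r <- map_controls(d, st); st <- r$state
    fired <- fired || r$frame$a == 1
  }
  expect_false(fired)

  # neutral forever: all-zero frames
  st <- transfer_state(cfg)
  for (i in 1:5) {
    r <- map_controls("neutral", st); st <- r$state
    expect_equal(unlist(r$frame[c("x", "y", "a", "b")]), c(x = 0, y = 0,
                                                           a = 0, b = 0))
  }
  expect_error(map_controls("jump", st), "unmapped")
})

test_that("latency summaries use the nearest-rank definition", {
  log <- data.frame(acquisition_t = (0:99) * 1,
                    preprocess_t = (0:99) * 1 + 0.010,
                    classify_t = (0:99) * 1 + 0.030,
                    transfer_t = (0:99) * 1 + 0.035)
  s <- latency_summary(log)
  expect_equal(s$median_ms[s$stage == "preprocess"], 10)
  expect_equal(s$median_ms[s$stage == "classify"], 20)
  expect_equal(s$median_ms[s$stage == "transfer"], 5)
  expect_equal(s$median_ms[s$stage == "total"], 35)

  set.seed(2)
  d <- runif(100)
  log2 <- data.frame(acquisition_t = 0, preprocess_t = d,
                     classify_t = d, transfer_t = d)
  s2 <- latency_summary(log2)
  expect_equal(s2$p95_ms[1], sort(d)[95] * 1000)
  expect_equal(s2$p99_ms[1], sort(d)[99] * 1000)

  single <- latency_summary(log[1, ])
  expect_equal(single$median_ms, single$p95_ms)
  expect_equal(single$p95_ms, single$p99_ms)
  expect_error(latency_summary(log[0, ]), "empty")
})

test_that("latency logs round-trip through JSON lines", {
  log <- data.frame(acquisition_t = c(0, 1), preprocess_t = c(0.01, 1.01),
                    classify_t = c(0.03, 1.02), transfer_t = c(0.04, 1.05))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_latency_log(log, path)
  expect_equal(read_latency_log(path), log)
})

test_that("the Wolpaw rate matches closed-form and information-theoretic checks", {
  expect_equal(compute_itr(3, 1 / 3, 1), 0, tolerance = 1e-12)
  expect_equal(compute_itr(3, 1.0, 60), log2(3), tolerance = 1e-12)
  expect_equal(compute_itr(2, 0.5, 1), 0, tolerance = 1e-12)
  # brute-force mutual information of the symmetric-confusion channel
  for (P in c(0.5, 0.73, 0.9)) {
    N <- 3
    joint <- matrix((1 - P) / (N - 1) / N, N, N)
    diag(joint) <- P / N
    py <- colSums(joint)
    mi <- sum(joint * log2(joint / (outer(rep(1 / N, N), py))))
    expect_equal(compute_itr(N, P, 60), mi, tolerance = 1e-10)
  }
  # continuity near the minimum, minimized at chance
  ps <- seq(0.2, 0.9, by = 0.01)
  bits <- sapply(ps, function(p) compute_itr(3, p, 60))
  expect_equal(ps[which.min(bits)], 1 / 3, tolerance = 0.01)
  expect_error(compute_itr(1, 0.5, 1), ">= 2")
  expect_error(compute_itr(3, 1.5, 1), "\\[0, 1\\]")
  expect_error(compute_itr(3, 0.5, 0), "> 0")
})

test_that("the chunked online pipeline reproduces the batch decoder", {
  sim <- sim_config(seed = 31, erd_depth = default_erd_depth())
  rec <- generate_recording(sim, paradigm_spec(trials_per_class = 2))
  rec$data <- rec$data[, seq_len(30 * 250)]          # 30 s slice
  cal <- generate_calibration(sim, 70)
  fl <- design_filter(filter_spec())
  cal_f <- crop_head(filter_recording(cal, fl), 10)
  asr <- fit_asr(cal_f)

  set.seed(77)
  arr <- array(rnorm(12 * 24 * 250), c(12, 24, 250))
  csp <- fit_csp(arr, rep(c("a", "b"), each = 6))
  mspec <- morlet_spec()
  model <- s4d_init(s4d_config(hidden_dim = 8, num_layers = 1, state_dim = 8),
                    n_features = 24 * 12 + 4, seed = 1)
  model$classes <- c("rest", "left_mi", "right_mi")
  cfg <- online_config(fl, asr, mspec, csp, model, window = 1, stride = 1)

  online <- run_pipeline(replay(rec, 100), cfg)
  batch <- decode_batch(rec, cfg)
  expect_equal(dim(online$probs), dim(batch$probs))
  expect_equal(online$window_starts, batch$window_starts)
  expect_lt(max(abs(online$probs - batch$probs)), 1e-5)
  expect_equal(online$dropped_chunks, 0L)

  # stamp monotonicity along every lineage
  lat <- online$latency
  expect_true(all(lat$preprocess_t >= lat$acquisition_t))
  expect_true(all(lat$classify_t >= lat$preprocess_t))
  expect_true(all(lat$transfer_t >= lat$classify_t))

  # control frames and feedback are emitted per window
  expect_equal(nrow(online$controls), nrow(online$probs))
  expect_length(online$feedback, nrow(online$probs))
})

test_that("a feature-specification mismatch refuses to start", {
  fl <- design_filter(filter_spec())
  sim <- sim_config(seed = 1)
  cal_f <- crop_head(filter_recording(generate_calibration(sim, 70), fl), 10)
  asr <- fit_asr(cal_f)
  set.seed(1)
  arr <- array(rnorm(8 * 24 * 250), c(8, 24, 250))
  csp <- fit_csp(arr, rep(c("a", "b"), each = 4))
  model <- s4d_init(s4d_config(hidden_dim = 4, num_layers = 1, state_dim = 4),
                    n_features = 292, seed = 1)
  model$feature_hash <- "something else"
  cfg <- online_config(fl, asr, morlet_spec(), csp, model)
  rec <- generate_calibration(sim, 35)
  expect_error(run_pipeline(replay(rec), cfg), "hash mismatch")
})

test_that("an empty stream shuts down cleanly", {
  fl <- design_filter(filter_spec())
  sim <- sim_config(seed = 1)
  cal_f <- crop_head(filter_recording(generate_calibration(sim, 70), fl), 10)
  asr <- fit_asr(cal_f)
  set.seed(1)
  arr <- array(rnorm(8 * 24 * 250), c(8, 24, 250))
  csp <- fit_csp(arr, rep(c("a", "b"), each = 4))
  model <- s4d_init(s4d_config(hidden_dim = 4, num_layers = 1, state_dim = 4),
                    n_features = 24 * 12 + 4, seed = 1)
  cfg <- online_config(fl, asr, morlet_spec(), csp, model)
  out <- run_pipeline(list(), cfg)
  expect_null(out$probs)
  expect_equal(out$dropped_chunks, 0L)
})
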