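test_that("identical configuration reproduces the recording bit for bit", {
  sim <- sim_config(seed = 7, erd_depth = default_erd_depth())
  par <- paradigm_spec(trials_per_class = 2)
  r1 <- generate_recording(sim, par)
  r2 <- generate_recording(sim, par)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$markers, r2$markers)
  c1 <- generate_calibration(sim, 35)
  c2 <- generate_calibration(sim, 35)
  expect_identical(c1$data, c2$data)
})

test_that("marker bookkeeping follows the paradigm timeline", {
  par <- paradigm_spec(trials_per_class = 10)
  rec <- generate_recording(quiet_sim(3), par)
  task <- rec$markers[grepl("/task$", rec$markers$label), ]
  expect_equal(nrow(task), 30)                       # trials x classes
  expect_equal(unique(diff(task$onset)), 7.0)        # cue + task + break
  cues <- rec$markers[!grepl("/task$", rec$markers$label), ]
  expect_true(all(cues$label %in% par$marker_vocabulary))
  # task onset is cue offset
  expect_equal(task$onset - cues$onset, rep(par$cue_duration, 30))
})

test_that("ERD attenuates oscillatory band power as (1 - depth)^2", {
  sim <- quiet_sim(5, background_amp = 0,
                   erd_depth = list(right_mi = c(C3 = 0.5)))
  rec <- generate_recording(sim, paradigm_spec(trials_per_class = 8))
  cls <- attr(rec, "classes")
  on <- rec$markers$onset[grepl("/task$", rec$markers$label)][cls == "right_mi"]
  p_task <- mean(sapply(on, function(t0)
    band_power(rec, "C3", c(8, 12), c(t0, t0 + 3))))
  p_break <- mean(sapply(on, function(t0)
    band_power(rec, "C3", c(8, 12), c(t0 - 4, t0 - 1))))
  expect_equal(p_task / p_break, 0.25, tolerance = 0.05)
})

test_that("band power during tasks decreases strictly with ERD depth", {
  powers <- sapply(c(0, 0.3, 0.6), function(d) {
    erd <- if (d > 0) list(right_mi = c(C3 = d)) else list()
    sim <- quiet_sim(5, background_amp = 0, erd_depth = erd)
    rec <- generate_recording(sim, paradigm_spec(trials_per_class = 4))
    cls <- attr(rec, "classes")
    on <- rec$markers$onset[grepl("/task$", rec$markers$label)][cls == "right_mi"]
    mean(sapply(on, function(t0) band_power(rec, "C3", c(8, 12), c(t0, t0 + 3))))
  })
  expect_true(all(diff(powers) < 0))
})

test_that("without ERD, task and break band powers are indistinguishable", {
  rec <- generate_recording(quiet_sim(11), paradigm_spec(trials_per_class = 14))
  on <- rec$markers$onset[grepl("/task$", rec$markers$label)]
  p_task <- sapply(on, function(t0) band_power(rec, "C3", c(8, 12), c(t0, t0 + 3)))
  p_break <- sapply(on, function(t0) band_power(rec, "C3", c(8, 12), c(t0 - 4, t0 - 1)))
  expect_gt(stats::t.test(p_task, p_break)$p.value, 0.01)
})

test_that("calibration is clean, sized by duration, and marker-free", {
  sim <- sim_config(seed = 9, blink_rate = 10)
  cal <- generate_calibration(sim, 60)
  expect_equal(ncol(cal$data), 60 * 250)
  expect_equal(nrow(cal$markers), 0)
  blinky <- generate_recording(sim, paradigm_spec(trials_per_class = 3))
  v_cal <- var(cal$data["Fp1", ])
  v_blink <- var(blinky$data["Fp1", seq_len(ncol(cal$data))])
  expect_lt(v_cal / v_blink, 0.8)
})

test_that("background spectrum follows the configured 1/f slope", {
  sim <- quiet_sim(13, alpha_amp = 0, beta_amp = 0)
  cal <- generate_calibration(sim, 60)
  x <- cal$data[1, ]
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * cal$fs / n
  sel <- f >= 4 & f <= 36
  slope <- unname(coef(stats::lm(log(p[sel]) ~ log(f[sel])))[2])
  expect_equal(slope, -1, tolerance = 0.3)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(fs = 60), "too low")
  expect_error(sim_config(erd_depth = list(left_mi = c(C3 = 1))), "\\[0, 1\\)")
  expect_error(sim_config(alpha_amp = -1), ">= 0")
  expect_error(paradigm_spec(cue_duration = 0), "> 0")
  expect_error(paradigm_spec(class_labels = "rest"), "2 classes")
  expect_error(generate_calibration(quiet_sim(1), duration = 0), "> 0")
})

test_that("band_power concentrates energy and validates its inputs", {
  fs <- 250
  t <- (0:(10 * fs - 1)) / fs
  data <- rbind(sin(2 * pi * 10 * t), 0 * t)
  rec <- raw_recording(data, fs, c("C3", "C4"))
  expect_gt(band_power(rec, "C3", c(8, 12)) / band_power(rec, "C3", c(20, 30)),
            100)
  expect_equal(band_power(rec, "C4", c(8, 12)), 0)
  expect_error(band_power(rec, "XX", c(8, 12)), "unknown channel")
  expect_error(band_power(rec, "C3", c(8, 12), c(3, 3)), "invalid interval")
  expect_error(band_power(rec, "C3", c(0, 500)), "fs/2")
})

test_that("white-noise power is flat across equal-width bands", {
  set.seed(4)
  rec <- raw_recording(matrix(rnorm(2 * 60 * 250), 2), 250, c("a", "b"))
  p1 <- band_power(rec, "a", c(10, 30))
  p2 <- band_power(rec, "a", c(50, 70))
  expect_equal(p1 / p2, 1, tolerance = 0.2)
})

test_that("EDF round-trips signals and sidecar markers", {
  rec <- generate_recording(quiet_sim(2), paradigm_spec(trials_per_class = 2))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$channel_names, rec$channel_names)
  expect_equal(back$fs, rec$fs)
  expect_equal(ncol(back$data), ncol(rec$data))
  # 16-bit quantization over the recording's dynamic range
  qstep <- (max(rec$data) - min(rec$data)) / 65535
  expect_lt(max(abs(back$data - rec$data)), qstep)
  expect_equal(back$markers$label, rec$markers$label)
  expect_equal(back$markers$onset, rec$markers$onset)
})
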