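fs <- 250

test_that("Morlet power peaks at the stimulus frequency with a^2/4 power", {
  t <- (0:749) / fs
  x <- array(0, c(1, 2, 750))
  x[1, 1, ] <- 3 * sin(2 * pi * 10 * t)
  ep <- mibci:::epoch_set(x, "a", 0, 0, 3, fs, c("C3", "C4"), "S1")
  pw <- morlet_power(ep)
  expect_equal(dim(pw), c(1, 2, 12, 250))            # 750 / decim 3
  prof <- apply(pw[1, 1, , 80:170], 1, mean)
  expect_equal(attr(pw, "freqs")[which.max(prof)], 10)
  expect_equal(max(prof), 9 / 4, tolerance = 0.01)   # (a/2)^2
  expect_true(all(pw[1, 2, , ] == 0))
})

test_that("Morlet power is sign-invariant and scales quadratically", {
  set.seed(6)
  x <- array(rnorm(2 * 1 * 400), c(2, 1, 400))
  ep <- mibci:::epoch_set(x, c("a", "a"), 1:2, 0, 1.6, fs, "C3", c("S1", "S1"))
  pw <- morlet_power(ep)
  neg <- ep; neg$epochs <- -neg$epochs
  expect_equal(morlet_power(neg), pw)
  dbl <- ep; dbl$epochs <- 2 * dbl$epochs
  expect_equal(morlet_power(dbl), 4 * pw, tolerance = 1e-12)
})

test_that("FFT-based Morlet power matches the direct convolution sum", {
  set.seed(8)
  x <- rnorm(300)
  spec <- morlet_spec(freqs = c(10, 20), decim = 1)
  pw <- morlet_power(matrix(x, 1), spec, fs = fs)
  for (fi in 1:2) {
    ref <- naive_morlet_power(x, spec$freqs[fi], fs, spec$n_cycles)
    expect_equal(pw[1, 1, fi, ], ref, tolerance = 1e-10)
  }
})

test_that("epochs shorter than the wavelet support are rejected", {
  x <- array(rnorm(1 * 1 * 50), c(1, 1, 50))
  ep <- mibci:::epoch_set(x, "a", 1, 0, 0.2, fs, "C3", "S1")
  expect_error(morlet_power(ep), "too short")
})

test_that("CSP recovers the axis-aligned two-class structure", {
  set.seed(2)
  arr <- array(0, c(40, 2, 64))
  arr[1:20, , ] <- trials_with_cov(diag(c(2, 1)), 20, 64)
  arr[21:40, , ] <- trials_with_cov(diag(c(1, 2)), 20, 64)
  m <- fit_csp(arr, rep(c("A", "B"), each = 20))
  expect_equal(sort(unique(round(m$eigenvalues, 6))), c(1 / 3, 2 / 3),
               tolerance = 1e-6)
  # filters align with the coordinate axes
  for (i in seq_len(nrow(m$filters))) {
    w <- abs(m$filters[i, ]) / max(abs(m$filters[i, ]))
    expect_lt(sort(w)[1], 1e-6)
  }
})

test_that("CSP filters match the brute-force generalized eigenproblem", {
  set.seed(5)
  for (rep_ in 1:4) {
    ch <- 5
    mk_spd <- function() {
      M <- matrix(rnorm(ch * ch), ch)
      crossprod(M) + diag(ch) * 0.1
    }
    Sa <- mk_spd(); Sb <- mk_spd()
    arr <- array(0, c(8, ch, 40))
    arr[1:4, , ] <- trials_with_cov(Sa, 4, 40)
    arr[5:8, , ] <- trials_with_cov(Sb, 4, 40)
    m <- fit_csp(arr, rep(c("A", "B"), each = 4))
    # the trace normalization rescales class covariances; reproduce it
    Sa_n <- Sa / sum(diag(Sa)); Sb_n <- Sb / sum(diag(Sb))
    oracle <- brute_csp(Sa_n, Sb_n)
    w_top <- m$filters[1, ]; w_bot <- m$filters[2, ]
    align <- function(w, v) abs(sum(w * v)) / sqrt(sum(w^2) * sum(v^2))
    expect_equal(align(w_top, oracle$vectors[, 1]), 1, tolerance = 1e-8)
    expect_equal(align(w_bot, oracle$vectors[, ch]), 1, tolerance = 1e-8)
    expect_equal(m$eigenvalues[1], oracle$values[1], tolerance = 1e-8)
    expect_equal(m$eigenvalues[2], oracle$values[ch], tolerance = 1e-8)
  }
})

test_that("identical class covariances give eigenvalue 1/2 everywhere", {
  set.seed(9)
  arr <- array(0, c(12, 3, 60))
  S <- diag(3)
  arr[1:6, , ] <- trials_with_cov(S, 6, 60)
  arr[7:12, , ] <- trials_with_cov(S, 6, 60)
  m <- fit_csp(arr, rep(c("A", "B"), each = 6))
  expect_equal(m$eigenvalues, rep(0.5, 4), tolerance = 1e-8)
})

test_that("CSP preconditions and feature transforms behave", {
  arr <- array(rnorm(3 * 2 * 50), c(3, 2, 50))
  expect_error(fit_csp(arr, c("A", "A", "B")), ">= 2 trials")
  set.seed(1)
  arr <- array(rnorm(8 * 3 * 100), c(8, 3, 100))
  m <- fit_csp(arr, rep(c("A", "B"), each = 4))
  f1 <- csp_features(arr[1, , ], m)
  expect_equal(dim(f1), c(1, 4))
  expect_equal(as.vector(csp_features(2 * arr[1, , ], m) - f1),
               rep(log(4), 4), tolerance = 1e-12)
  expect_error(csp_features(matrix(0, 5, 50), m), "channels")
  fz <- csp_features(matrix(0, 3, 50), m)
  expect_true(all(fz == log(1e-12)))
  expect_equal(attr(fz, "floored"), 4)
})

test_that("white noise through near-orthonormal filters gives ~log(sigma^2)", {
  set.seed(12)
  arr <- array(rnorm(10 * 4 * 2000, sd = 2), c(10, 4, 2000))
  m <- fit_csp(arr, rep(c("A", "B"), each = 5))
  # trace-normalized class covariances are ~I/4, so the composite is ~I/2
  # and the metric constraint w' St w = 1 gives |w|^2 ~ 2: projected
  # variance ~ sigma^2 * 2 = 8
  f <- csp_features(arr[1, , ], m)
  expect_equal(as.vector(f), rep(log(8), 4), tolerance = 0.15)
})

test_that("window counts follow trials x windows_per_epoch", {
  for (cnt in c(190L, 720L)) {
    arr <- array(0, c(cnt, 2, 750))
    ep <- mibci:::epoch_set(arr, rep(c("a", "b"), length.out = cnt),
                            seq_len(cnt), 0, 3, fs, c("C3", "C4"),
                            rep("S1", cnt))
    w <- sliding_windows(ep, window = 1, windows_per_epoch = 4)
    expect_equal(n_epochs(w), cnt * 4L)
    expect_equal(dim(w$epochs)[3], 250)
  }
  # stride for 3 s epochs is 2/3 s
  ep <- mibci:::epoch_set(array(0, c(1, 2, 750)), "a", 1, 0, 3, fs,
                          c("C3", "C4"), "S1")
  w <- sliding_windows(ep)
  expect_equal(w$offsets_s, c(0, 167, 333, 500) / 250)
  w1 <- sliding_windows(ep, window = 3, windows_per_epoch = 1)
  expect_equal(n_epochs(w1), 1)
  expect_equal(w1$offsets_s, 0)
  expect_error(sliding_windows(ep, window = 4), "shorter")
})

test_that("stacking yields the documented feature-channel counts", {
  n_win <- 6
  pw <- array(abs(rnorm(n_win * 24 * 12 * 84)), c(n_win, 24, 12, 84))
  cf <- matrix(rnorm(n_win * 6), n_win, 6)
  both <- stack_features(pw, cf, labels = rep("a", n_win))
  expect_equal(dim(both$x), c(n_win, 294, 84))
  expect_equal(dim(stack_features(pw, NULL, rep("a", n_win))$x),
               c(n_win, 288, 84))
  csp_only <- stack_features(NULL, cf, rep("a", n_win))
  expect_equal(dim(csp_only$x)[2], 6)
  # CSP values are constant along time
  expect_equal(both$x[2, 289, 1], both$x[2, 289, 84])
  expect_error(stack_features(pw, cf[1:3, ], rep("a", n_win)), "mismatch")
})

test_that("the stratified split is reproducible, balanced and leak-free", {
  n_tr <- 190
  labels <- rep(c("rest", "left", "right"), length.out = n_tr)
  src <- seq_len(n_tr)
  wl <- rep(labels, each = 4)
  ws <- rep(src, each = 4)
  ft <- list(labels = wl, source_trial = ws)
  sp <- stratified_split(ft, seed = 3)
  expect_equal(length(sp$train) + length(sp$test), 760)
  # per-class train fraction within one trial's worth of windows of 80%
  for (cl in unique(labels)) {
    n_cl <- sum(wl == cl)
    expect_lte(abs(sum(wl[sp$train] == cl) - 0.8 * n_cl), 4)
  }
  expect_identical(stratified_split(ft, seed = 3), sp)
  expect_false(identical(stratified_split(ft, seed = 4), sp))
  expect_length(intersect(ws[sp$train], ws[sp$test]), 0)
  expect_error(stratified_split(list(labels = rep("a", 20),
                                     source_trial = 1:20)),
               "class")
})

test_that("ERDS reports the (1-d)^2 - 1 percentage change", {
  sim <- quiet_sim(5, background_amp = 0,
                   erd_depth = list(right_mi = c(C3 = 0.5)))
  rec <- generate_recording(sim, paradigm_spec(trials_per_class = 4))
  eps <- epoch(rec, c(cue_right_mi = "right_mi"), tmin = -2, tmax = 3)
  em <- erds(eps, baseline = c(-2, -1))
  i_c3 <- match("C3", eps$channel_names)
  times <- attr(em, "times")
  alpha_rows <- attr(em, "freqs") %in% c(10)
  task_cells <- mean(em[i_c3, alpha_rows, times > 0.5 & times < 2.5])
  expect_equal(task_cells, -75, tolerance = 3)
  # an unmodulated channel stays near zero
  i_oz <- match("Oz", eps$channel_names)
  expect_lt(abs(mean(em[i_oz, alpha_rows, times > 0.5 & times < 2.5])), 5)
  expect_error(erds(eps, baseline = c(-5, -4)), "inside the epoch")
})
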