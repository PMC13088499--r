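# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational paths: the recurrence is a literal state
# update loop, the CSP oracle a direct generalized eigenproblem, the
# Morlet oracle a direct time-domain convolution sum.

# Impulse response of the diagonal state-space recurrence
# x_l = exp(dt A) x_{l-1} + Bbar u_l, y_l = 2 Re(C x_l), stepped naively.
naive_s4d_kernel <- function(kp, L) {
  dm <- dim(kp$a_im)
  A <- matrix(complex(real = -exp(kp$log_neg_a_re), imaginary = kp$a_im),
              dm[1], dm[2])
  B <- matrix(complex(real = kp$b_re, imaginary = kp$b_im), dm[1], dm[2])
  C <- matrix(complex(real = kp$c_re, imaginary = kp$c_im), dm[1], dm[2])
  dt <- exp(kp$log_dt)
  K <- matrix(0, dm[1], L)
  for (ch in seq_len(dm[1])) {
    E <- exp(dt[ch] * A[ch, ])
    Bb <- (E - 1) / A[ch, ] * B[ch, ]
    x <- rep(0 + 0i, dm[2])
    u <- c(1, rep(0, L - 1))
    for (l in seq_len(L)) {
      x <- E * x + Bb * u[l]
      K[ch, l] <- 2 * Re(sum(C[ch, ] * x))
    }
  }
  K
}

# Generalized eigenvectors of (Sc, Sc + Sr) via the plain (non-symmetric)
# eigenproblem solve(St) %*% Sc, normalized so v' St v = 1.
brute_csp <- function(Sc, Sr) {
  St <- Sc + Sr
  eg <- eigen(solve(St) %*% Sc)
  ord <- order(Re(eg$values), decreasing = TRUE)
  vals <- Re(eg$values)[ord]
  vecs <- Re(eg$vectors)[, ord, drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    vecs[, j] <- vecs[, j] / sqrt(drop(t(vecs[, j]) %*% St %*% vecs[, j]))
  }
  list(values = vals, vectors = vecs)
}

# Trials whose per-trial covariance equals S exactly: rows of Z are
# orthogonal with norm sqrt(n), so (LZ)(LZ)' = n * S.
trials_with_cov <- function(S, n_trials, n_samples) {
  ch <- nrow(S)
  L <- t(chol(S))
  arr <- array(0, c(n_trials, ch, n_samples))
  for (k in seq_len(n_trials)) {
    Q <- qr.Q(qr(matrix(stats::rnorm(n_samples * ch), n_samples, ch)))
    arr[k, , ] <- L %*% (t(Q) * sqrt(n_samples))
  }
  arr
}

# Direct time-domain Morlet convolution (same-length, zero-padded edges).
naive_morlet_power <- function(x, f, fs, n_cycles) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(5 * sigma_t * fs)
  t <- (-half:half) / fs
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w <- w / sum(Mod(w))
  n <- length(x)
  y <- complex(n)
  for (i in seq_len(n)) {
    idx <- i - (-half:half)
    ok <- idx >= 1 & idx <= n
    y[i] <- sum(w[ok] * x[idx[ok]])
  }
  Mod(y)^2
}

quiet_sim <- function(seed = 1, ...) {
  sim_config(seed = seed, blink_rate = 0, muscle_rate = 0, line_amp = 0, ...)
}

default_mapping <- function(paradigm) {
  stats::setNames(paradigm$class_labels,
                  paradigm$marker_vocabulary[paradigm$class_labels])
}
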