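# S4D network: parameter construction, forward pass with caches, and
# reverse-mode gradients.  Arrays are kept as (channels, time, batch); the
# FFT convolutions flatten to (time, channels*batch) matrices for mvfft.

#' Initialize a full S4D model
#'
#' @param config An `mi_s4dconfig`.
#' @param n_features Input feature-channel count.
#' @param seed Integer seed for the random parameters.
#' @return An object of class `mi_s4d` holding `config`, `n_features` and
#'   the parameter list.
#' @export
s4d_init <- function(config, n_features, seed = 1) {
  stopifnot(inherits(config, "mi_s4dconfig"))
  with_seed(seed, {
    h <- config$hidden_dim
    cin <- if (config$bidirectional) 2L * h else h
    layers <- lapply(seq_len(config$num_layers), function(l) {
      lay <- list(
        ln_gamma = rep(1, h), ln_beta = rep(0, h),
        fwd = init_kernel(h, config$state_dim),
        out_w = matrix(stats::rnorm(2 * h * cin, sd = 1 / sqrt(cin)),
                       2 * h, cin),
        out_b = rep(0, 2 * h)
      )
      if (config$bidirectional) lay$bwd <- init_kernel(h, config$state_dim)
      lay
    })
    params <- list(
      w_in = matrix(stats::rnorm(h * n_features, sd = 1 / sqrt(n_features)),
                    h, n_features),
      b_in = rep(0, h),
      layers = layers,
      w_head = matrix(stats::rnorm(config$num_classes * h, sd = 1 / sqrt(h)),
                      config$num_classes, h),
      b_head = rep(0, config$num_classes)
    )
    structure(list(config = config, n_features = as.integer(n_features),
                   params = params, classes = NULL, feature_hash = NULL),
              class = "mi_s4d")
  })
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)
sigmoid <- function(x) 1 / (1 + exp(-x))

# Causal FFT convolution of U (h, L, B) with per-channel kernels K (h, L),
# zero-padded to >= 2L and truncated back to L (linear, causal).
conv_causal <- function(U, Kf_fft, n2) {
  h <- dim(U)[1]; L <- dim(U)[2]; B <- dim(U)[3]
  Um <- matrix(0, n2, h * B)
  Um[seq_len(L), ] <- matrix(aperm(U, c(2, 1, 3)), L, h * B)
  Uf <- stats::mvfft(Um)
  Y <- Re(stats::mvfft(Uf * Kf_fft[, rep(seq_len(h), B), drop = FALSE],
                       inverse = TRUE)) / n2
  aperm(array(Y[seq_len(L), , drop = FALSE], c(L, h, B)), c(2, 1, 3))
}

# Correlation (adjoint of conv_causal in its first argument): same layout.
corr_anticausal <- function(dY, Kf_fft, n2) {
  h <- dim(dY)[1]; L <- dim(dY)[2]; B <- dim(dY)[3]
  Dm <- matrix(0, n2, h * B)
  Dm[seq_len(L), ] <- matrix(aperm(dY, c(2, 1, 3)), L, h * B)
  Df <- stats::mvfft(Dm)
  X <- Re(stats::mvfft(Df * Conj(Kf_fft[, rep(seq_len(h), B), drop = FALSE]),
                       inverse = TRUE)) / n2
  aperm(array(X[seq_len(L), , drop = FALSE], c(L, h, B)), c(2, 1, 3))
}

# Kernel gradient: dK[h, m] = sum_{b, l} dY[h, l, b] * U[h, l - m, b].
conv_kernel_grad <- function(dY, U, n2) {
  h <- dim(dY)[1]; L <- dim(dY)[2]; B <- dim(dY)[3]
  Dm <- matrix(0, n2, h * B); Um <- matrix(0, n2, h * B)
  Dm[seq_len(L), ] <- matrix(aperm(dY, c(2, 1, 3)), L, h * B)
  Um[seq_len(L), ] <- matrix(aperm(U, c(2, 1, 3)), L, h * B)
  G <- Re(stats::mvfft(stats::mvfft(Dm) * Conj(stats::mvfft(Um)),
                       inverse = TRUE)) / n2
  # sum over batch: columns h + (b-1)*h share a channel
  gk <- matrix(0, h, L)
  for (b in seq_len(B)) {
    gk <- gk + t(G[seq_len(L), (b - 1) * h + seq_len(h), drop = FALSE])
  }
  gk
}

rev_time <- function(X) X[, rev(seq_len(dim(X)[2])), , drop = FALSE]

#' Forward pass of the S4D classifier
#'
#' @param model An `mi_s4d`.
#' @param x Input array: features x time, or features x time x batch.
#' @param training Apply dropout (stochastic pass) and keep caches.
#' @param want_cache Keep intermediate activations for the backward pass.
#' @return A list with `logits` (classes x batch), `probs` (softmax
#'   columns), and `cache` when requested.
#' @export
s4d_forward <- function(model, x, training = FALSE, want_cache = FALSE) {
  cfg <- model$config; p <- model$params
  if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1))
  if (dim(x)[1] != model$n_features)
    stop_mibci("input has %d feature channels, model expects %d",
               dim(x)[1], model$n_features)
  if (!is.null(model$feature_scale)) {
    x <- (x - model$feature_scale$mean) / model$feature_scale$sd
  }
  L <- dim(x)[2]; B <- dim(x)[3]; h <- cfg$hidden_dim
  n2 <- stats::nextn(2 * L, 2)
  cache <- list(x = x, L = L, B = B, n2 = n2, layers = vector("list",
                                                             cfg$num_layers))

  Xm <- p$w_in %*% matrix(x, model$n_features, L * B) + p$b_in
  X <- array(Xm, c(h, L, B))

  for (li in seq_len(cfg$num_layers)) {
    lay <- p$layers[[li]]
    lc <- list()
    # pre-layer-norm over channels at every (t, b)
    Xf <- matrix(X, h, L * B)
    mu <- colMeans(Xf)
    xc <- sweep(Xf, 2, mu)
    sdv <- sqrt(colMeans(xc^2) + 1e-5)
    xhat <- sweep(xc, 2, sdv, "/")
    U <- array(lay$ln_gamma * xhat + lay$ln_beta, c(h, L, B))
    lc$xhat <- xhat; lc$sdv <- sdv; lc$U <- U; lc$X_in <- X

    Kf <- compute_kernel(lay$fwd, L, want_cache = want_cache)
    Kf_fft <- stats::mvfft(rbind(t(Kf), matrix(0, n2 - L, h)))
    Yf <- conv_causal(U, Kf_fft, n2) + lay$fwd$d_skip * array(U, c(h, L, B))
    lc$Kf <- Kf; lc$Kf_fft <- Kf_fft
    if (cfg$bidirectional) {
      Kb <- compute_kernel(lay$bwd, L, want_cache = want_cache)
      Kb_fft <- stats::mvfft(rbind(t(Kb), matrix(0, n2 - L, h)))
      Ur <- rev_time(U)
      Yb <- rev_time(conv_causal(Ur, Kb_fft, n2)) +
        lay$bwd$d_skip * array(U, c(h, L, B))
      lc$Kb <- Kb; lc$Kb_fft <- Kb_fft; lc$Ur <- Ur
      Ycat <- array(0, c(2 * h, L, B))
      Ycat[seq_len(h), , ] <- Yf
      Ycat[h + seq_len(h), , ] <- Yb
    } else {
      Ycat <- Yf
    }
    lc$Ycat <- Ycat

    G <- gelu(Ycat)
    if (training && cfg$dropout_rate > 0) {
      mask <- array(stats::rbinom(length(G), 1, 1 - cfg$dropout_rate),
                    dim(G)) / (1 - cfg$dropout_rate)
      G <- G * mask
      lc$mask <- mask
    }
    lc$G <- G

    V <- lay$out_w %*% matrix(G, dim(G)[1], L * B) + lay$out_b
    val <- V[seq_len(h), , drop = FALSE]
    gate <- V[h + seq_len(h), , drop = FALSE]
    sg <- sigmoid(gate)
    O <- array(val * sg, c(h, L, B))
    lc$val <- val; lc$sg <- sg
    X <- X + O
    cache$layers[[li]] <- lc
  }

  pooled <- apply(X, c(1, 3), mean)                    # h x B
  pooled <- matrix(pooled, h, B)
  logits <- p$w_head %*% pooled + p$b_head
  lm <- apply(logits, 2, max)
  el <- exp(sweep(logits, 2, lm))
  probs <- sweep(el, 2, colSums(el), "/")
  cache$pooled <- pooled; cache$X_final <- X
  out <- list(logits = logits, probs = probs)
  if (want_cache) out$cache <- cache
  out
}

# Reverse-mode gradients of mean cross-entropy w.r.t. all parameters.
# `y` is an integer class index per batch column (1-based).
s4d_backward <- function(model, fw, y) {
  cfg <- model$config; p <- model$params
  cache <- fw$cache
  L <- cache$L; B <- cache$B; h <- cfg$hidden_dim; n2 <- cache$n2
  probs <- fw$probs
  dlogits <- probs
  dlogits[cbind(y, seq_len(B))] <- dlogits[cbind(y, seq_len(B))] - 1
  dlogits <- dlogits / B

  g <- list(w_head = dlogits %*% t(cache$pooled),
            b_head = rowSums(dlogits),
            layers = vector("list", cfg$num_layers))
  dpooled <- t(p$w_head) %*% dlogits                    # h x B
  dX <- array(0, c(h, L, B))
  for (b in seq_len(B)) dX[, , b] <- matrix(dpooled[, b], h, L) / L

  for (li in rev(seq_len(cfg$num_layers))) {
    lay <- p$layers[[li]]; lc <- cache$layers[[li]]
    dO <- dX                                           # residual branch
    dOm <- matrix(dO, h, L * B)
    dval <- dOm * lc$sg
    dgate <- dOm * lc$val * lc$sg * (1 - lc$sg)
    dV <- rbind(dval, dgate)
    Gm <- matrix(lc$G, dim(lc$G)[1], L * B)
    gl <- list(out_w = dV %*% t(Gm), out_b = rowSums(dV))
    dG <- array(t(lay$out_w) %*% dV, dim(lc$G))
    if (!is.null(lc$mask)) dG <- dG * lc$mask
    dYcat <- dG * gelu_grad(lc$Ycat)

    if (cfg$bidirectional) {
      dYf <- dYcat[seq_len(h), , , drop = FALSE]
      dYb <- dYcat[h + seq_len(h), , , drop = FALSE]
    } else {
      dYf <- dYcat
      dYb <- NULL
    }
    dU <- corr_anticausal(dYf, lc$Kf_fft, n2) + lay$fwd$d_skip * dYf
    dKf <- conv_kernel_grad(dYf, lc$U, n2)
    gl$fwd <- kernel_backward(lay$fwd, lc$Kf, dKf)
    gl$fwd$d_skip <- apply(dYf * lc$U, 1, sum)
    if (cfg$bidirectional) {
      dYb_r <- rev_time(dYb)
      dU <- dU + rev_time(corr_anticausal(dYb_r, lc$Kb_fft, n2)) +
        lay$bwd$d_skip * dYb
      dKb <- conv_kernel_grad(dYb_r, lc$Ur, n2)
      gl$bwd <- kernel_backward(lay$bwd, lc$Kb, dKb)
      gl$bwd$d_skip <- apply(dYb * lc$U, 1, sum)
    }

    dUm <- matrix(dU, h, L * B)
    gl$ln_gamma <- rowSums(dUm * lc$xhat)
    gl$ln_beta <- rowSums(dUm)
    dxhat <- dUm * lay$ln_gamma
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * lc$xhat)
    dXf <- sweep(dxhat, 2, m1) - sweep(lc$xhat, 2, m2, "*")
    dXf <- sweep(dXf, 2, lc$sdv, "/")
    dX <- dX + array(dXf, c(h, L, B))
    g$layers[[li]] <- gl
  }

  xin <- matrix(cache$x, model$n_features, L * B)
  dXin <- matrix(dX, h, L * B)
  g$w_in <- dXin %*% t(xin)
  g$b_in <- rowSums(dXin)
  g
}
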