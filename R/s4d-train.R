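#' Training configuration for the S4D classifier
#'
#' Cross-entropy objective under Adam, with the state-space parameters
#' (`A`, `dt`) in a reduced-learning-rate group without weight decay, as is
#' standard for structured state-space models.  Early stopping monitors
#' validation accuracy.
#'
#' @param learning_rate Adam step size for network parameters.
#' @param ssm_learning_rate Step size for `A` and `dt` reparameterizations.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param early_stopping_patience Epochs without validation improvement
#'   before stopping.
#' @param seed Seed for shuffling, dropout and initialization.
#' @return An object of class `mi_trainconfig`.
#' @export
train_config <- function(learning_rate = 1e-3, ssm_learning_rate = 1e-4,
                         batch_size = 32, max_epochs = 60,
                         early_stopping_patience = 8, seed = 1) {
  if (learning_rate <= 0 || ssm_learning_rate <= 0)
    stop_mibci("learning rates must be > 0")
  if (early_stopping_patience < 1) stop_mibci("patience must be >= 1")
  structure(list(learning_rate = learning_rate,
                 ssm_learning_rate = ssm_learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 seed = as.integer(seed)),
            class = "mi_trainconfig")
}

ssm_param_names <- c("log_neg_a_re", "a_im", "log_dt")

tree_zero <- function(p) {
  if (is.list(p)) lapply(p, tree_zero) else 0 * p
}

adam_step <- function(params, grads, state, t, cfg,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v, name) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]], nm)
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    lr <- if (name %in% ssm_param_names) cfg$ssm_learning_rate else
      cfg$learning_rate
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk(params, grads, state$m, state$v, "")
}

#' Train the S4D classifier
#'
#' Minimizes mean cross-entropy with Adam; stops early when validation
#' accuracy has not improved for `early_stopping_patience` epochs and
#' restores the best-scoring parameters.  Fully seeded: a fixed
#' `mi_trainconfig` reproduces the run.
#'
#' @param model An `mi_s4d` from [s4d_init()].
#' @param x_train,x_val Arrays features x time x windows.
#' @param y_train,y_val Class label per window.
#' @param cfg An `mi_trainconfig`.
#' @return The trained `mi_s4d` with `classes` set and a `history`
#'   data.frame (epoch, train_loss, val_acc) attached.
#' @export
s4d_train <- function(model, x_train, y_train, x_val, y_val,
                      cfg = train_config()) {
  classes <- sort(unique(c(y_train, y_val)))
  if (!all(classes %in% unique(y_train)))
    stop_mibci("class '%s' missing from the training set",
               setdiff(classes, unique(y_train))[1])
  if (length(classes) != model$config$num_classes)
    stop_mibci("%d classes in data, model configured for %d",
               length(classes), model$config$num_classes)
  yi_train <- match(y_train, classes)
  yi_val <- match(y_val, classes)
  n <- dim(x_train)[3]

  # per-feature-channel standardization, estimated on the training set and
  # stored with the checkpoint (applied inside every forward pass)
  if (is.null(model$feature_scale)) {
    mu <- apply(x_train, 1, mean)
    sdv <- pmax(apply(x_train, 1, stats::sd), 1e-8)
    model$feature_scale <- list(mean = mu, sd = sdv)
  }

  with_seed(cfg$seed, {
    state <- list(m = tree_zero(model$params), v = tree_zero(model$params))
    best <- list(acc = -Inf, params = model$params, epoch = 0L)
    history <- NULL
    t_step <- 0L
    for (ep in seq_len(cfg$max_epochs)) {
      perm <- sample(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- perm[start:min(n, start + cfg$batch_size - 1)]
        xb <- x_train[, , idx, drop = FALSE]
        yb <- yi_train[idx]
        fw <- s4d_forward(model, xb, training = TRUE, want_cache = TRUE)
        pr <- pmax(fw$probs[cbind(yb, seq_along(yb))], 1e-12)
        losses <- c(losses, -mean(log(pr)))
        gr <- s4d_backward(model, fw, yb)
        t_step <- t_step + 1L
        upd <- adam_step(model$params, gr, state, t_step, cfg)
        model$params <- upd$p
        state$m <- upd$m; state$v <- upd$v
      }
      val_pred <- s4d_predict(model, x_val)$class_index
      val_acc <- mean(val_pred == yi_val)
      history <- rbind(history,
                       data.frame(epoch = ep, train_loss = mean(losses),
                                  val_acc = val_acc))
      if (val_acc > best$acc + 1e-12) {
        best <- list(acc = val_acc, params = model$params, epoch = ep)
      } else if (ep - best$epoch >= cfg$early_stopping_patience) {
        break
      }
    }
    model$params <- best$params
    model$classes <- classes
    model$history <- history
    model$train_config <- cfg
    model
  })
}

#' Deterministic prediction
#'
#' @param model A trained `mi_s4d`.
#' @param x Features x time (x windows) array.
#' @return List with `probs` (classes x windows), `class_index`, and
#'   `class` labels when the model knows them.
#' @export
s4d_predict <- function(model, x) {
  fw <- s4d_forward(model, x, training = FALSE)
  ci <- apply(fw$probs, 2, which.max)
  list(probs = fw$probs, class_index = ci,
       class = if (!is.null(model$classes)) model$classes[ci] else NULL)
}

#' Monte-Carlo-dropout prediction with uncertainty
#'
#' Runs `n_passes` stochastic forward passes with dropout active and
#' reports the mean class probabilities, their standard deviation across
#' passes, and the predictive entropy of the mean distribution.
#'
#' @param model A trained `mi_s4d`.
#' @param x Features x time (x windows) array.
#' @param n_passes Number of stochastic passes (>= 1).
#' @param seed Seed for the dropout masks.
#' @return A list with `mc_mean`, `mc_sd` (classes x windows),
#'   `predictive_entropy` (per window), `n_passes`.
#' @export
mc_dropout_predict <- function(model, x, n_passes = 20, seed = 1) {
  if (n_passes < 1) stop_mibci("n_passes must be >= 1")
  with_seed(seed, {
    runs <- lapply(seq_len(n_passes), function(i)
      s4d_forward(model, x, training = TRUE)$probs)
    arr <- simplify2array(runs)                 # classes x windows x passes
    if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
    mc_mean <- apply(arr, c(1, 2), mean)
    mc_sd <- apply(arr, c(1, 2), stats::sd)
    if (n_passes == 1) mc_sd[] <- 0
    ent <- apply(mc_mean, 2, function(q) -sum(ifelse(q > 0, q * log2(q), 0)))
    list(mc_mean = mc_mean, mc_sd = mc_sd, predictive_entropy = ent,
         n_passes = n_passes)
  })
}

#' Save / load an S4D checkpoint
#'
#' The checkpoint stores the configuration, parameters, class labels,
#' training history and the feature-specification hash used to guard the
#' online pipeline against mismatched feature configurations.
#'
#' @param model An `mi_s4d`.
#' @param path File path.
#' @return `s4d_save`: `path` invisibly.  `s4d_load`: the `mi_s4d`.
#' @export
s4d_save <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname s4d_save
#' @export
s4d_load <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "mi_s4d"))
  model
}

#' Fingerprint of a feature configuration
#'
#' A plain, human-readable digest of everything that determines the feature
#' tensor layout; the online pipeline refuses to start when the model's
#' stored hash differs.
#'
#' @param morlet An `mi_morletspec` (or `NULL`).
#' @param csp A fitted `mi_csp` (or `NULL`).
#' @param n_channels EEG channel count.
#' @param window Window length in seconds.
#' @param fs Sampling rate.
#' @return A character scalar.
#' @export
feature_spec_hash <- function(morlet, csp, n_channels, window, fs) {
  paste(
    "morlet", if (is.null(morlet)) "none" else
      paste(c(morlet$freqs, morlet$n_cycles, morlet$decim), collapse = ","),
    "csp", if (is.null(csp)) "none" else
      paste(dim(csp$filters), collapse = "x"),
    "ch", n_channels, "win", window, "fs", fs, sep = ":")
}
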