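#' Fit common spatial patterns (one-vs-rest)
#'
#' For each class, spatial filters are the generalized eigenvectors of the
#' pair (class covariance, class + rest covariance); the filters belonging
#' to the largest and smallest eigenvalue are kept (2 per class, 6 total
#' for 3 classes).  Per-trial covariances are trace-normalized before
#' averaging; no shrinkage/regularization is applied.
#'
#' @param epochs An `mi_epochs` (or trials x channels x samples array with
#'   `labels` supplied).
#' @param labels Class label per trial (taken from the epochs when omitted).
#' @param components_per_class Filters kept per class (split evenly between
#'   the top and bottom of the eigenvalue spectrum).
#' @param rank_deficient `"error"` signals rank deficiency (the default:
#'   common-average referencing reduces the data rank by one, which must be
#'   handled deliberately); `"subspace"` whitens within the non-degenerate
#'   principal subspace instead, the standard remedy after re-referencing.
#' @return An object of class `mi_csp` with `filters` (components x
#'   channels), `eigenvalues`, `classes`.  Serializable with `saveRDS` for
#'   online reuse.
#' @export
fit_csp <- function(epochs, labels = NULL, components_per_class = 2,
                    rank_deficient = c("error", "subspace")) {
  rank_deficient <- match.arg(rank_deficient)
  if (inherits(epochs, "mi_epochs")) {
    labels <- labels %||% epochs$labels
    x <- epochs$epochs
  } else {
    x <- epochs
    if (is.null(labels)) stop_mibci("labels required for array input")
  }
  classes <- sort(unique(labels))
  counts <- table(labels)
  if (any(counts < 2))
    stop_mibci("need >= 2 trials per class; class '%s' has %d",
               names(counts)[which.min(counts)], min(counts))
  n_ch <- dim(x)[2]

  class_cov <- lapply(classes, function(cl) {
    idx <- which(labels == cl)
    covs <- lapply(idx, function(k) {
      m <- x[k, , ]
      cc <- tcrossprod(m)
      cc / sum(diag(cc))
    })
    Reduce(`+`, covs) / length(covs)
  })
  names(class_cov) <- classes

  filters <- NULL
  eigvals <- numeric(0)
  filter_class <- character(0)
  half <- components_per_class / 2
  for (cl in classes) {
    Sc <- class_cov[[cl]]
    Sr <- Reduce(`+`, class_cov[setdiff(classes, cl)]) /
      (length(classes) - 1)
    St <- Sc + Sr
    eg <- eigen(St, symmetric = TRUE)
    ok <- eg$values > 1e-10 * max(eg$values)
    if (!all(ok) && rank_deficient == "error")
      stop_mibci(paste0("singular composite covariance (rank deficiency; ",
                        "common-average referencing reduces rank by one - ",
                        "drop one channel or use rank_deficient = ",
                        "\"subspace\")"))
    if (sum(ok) < components_per_class)
      stop_mibci("composite covariance rank too low for CSP")
    P <- eg$vectors[, ok, drop = FALSE] %*% diag(1 / sqrt(eg$values[ok]))
    M <- crossprod(P, Sc %*% P)                 # rank x rank
    M <- (M + t(M)) / 2
    em <- eigen(M, symmetric = TRUE)
    r <- sum(ok)
    pick <- c(seq_len(ceiling(half)), r - seq_len(floor(half)) + 1L)
    W <- t(P %*% em$vectors[, pick, drop = FALSE])
    filters <- rbind(filters, W)
    eigvals <- c(eigvals, em$values[pick])
    filter_class <- c(filter_class, rep(cl, length(pick)))
  }
  structure(list(filters = filters, eigenvalues = eigvals,
                 filter_class = filter_class, classes = classes,
                 components_per_class = components_per_class,
                 n_channels = n_ch, log_transform = TRUE),
            class = "mi_csp")
}

#' CSP log-variance features
#'
#' Projects each item onto the fitted spatial filters and returns the log
#' of the projected variance, one value per filter.  Zero-variance
#' projections are floored at `log(1e-12)` and flagged.
#'
#' @param x An `mi_epochs`, a trials x channels x samples array, or a
#'   single channels x samples matrix.
#' @param model A fitted `mi_csp`.
#' @return Matrix items x n_filters; attribute `floored` counts floored
#'   cells.
#' @export
csp_features <- function(x, model) {
  stopifnot(inherits(model, "mi_csp"))
  if (inherits(x, "mi_epochs")) x <- x$epochs
  if (is.matrix(x)) x <- array(x, c(1, dim(x)))
  if (dim(x)[2] != model$n_channels)
    stop_mibci("item has %d channels, CSP model expects %d",
               dim(x)[2], model$n_channels)
  n_items <- dim(x)[1]
  out <- matrix(0, n_items, nrow(model$filters))
  for (k in seq_len(n_items)) {
    proj <- model$filters %*% x[k, , ]
    out[k, ] <- apply(proj, 1, stats::var)
  }
  floored <- out < 1e-12
  out[floored] <- 1e-12
  out <- log(out)
  attr(out, "floored") <- sum(floored)
  out
}
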