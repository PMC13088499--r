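#' Classical machine-learning baseline harness
#'
#' Fits the standard baseline classifiers (SVM, random forest, AdaBoost,
#' k-NN, MLP) on flattened feature vectors under a given train/test split
#' and tabulates test accuracy.  SVM, random forest, k-NN and the MLP use
#' e1071, randomForest, class and nnet; AdaBoost (multi-class SAMME over
#' decision stumps) is implemented here since no AdaBoost package is
#' available.
#'
#' @param features An `mi_features` (windows x feature_channels x time;
#'   flattened per window) or a windows x features matrix.
#' @param labels Class label per window (taken from `mi_features` when
#'   omitted).
#' @param split List with `train` and `test` index vectors, e.g. from
#'   [stratified_split()].
#' @param seed Seed for the stochastic learners.
#' @param models Subset of `c("svm", "random_forest", "adaboost", "knn",
#'   "mlp")`.
#' @return A data.frame with columns `model` and `accuracy`.
#' @export
baseline_suite <- function(features, labels = NULL, split, seed = 1,
                           models = c("svm", "random_forest", "adaboost",
                                      "knn", "mlp")) {
  if (inherits(features, "mi_features")) {
    labels <- labels %||% features$labels
    x <- matrix(features$x, dim(features$x)[1],
                dim(features$x)[2] * dim(features$x)[3])
  } else {
    x <- as.matrix(features)
    if (is.null(labels)) stop_mibci("labels required for matrix input")
  }
  y <- factor(labels)
  if (length(unique(y[split$train])) < 2)
    stop_mibci("degenerate split: training set has a single class")
  xtr <- x[split$train, , drop = FALSE]; ytr <- y[split$train]
  xte <- x[split$test, , drop = FALSE]; yte <- y[split$test]
  # drop constant columns (zero variance breaks scaling in some learners)
  keep <- apply(xtr, 2, stats::sd) > 1e-12
  xtr <- xtr[, keep, drop = FALSE]; xte <- xte[, keep, drop = FALSE]

  acc <- function(pred) mean(as.character(pred) == as.character(yte))
  out <- NULL
  with_seed(seed, {
    for (mdl in models) {
      a <- switch(
        mdl,
        svm = acc(stats::predict(e1071::svm(xtr, ytr), xte)),
        random_forest = acc(stats::predict(
          randomForest::randomForest(xtr, ytr, ntree = 200), xte)),
        adaboost = acc(adaboost_predict(
          adaboost_fit(xtr, ytr, n_rounds = 40), xte)),
        knn = acc(class::knn(xtr, xte, ytr, k = 5)),
        mlp = {
          sc <- scale(xtr)
          ctr <- attr(sc, "scaled:center"); scl <- attr(sc, "scaled:scale")
          fit <- nnet::nnet(sc, stats::model.matrix(~ ytr - 1), size = 16,
                            softmax = TRUE, maxit = 200, trace = FALSE,
                            MaxNWts = 1e6, decay = 1e-3)
          pr <- stats::predict(fit, scale(xte, ctr, scl), type = "class")
          acc(sub("^ytr", "", pr))
        },
        stop_mibci("unknown baseline '%s'", mdl))
      out <- rbind(out, data.frame(model = mdl, accuracy = a))
    }
  })
  rownames(out) <- NULL
  out
}

# Multi-class AdaBoost (SAMME) over rpart stumps.
adaboost_fit <- function(x, y, n_rounds = 40) {
  n <- nrow(x); k <- nlevels(y)
  w <- rep(1 / n, n)
  df <- data.frame(y = y, x)
  learners <- list(); alphas <- numeric(0)
  for (r in seq_len(n_rounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w,
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = 0, minsplit = 2,
                                                       xval = 0))
    pred <- stats::predict(fit, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- log((1 - err) / err) + log(k - 1)
    if (alpha <= 0) break
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    learners[[length(learners) + 1]] <- fit
    alphas <- c(alphas, alpha)
  }
  list(learners = learners, alphas = alphas, levels = levels(y))
}

adaboost_predict <- function(model, x) {
  df <- data.frame(x)
  votes <- matrix(0, nrow(x), length(model$levels),
                  dimnames = list(NULL, model$levels))
  for (i in seq_along(model$learners)) {
    pred <- stats::predict(model$learners[[i]], df, type = "class")
    idx <- cbind(seq_len(nrow(x)), match(as.character(pred), model$levels))
    votes[idx] <- votes[idx] + model$alphas[i]
  }
  factor(model$levels[max.col(votes, ties.method = "first")],
         levels = model$levels)
}
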