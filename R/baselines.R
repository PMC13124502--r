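# Classical baseline classifiers on the PCA feature scores (sequence axis
# collapsed by mean). Fixed, documented hyperparameters; deterministic
# given the seed.

#' Train a baseline classifier
#'
#' @param kind one of "svm" (RBF, C = 1, gamma = 1/k), "rf" (500 trees),
#'   "knn" (k = 5), "xgb" (300 rounds, depth 4, eta 0.1).
#' @param X n x k numeric matrix (PCA scores, sequence-mean collapsed).
#' @param y class labels (factor or character).
#' @param seed RNG seed (tree bootstraps, tie-breaking).
#' @return `baseline_model` list.
#' @export
train_baseline <- function(kind = c("svm", "rf", "knn", "xgb"), X, y,
                           seed = 1L) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  colnames(X) <- paste0("PC", seq_len(ncol(X)))
  y <- factor(y)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (nlevels(y) == 1) {
    return(structure(list(kind = "constant", fit = levels(y),
                          levels = levels(y), seed = seed),
                     class = "baseline_model"))
  }
  fit <- switch(kind,
    svm = e1071::svm(X, y, kernel = "radial", cost = 1,
                     gamma = 1 / ncol(X), scale = FALSE),
    rf = randomForest::randomForest(X, y, ntree = 500),
    knn = list(X = X, y = y, k = 5),
    xgb = xgboost::xgboost(
      x = X, y = y, objective = "multi:softprob", nrounds = 300,
      max_depth = 4, learning_rate = 0.1, nthreads = 1, verbosity = 0)
  )
  structure(list(kind = kind, fit = fit, levels = levels(y), seed = seed),
            class = "baseline_model")
}

#' Predict with a baseline classifier
#'
#' @param model a [train_baseline()] model.
#' @param X n x k matrix.
#' @return factor of predicted classes (levels as in training).
#' @export
predict_baseline <- function(model, X) {
  X <- as.matrix(X)
  colnames(X) <- paste0("PC", seq_len(ncol(X)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(model$seed)
  pred <- switch(model$kind,
    constant = rep(model$fit, nrow(X)),
    svm = stats::predict(model$fit, X),
    rf = stats::predict(model$fit, X),
    knn = class::knn(model$fit$X, X, model$fit$y, k = model$fit$k),
    xgb = stats::predict(model$fit, X, type = "class"))
  factor(as.character(pred), levels = model$levels)
}
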