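# PCA dimensionality reduction at the 90% cumulative-variance criterion.

#' Fit a PCA model
#'
#' Eigendecomposition of the covariance matrix `C = X_c' X_c / (n-1)` of
#' the mean-centered data. The retained dimension `k` is the smallest
#' number of leading components whose cumulative explained variance reaches
#' `var_threshold`. Eigenvector signs are fixed so that each column's
#' largest-magnitude entry is positive.
#'
#' @param X n x p numeric matrix (rows = observations); callers are
#'   expected to standardize columns on training statistics beforehand.
#' @param var_threshold cumulative-variance criterion (default 0.90).
#' @return `pca_model` list: `means`, `eigenvalues` (descending), `W`
#'   (p x p orthonormal), `W_k` (p x k), `k`, `cumvar` (length p),
#'   `cumvar_k`.
#' @export
fit_pca <- function(X, var_threshold = 0.90) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2, all(is.finite(X)))
  means <- colMeans(X)
  Xc <- sweep(X, 2, means)
  C <- crossprod(Xc) / (nrow(X) - 1)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  W <- e$vectors
  for (j in seq_len(ncol(W))) {
    if (W[which.max(abs(W[, j])), j] < 0) W[, j] <- -W[, j]
  }
  total <- sum(vals)
  cumvar <- if (total > 0) cumsum(vals) / total else rep(1, length(vals))
  k <- which(cumvar >= var_threshold)[1]
  structure(list(means = means, eigenvalues = vals, W = W,
                 W_k = W[, seq_len(k), drop = FALSE], k = k,
                 cumvar = cumvar, cumvar_k = cumvar[k]),
            class = "pca_model")
}

#' Project data onto retained principal components
#'
#' `Z = (X - means) W_k`.
#'
#' @param model a [fit_pca()] model.
#' @param X n x p matrix (or a single length-p vector).
#' @return n x k score matrix.
#' @export
transform_pca <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  stopifnot(ncol(X) == length(model$means))
  sweep(as.matrix(X), 2, model$means) %*% model$W_k
}
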