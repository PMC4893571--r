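#' Fit an SVD-based PCA model
#'
#' Principal component analysis by singular value decomposition of the
#' (column-mean-centered) data matrix. The loadings are the leading
#' right singular vectors; if the s variables obey m exact linear
#' relations, the last m singular values are zero, and projecting onto
#' the first k loadings discards directions dominated by noise.
#'
#' @param x N x s numeric data matrix (rows = samplings).
#' @param k Number of components to retain, `0 <= k <= min(N, s)`
#'   (k = 0 yields an empty basis, useful as a baseline).
#' @param center Subtract column means before the SVD (default `TRUE`).
#' @return Object of class `pca_model`: `mean` (s-vector), `loadings`
#'   (s x k orthonormal matrix), `singular_values` (descending),
#'   `k`, `center`.
#' @export
fit_pca <- function(x, k, center = TRUE) {
  stopifnot(is.matrix(x), nrow(x) >= 1, ncol(x) >= 1)
  k <- as.integer(k)
  if (k < 0L || k > min(dim(x))) {
    stop("k must be in 0..min(N, s) = ", min(dim(x)))
  }
  mu <- if (center) colMeans(x) else rep(0, ncol(x))
  xc <- sweep(x, 2, mu)
  if (k == 0L) {
    return(structure(list(mean = mu, loadings = matrix(0, ncol(x), 0),
                          singular_values = numeric(0), k = 0L,
                          center = center),
                     class = "pca_model"))
  }
  sv <- svd(xc, nu = 0, nv = k)
  structure(list(mean = mu, loadings = sv$v[, seq_len(k), drop = FALSE],
                 singular_values = sv$d[seq_len(k)],
                 k = k, center = center),
            class = "pca_model")
}

#' Project data onto a fitted PCA basis
#'
#' Scores are r_i(t) = (x(t) - mean) . q_i for each retained loading
#' q_i.
#'
#' @param object A `pca_model`.
#' @param newdata N x s matrix with the same variables the model was
#'   fitted on.
#' @param ... Unused.
#' @return N x k score matrix.
#' @export
predict.pca_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(object$mean)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$mean))
  }
  sweep(newdata, 2, object$mean) %*% object$loadings
}

#' PCA reconstruction error
#'
#' Frobenius norm of the residual E = X_centered - sum_i r_i q_i', the
#' part of the data not captured by the retained components. Zero when
#' k reaches the rank of the centered data; non-increasing in k.
#'
#' @inheritParams predict.pca_model
#' @param x Data matrix to reconstruct.
#' @return Non-negative scalar.
#' @export
reconstruction_error <- function(object, x) {
  scores <- predict(object, x)
  xc <- sweep(x, 2, object$mean)
  resid <- xc - scores %*% t(object$loadings)
  sqrt(sum(resid^2))
}
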