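#' Gaussian kernel matrix
#'
#' K(x, x') = exp(-||x - x'||^2 / (2 width^2)) between the rows of two
#' matrices (the default `form = "bandwidth"`). `form = "gamma"`
#' instead uses exp(-width ||x - x'||^2), the parameterization common
#' in SVM software.
#'
#' @param x,y Numeric matrices with matching column counts.
#' @param width Positive kernel width.
#' @param form `"bandwidth"` (default) or `"gamma"`; see above.
#' @return `nrow(x)` x `nrow(y)` kernel matrix.
#' @export
gaussian_kernel <- function(x, y = x, width = 0.6,
                            form = c("bandwidth", "gamma")) {
  form <- match.arg(form)
  stopifnot(width > 0, ncol(x) == ncol(y))
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  if (form == "bandwidth") exp(-d2 / (2 * width^2)) else exp(-width * d2)
}

#' RVM design matrix
#'
#' The N x (N + 1) basis matrix Phi of the relevance vector machine: a
#' leading column of ones (the bias w0) followed by the Gaussian kernel
#' evaluated between every pair of training points, Phi\[i, j + 1\] =
#' K(x_i, x_j).
#'
#' @param x N x d training feature matrix.
#' @inheritParams gaussian_kernel
#' @return N x (N + 1) numeric matrix.
#' @export
build_design_matrix <- function(x, width = 0.6,
                                form = c("bandwidth", "gamma")) {
  cbind(1, gaussian_kernel(x, x, width, form))
}

#' Posterior over RVM weights
#'
#' Given the Gaussian likelihood t = Phi w + noise with noise variance
#' sigma2 and the zero-mean Gaussian prior with precision diag(alpha)
#' on the weights, the posterior over w is Gaussian with
#' Sigma = (sigma2^-1 Phi'Phi + diag(alpha))^-1 and
#' mu = sigma2^-1 Sigma Phi' t.
#'
#' @param phi N x m design matrix (m basis functions).
#' @param t N-vector of targets (class labels 0/1 under the regression
#'   formulation).
#' @param alpha m-vector of positive prior precisions.
#' @param sigma2 Positive noise variance.
#' @return List with `mu` (m-vector) and `Sigma` (m x m symmetric
#'   positive-definite matrix).
#' @export
rvm_posterior <- function(phi, t, alpha, sigma2) {
  stopifnot(length(alpha) == ncol(phi), all(alpha > 0), sigma2 > 0,
            length(t) == nrow(phi))
  h <- crossprod(phi) / sigma2 + diag(alpha, ncol(phi))
  ch <- tryCatch(chol(h), error = function(e) NULL)
  if (is.null(ch)) {
    warning("ill-conditioned posterior precision; adding jitter")
    ch <- chol(h + diag(1e-8 * max(diag(h)), ncol(phi)))
  }
  sigma <- chol2inv(ch)
  mu <- drop(sigma %*% crossprod(phi, t)) / sigma2
  list(mu = mu, Sigma = sigma)
}

#' Evidence-maximization hyperparameter update
#'
#' One fixed-point step of type-II maximum likelihood: for each basis
#' function, gamma_i = 1 - alpha_i Sigma_ii (the fraction of weight i
#' "well determined" by the data), then alpha_i <- gamma_i / mu_i^2 and
#' sigma2 <- ||t - Phi mu||^2 / (N - sum(gamma)). A weight with mu_i = 0
#' is sent to the pruning ceiling `alpha_max`.
#'
#' @inheritParams rvm_posterior
#' @param mu,Sigma Posterior mean and covariance from
#'   [rvm_posterior()].
#' @param alpha_max Ceiling treated as an infinite precision.
#' @param sigma2_floor Lower clamp on the noise-variance update.
#' @return List with `alpha`, `sigma2`, `gamma`.
#' @export
rvm_update_hyperparameters <- function(mu, Sigma, t, phi, alpha,
                                       alpha_max = 1e12,
                                       sigma2_floor = 1e-12) {
  gamma <- 1 - alpha * diag(Sigma)
  alpha_new <- ifelse(mu == 0, alpha_max, gamma / mu^2)
  alpha_new[!is.finite(alpha_new) | alpha_new > alpha_max] <- alpha_max
  alpha_new[alpha_new <= 0] <- alpha_max  # numerically negative gamma
  n <- nrow(phi)
  denom <- n - sum(gamma)
  resid2 <- sum((t - drop(phi %*% mu))^2)
  sigma2_new <- if (denom > 0) max(resid2 / denom, sigma2_floor) else sigma2_floor
  list(alpha = alpha_new, sigma2 = sigma2_new, gamma = gamma)
}

#' Fit a relevance vector machine classifier
#'
#' Sparse Bayesian learning on binary labels treated as regression
#' targets (Gaussian noise, no logistic link), the decision rule being
#' score >= 0.5. Starting from alpha_i = 1/N^2 for every basis function
#' (bias included), the fit alternates the weight posterior with the
#' evidence fixed-point update of the hyperparameters; basis functions
#' whose precision alpha_i crosses `alpha_max` are pruned. The training
#' points whose kernel columns survive are the relevance vectors.
#'
#' @param x N x d feature matrix.
#' @param t N-vector of labels in \{0, 1\}, both classes present.
#' @param width,form Gaussian kernel parameters; see
#'   [gaussian_kernel()]. Default width 0.6.
#' @param max_iter Maximum fixed-point iterations (default 500).
#' @param tol Convergence tolerance on max |delta log alpha| (default
#'   1e-3).
#' @param alpha_max Pruning ceiling on alpha (default 1e12).
#' @param sigma2 Initial noise variance; default `0.1 * var(t)`.
#' @param sigma2_floor Lower clamp on sigma2 (default 1e-12).
#' @return Object of class `rvm`: relevance vectors and their indices,
#'   posterior mean `mu` and covariance `Sigma` over the retained
#'   weights, `alpha`, `sigma2`, kernel config, `bias_retained`,
#'   iteration count and convergence flag.
#' @export
rvm_fit <- function(x, t, width = 0.6, form = c("bandwidth", "gamma"),
                    max_iter = 500, tol = 1e-3, alpha_max = 1e12,
                    sigma2 = NULL, sigma2_floor = 1e-12) {
  form <- match.arg(form)
  x <- as.matrix(x)
  t <- as.numeric(t)
  if (!all(t %in% c(0, 1))) stop("labels must be 0 or 1")
  if (length(unique(t)) < 2) stop("both classes must be present")
  n <- nrow(x)
  phi_full <- build_design_matrix(x, width, form)
  active <- seq_len(n + 1L)           # 1 = bias, j + 1 = kernel on x_j
  alpha <- rep(1 / n^2, n + 1L)
  if (is.null(sigma2)) sigma2 <- max(0.1 * stats::var(t), sigma2_floor)
  converged <- FALSE
  iter <- 0L
  post <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    phi <- phi_full[, active, drop = FALSE]
    post <- rvm_posterior(phi, t, alpha[active], sigma2)
    upd <- rvm_update_hyperparameters(post$mu, post$Sigma, t, phi,
                                      alpha[active], alpha_max,
                                      sigma2_floor)
    delta <- max(abs(log(upd$alpha) - log(alpha[active])))
    alpha[active] <- upd$alpha
    sigma2 <- upd$sigma2
    keep <- upd$alpha < alpha_max
    if (!any(keep)) {
      stop("all basis functions pruned; try a larger width or tol")
    }
    if (!all(keep)) {
      active <- active[keep]
      next  # re-evaluate posterior on the reduced basis before testing
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  phi <- phi_full[, active, drop = FALSE]
  post <- rvm_posterior(phi, t, alpha[active], sigma2)
  bias_retained <- 1L %in% active
  rv_index <- setdiff(active, 1L) - 1L
  structure(list(
    relevance_vectors = x[rv_index, , drop = FALSE],
    rv_index = rv_index,
    mu = post$mu, Sigma = post$Sigma,
    alpha = alpha[active], sigma2 = sigma2,
    kernel = list(width = width, form = form),
    bias_retained = bias_retained,
    n_train = n, d = ncol(x),
    iterations = iter, converged = converged
  ), class = "rvm")
}

#' Predict with a fitted RVM
#'
#' Scores are y(x) = sum_j mu_j K(x, rv_j) + mu_0 over the retained
#' relevance vectors (the bias term is absent if it was pruned); the
#' predicted label is 1 when y >= 0.5.
#'
#' @param object A fitted `rvm`.
#' @param newdata Feature matrix with the training dimensionality.
#' @param ... Unused.
#' @return List with numeric `score` and integer `label` vectors.
#' @export
predict.rvm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) {
    return(list(score = numeric(0), label = integer(0)))
  }
  if (ncol(newdata) != object$d) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         object$d)
  }
  w <- object$mu
  score <- numeric(nrow(newdata))
  if (object$bias_retained) {
    score <- score + w[[1]]
    w <- w[-1]
  }
  if (nrow(object$relevance_vectors)) {
    k <- gaussian_kernel(newdata, object$relevance_vectors,
                         object$kernel$width, object$kernel$form)
    score <- score + drop(k %*% w)
  }
  list(score = score, label = as.integer(score >= 0.5))
}

#' @export
print.rvm <- function(x, ...) {
  cat("Relevance vector machine (regression-on-labels form)\n")
  cat(sprintf("  training points: %d  relevance vectors: %d  bias: %s\n",
              x$n_train, nrow(x$relevance_vectors),
              if (x$bias_retained) "retained" else "pruned"))
  cat(sprintf("  kernel: gaussian width=%g (%s)  sigma2=%.4g\n",
              x$kernel$width, x$kernel$form, x$sigma2))
  cat(sprintf("  iterations: %d (%s)\n", x$iterations,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}
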