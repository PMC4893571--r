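test_that("design matrix matches the pairwise-kernel oracle", {
  set.seed(31)
  x <- matrix(rnorm(15), 5, 3)
  phi <- build_design_matrix(x, width = 0.6)
  expect_equal(dim(phi), c(5, 6))
  expect_equal(phi[, 1], rep(1, 5))
  for (i in 1:5) for (j in 1:5) {
    expect_equal(phi[i, j + 1],
                 exp(-sum((x[i, ] - x[j, ])^2) / (2 * 0.6^2)),
                 tolerance = 1e-12)
  }
  expect_equal(diag(phi[, -1]), rep(1, 5))  # zero distance -> K = 1
  # alternative gamma parameterization
  phig <- build_design_matrix(x, width = 2, form = "gamma")
  expect_equal(phig[1, 3], exp(-2 * sum((x[1, ] - x[2, ])^2)),
               tolerance = 1e-12)
})

test_that("posterior matches a dense linear-algebra oracle", {
  # N = 1 hand instance: Phi = [1 1], t = 1, alpha = (1,1), sigma2 = 1
  p <- rvm_posterior(matrix(c(1, 1), 1, 2), 1, c(1, 1), 1)
  h <- matrix(c(2, 1, 1, 2), 2, 2)  # Phi'Phi + I
  expect_equal(p$Sigma, solve(h), tolerance = 1e-12)
  expect_equal(p$mu, drop(solve(h) %*% c(1, 1)), tolerance = 1e-12)

  # random N = 6 instance vs independent dense solve
  set.seed(32)
  x <- matrix(rnorm(12), 6, 2)
  t <- c(0, 1, 0, 1, 1, 0)
  phi <- build_design_matrix(x)
  alpha <- rexp(7) + 0.1
  s2 <- 0.3
  p <- rvm_posterior(phi, t, alpha, s2)
  sigma_oracle <- solve(crossprod(phi) / s2 + diag(alpha))
  expect_equal(p$Sigma, sigma_oracle, tolerance = 1e-8)
  expect_equal(p$mu, drop(sigma_oracle %*% t(phi) %*% t) / s2,
               tolerance = 1e-8)
  # Sigma symmetric positive-definite
  expect_equal(p$Sigma, t(p$Sigma), tolerance = 1e-10)
  expect_gt(min(eigen(p$Sigma, symmetric = TRUE)$values), 0)
})

test_that("huge prior precision shrinks the posterior mean to zero", {
  set.seed(33)
  x <- matrix(rnorm(10), 5, 2)
  phi <- build_design_matrix(x)
  p <- rvm_posterior(phi, c(1, 0, 1, 0, 1), rep(1e12, 6), 1)
  expect_lt(max(abs(p$mu)), 1e-6)
})

test_that("hyperparameter update applies the fixed-point formulas", {
  # gamma_i = 1 - alpha_i Sigma_ii: 1 - 2 * 0.1 = 0.8
  # alpha_new = gamma / mu^2: 0.8 / 4 = 0.2
  mu <- c(2, 1)
  sigma <- diag(c(0.1, 0.25))
  phi <- matrix(c(1, 1, 0.5, 0.2), 2, 2)
  t <- c(1, 0)
  upd <- rvm_update_hyperparameters(mu, sigma, t, phi, alpha = c(2, 2))
  expect_equal(upd$gamma, c(0.8, 0.5))
  expect_equal(upd$alpha[1], 0.2)
  expect_equal(upd$alpha[2], 0.5 / 1)
  # sigma2 = ||t - Phi mu||^2 / (N - sum(gamma))
  expect_equal(upd$sigma2, sum((t - phi %*% mu)^2) / (2 - 1.3))
  # perfect fit -> residual zero -> clamped at the floor
  upd0 <- rvm_update_hyperparameters(mu, sigma, drop(phi %*% mu),
                                     phi, alpha = c(2, 2))
  expect_equal(upd0$sigma2, 1e-12)
  # zero weight is sent to the pruning ceiling
  updz <- rvm_update_hyperparameters(c(0, 1), sigma, t, phi, c(2, 2),
                                     alpha_max = 1e12)
  expect_equal(updz$alpha[1], 1e12)
})

test_that("one full fit iteration reproduces the hand-executed update", {
  set.seed(34)
  x <- matrix(rnorm(12), 6, 2)
  t <- c(1, 0, 1, 0, 1, 0)
  phi <- build_design_matrix(x, width = 0.6)
  n <- 6
  alpha0 <- rep(1 / n^2, n + 1)
  s20 <- max(0.1 * var(t), 1e-12)
  # hand-executed step
  sig <- solve(crossprod(phi) / s20 + diag(alpha0))
  mu <- drop(sig %*% t(phi) %*% t) / s20
  gam <- 1 - alpha0 * diag(sig)
  alpha1 <- gam / mu^2
  s21 <- sum((t - phi %*% mu)^2) / (n - sum(gam))
  m <- rvm_fit(x, t, width = 0.6, max_iter = 1)
  expect_equal(m$alpha, alpha1, tolerance = 1e-8)
  expect_equal(m$sigma2, s21, tolerance = 1e-8)
})

test_that("RVM separates Gaussian blobs sparsely and predicts held-out data", {
  blobs <- make_blobs(n = 100, d = 2, sep = 3, seed = 35)
  m <- rvm_fit(blobs$x, blobs$y)
  pred <- predict(m, blobs$x)
  expect_gte(mean(pred$label == blobs$y), 0.95)
  # sparsity: far fewer relevance vectors than training points
  expect_lt(nrow(m$relevance_vectors), 100 / 2)
  # held-out set from the same distribution, new seed
  test <- make_blobs(n = 200, d = 2, sep = 3, seed = 36)
  pred_te <- predict(m, test$x)
  expect_gte(mean(pred_te$label == test$y), 0.9)
  # log-alpha converged within tolerance
  expect_true(m$converged)
  expect_true(all(is.finite(m$alpha) & m$alpha > 0))
})

test_that("decision function is invariant to training-row permutation", {
  blobs <- make_blobs(n = 60, d = 2, sep = 3, seed = 37)
  m1 <- rvm_fit(blobs$x, blobs$y)
  perm <- withr::with_seed(38, sample.int(60))
  m2 <- rvm_fit(blobs$x[perm, ], blobs$y[perm])
  grid <- as.matrix(expand.grid(seq(-3, 6, length.out = 7),
                                seq(-3, 3, length.out = 7)))
  expect_equal(predict(m1, grid)$score, predict(m2, grid)$score,
               tolerance = 1e-6)
})

test_that("prediction contracts: empty input, dimension check, threshold", {
  blobs <- make_blobs(n = 40, seed = 39)
  m <- rvm_fit(blobs$x, blobs$y)
  empty <- predict(m, blobs$x[0, , drop = FALSE])
  expect_length(empty$score, 0)
  expect_length(empty$label, 0)
  expect_error(predict(m, matrix(0, 2, 5)), "columns")
  pred <- predict(m, blobs$x)
  expect_identical(pred$label, as.integer(pred$score >= 0.5))
})

test_that("degenerate training sets are rejected", {
  expect_error(rvm_fit(matrix(rnorm(10), 5, 2), c(1, 1, 1, 1, 1)),
               "both classes")
  expect_error(rvm_fit(matrix(rnorm(10), 5, 2), c(1, 0, 2, 0, 1)),
               "0 or 1")
})
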