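# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity.

# Direct double-sum STFT: F(u, x) = sum_{y in N_x} f(x - y) e^{-2i pi y'u}
# over the centered (2r+1) x (2r+1) window, valid positions only.
brute_stft <- function(mat, u, r) {
  n <- nrow(mat); m <- ncol(mat)
  out <- matrix(0i, n - 2 * r, m - 2 * r)
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      ci <- i + r; cj <- j + r
      s <- 0i
      for (dy in -r:r) {
        for (dx in -r:r) {
          s <- s + mat[ci - dy, cj - dx] *
            exp(-2i * pi * (dy * u[[1]] + dx * u[[2]]))
        }
      }
      out[i, j] <- s
    }
  }
  out
}

brute_lpq_codes <- function(mat, a, r) {
  freqs <- list(c(a, 0), c(0, a), c(a, a), c(a, -a))
  planes <- lapply(freqs, function(u) brute_stft(mat, u, r))
  comps <- c(lapply(planes, Re), lapply(planes, Im))
  code <- matrix(0L, nrow(planes[[1]]), ncol(planes[[1]]))
  for (j in seq_along(comps)) {
    code <- code + as.integer(comps[[j]] >= 0) * 2L^(j - 1L)
  }
  code
}

# 2-D "valid" convolution with a centrally symmetric kernel, used for
# the blur-invariance checks.
conv2_valid <- function(mat, kernel) {
  kr <- (nrow(kernel) - 1) %/% 2
  n <- nrow(mat) - 2 * kr; m <- ncol(mat) - 2 * kr
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      out[i, j] <- sum(mat[i:(i + 2 * kr), j:(j + 2 * kr)] *
                         kernel[nrow(kernel):1, ncol(kernel):1])
    }
  }
  out
}

gaussian_blur_kernel <- function(sigma = 0.8, radius = 2) {
  g <- outer(-radius:radius, -radius:radius,
             function(y, x) exp(-(x^2 + y^2) / (2 * sigma^2)))
  g / sum(g)
}

# AUC as the Mann-Whitney pair-counting statistic (ties count 1/2).
brute_auc <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Small seeded two-blob classification problem.
make_blobs <- function(n = 100, d = 2, sep = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * d), n, d)
  x[y == 1, 1] <- x[y == 1, 1] + sep
  list(x = x, y = y)
}
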