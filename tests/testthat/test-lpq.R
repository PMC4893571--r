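test_that("lpq_config validates its parameters", {
  expect_error(lpq_config(window = 4), "odd")
  expect_error(lpq_config(window = 1), "odd")
  expect_error(lpq_config(a = 0.7), "0, 0.5")
  expect_equal(lpq_config()$a, 1 / 3)
})

test_that("STFT equals the brute-force double-loop oracle", {
  freqs <- function(a) list(c(a, 0), c(0, a), c(a, a), c(a, -a))
  set.seed(101)
  # fixtures up to 16x16, two window sizes
  fixtures <- list(matrix(rnorm(64), 8, 8),
                   matrix(rnorm(16 * 16), 16, 16),
                   matrix(rnorm(12 * 9), 12, 9))
  for (mat in fixtures) {
    for (w in c(3L, 5L)) {
      cfg <- lpq_config(window = w)
      r <- (w - 1L) %/% 2L
      st <- lpq_stft(mat, cfg)
      for (k in 1:4) {
        expect_lt(max(abs(st$planes[[k]] -
                            brute_stft(mat, freqs(cfg$a)[[k]], r))), 1e-9)
      }
    }
  }
})

test_that("STFT of a constant matrix vanishes at a = 1/window", {
  st <- lpq_stft(matrix(7.3, 9, 9), lpq_config())
  for (p in st$planes) expect_lt(max(abs(p)), 1e-9)
})

test_that("STFT of a single impulse has |F| = 1 where the window sees it", {
  m <- matrix(0, 7, 7)
  m[4, 4] <- 1
  st <- lpq_stft(m, lpq_config())
  for (p in st$planes) {
    mag <- abs(p)
    # valid grid is 5x5; the impulse at input (4,4) is inside the window
    # of output centers (3..5, 3..5) -> ones there, zeros elsewhere
    expect_equal(mag > 0.5, outer(1:5, 1:5, function(i, j)
      abs(i - 3) <= 1 & abs(j - 3) <= 1))
    expect_equal(unname(mag[mag > 0.5]), rep(1, 9), tolerance = 1e-12)
  }
})

test_that("matrix smaller than the window errors under border='valid'", {
  expect_error(lpq_stft(matrix(0, 2, 8), lpq_config()), "smaller")
  expect_silent(lpq_stft(matrix(rnorm(16), 2, 8),
                         lpq_config(border = "zero")))
})

test_that("quantization encodes sign patterns per the 8-bit rule", {
  fake <- function(g) {
    # one-pixel coefficient planes with prescribed component values
    planes <- lapply(1:4, function(k) {
      matrix(complex(real = g[k], imaginary = g[4 + k]), 1, 1)
    })
    structure(list(planes = planes, config = lpq_config()),
              class = "lpq_stft")
  }
  # all-zero components: >= 0 so every bit set -> 255
  expect_equal(lpq_quantize(fake(rep(0, 8)))[1, 1], 255L)
  # signs [+,+,-,+,-,-,+,+] -> 1+2+8+64+128 = 203
  expect_equal(lpq_quantize(fake(c(1, 1, -1, 1, -1, -1, 1, 1)))[1, 1], 203L)
  # all negative -> 0
  expect_equal(lpq_quantize(fake(rep(-1, 8)))[1, 1], 0L)
  # exhaustive: the 256 sign patterns give exactly the codes 0..255
  codes <- vapply(0:255, function(n) {
    bits <- as.integer(intToBits(n))[1:8]
    lpq_quantize(fake(ifelse(bits == 1L, 1, -1)))[1, 1]
  }, integer(1))
  expect_identical(codes, 0:255)
})

test_that("histogram has 256 bins and counts every evaluated pixel", {
  set.seed(5)
  m <- matrix(rnorm(30 * 20), 30, 20)
  h <- lpq_histogram(m, normalized = FALSE)
  expect_length(h, 256)
  expect_equal(sum(h), 28 * 18)  # valid positions
  hn <- lpq_histogram(m)
  expect_equal(sum(hn), 1)
  # constant input: all mass in one bin
  hc <- lpq_histogram(matrix(2, 10, 10), normalized = FALSE)
  expect_equal(sum(hc > 0), 1)
  # end-to-end against the brute-force code pipeline
  oracle <- tabulate(as.vector(brute_lpq_codes(m, 1 / 3, 1)) + 1L, 256)
  expect_equal(unname(h), oracle)
})

test_that("codes ignore a constant offset of the input", {
  set.seed(6)
  m <- matrix(rnorm(100), 10, 10)
  cfg <- lpq_config()
  expect_identical(lpq_quantize(lpq_stft(m, cfg)),
                   lpq_quantize(lpq_stft(m + 42, cfg)))
})

test_that("featurize_pssm yields a normalized 256-vector, deterministically", {
  x <- pssm_from_sequence(paste(rep("ACDEFGHIKL", 5), collapse = ""))
  f1 <- featurize_pssm(x)
  expect_length(f1, 256)
  expect_equal(sum(f1), 1)
  expect_identical(f1, featurize_pssm(x + 0))
  expect_error(featurize_pssm(x[1:2, ], id = "shorty"), "shorty")
})

test_that("codes are blur-invariant for a centrally symmetric kernel", {
  # Local-phase blur invariance is exact in the global-transform limit;
  # with a 3x3 analysis window it holds for blurs small relative to the
  # window. Kernel: Gaussian sigma 0.4, H(u) > 0 at the four
  # frequencies; thresholds frozen from seeded runs.
  set.seed(8)
  # spatially correlated fixture (the theory assumes the coefficient
  # planes vary slowly relative to the blur extent)
  raw <- matrix(rnorm(60 * 44), 60, 44)
  base <- conv2_valid(raw, gaussian_blur_kernel(sigma = 1.5, radius = 4))
  k <- gaussian_blur_kernel(sigma = 0.4, radius = 1)
  blurred <- conv2_valid(base, k)
  orig <- base[2:(nrow(base) - 1), 2:(ncol(base) - 1)]
  cfg <- lpq_config()
  c1 <- lpq_quantize(lpq_stft(orig, cfg))
  c2 <- lpq_quantize(lpq_stft(blurred, cfg))
  expect_gte(mean(c1 == c2), 0.9)
})

test_that("PSSM histograms are stable under mild symmetric blur", {
  set.seed(9)
  s <- paste(sample(aa_alphabet(), 60, replace = TRUE), collapse = "")
  x <- pssm_from_sequence(s)
  k <- gaussian_blur_kernel(sigma = 0.4, radius = 1)
  padded <- x[c(1, 1:60, 60), c(1, 1:20, 20)]  # replicate borders
  xb <- conv2_valid(padded, k)
  h1 <- featurize_pssm(x)
  h2 <- lpq_histogram(xb)
  cosine <- sum(h1 * h2) / sqrt(sum(h1^2) * sum(h2^2))
  expect_gte(cosine, 0.9)
})
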