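#' Local Phase Quantization configuration
#'
#' Parameters of the LPQ descriptor. A short-term Fourier transform is
#' evaluated over a sliding `window` x `window` neighborhood at the four
#' low frequencies u1 = (a, 0), u2 = (0, a), u3 = (a, a), u4 = (a, -a);
#' the signs of the eight real/imaginary parts form an 8-bit code per
#' pixel. `a` must be small enough that a centrally symmetric blur
#' kernel has a non-negative transfer function at these frequencies —
#' that is what makes the codes blur-invariant.
#'
#' @param window Odd neighborhood side length, >= 3. Default 3, the
#'   smallest standard LPQ window; appropriate here because PSSM
#'   "images" are only 20 columns wide.
#' @param a Frequency parameter in (0, 0.5]; default `1/window`, which
#'   also cancels the DC component of the window so adding a constant
#'   to the input changes no code.
#' @param border One of `"valid"` (codes only where the full window
#'   fits; default), `"reflect"` or `"zero"` (pad, codes at every
#'   pixel).
#' @return An object of class `lpq_config`.
#' @export
lpq_config <- function(window = 3, a = 1 / window,
                       border = c("valid", "reflect", "zero")) {
  border <- match.arg(border)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    stop("window must be an odd integer >= 3")
  }
  if (!is.numeric(a) || a <= 0 || a > 0.5) stop("a must be in (0, 0.5]")
  structure(list(window = window, a = a, border = border),
            class = "lpq_config")
}

# The four LPQ frequencies as (row, col) pairs.
lpq_frequencies <- function(a) {
  list(c(a, 0), c(0, a), c(a, a), c(a, -a))
}

lpq_pad <- function(mat, r, border) {
  if (border == "valid") return(mat)
  n <- nrow(mat); m <- ncol(mat)
  ri <- switch(border,
    reflect = c(rev(seq_len(min(r, n))), seq_len(n), n + 1 - seq_len(min(r, n))),
    zero = seq_len(n))
  if (border == "zero") {
    out <- matrix(0, n + 2 * r, m + 2 * r)
    out[r + seq_len(n), r + seq_len(m)] <- mat
    return(out)
  }
  if (n <= r || m <= r) stop("matrix too small for reflect padding")
  ci <- c(rev(seq_len(r)), seq_len(m), m + 1 - seq_len(r))
  ri <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
  mat[ri, ci, drop = FALSE]
}

# Banded operator applying the 1-D window sum
#   out[i] = sum_{d = -r..r} f[c_i - d] * exp(-2i * pi * d * freq)
# along one axis; the 2-D STFT kernel exp(-2i*pi*(d_r*u_r + d_c*u_c))
# factorizes, so each frequency plane is two such matrix products.
lpq_band_matrix <- function(n_in, freq, r) {
  n_out <- n_in - 2L * r
  w <- exp(-2i * pi * (-r:r) * freq)  # weight for offset d = -r..r
  a <- matrix(0i, n_out, n_in)
  for (i in seq_len(n_out)) {
    centre <- i + r
    # column p = centre - d, d = -r..r  ->  p = centre + r .. centre - r
    a[i, centre - (-r:r)] <- w
  }
  a
}

#' Short-term Fourier transform at the four LPQ frequencies
#'
#' For every evaluated pixel x, computes
#' F(u, x) = sum_{y in N_x} f(x - y) exp(-2i pi y' u) over the centered
#' `window` x `window` neighborhood N_x, for the four frequencies of
#' [lpq_config()]. Implemented as separable complex banded-matrix
#' products; the contract is exact equality with the direct double sum.
#'
#' @param mat Real input matrix (for PSSMs: rows = residues,
#'   columns = amino acids).
#' @param config An [lpq_config()].
#' @return List with `planes` (list of 4 complex matrices, one per
#'   frequency, in u1..u4 order) and the config used.
#' @export
lpq_stft <- function(mat, config = lpq_config()) {
  stopifnot(is.matrix(mat))
  r <- (config$window - 1L) %/% 2L
  if (config$border == "valid" &&
      (nrow(mat) < config$window || ncol(mat) < config$window)) {
    stop("matrix (", nrow(mat), "x", ncol(mat),
         ") smaller than LPQ window (", config$window, ") with border='valid'")
  }
  padded <- lpq_pad(mat, r, config$border)
  freqs <- lpq_frequencies(config$a)
  planes <- lapply(freqs, function(u) {
    a_row <- lpq_band_matrix(nrow(padded), u[[1]], r)
    a_col <- lpq_band_matrix(ncol(padded), u[[2]], r)
    a_row %*% padded %*% t(a_col)
  })
  structure(list(planes = planes, config = config), class = "lpq_stft")
}

#' Quantize STFT coefficients into 8-bit LPQ codes
#'
#' Per pixel, the vector \[Re F(u1), Re F(u2), Re F(u3), Re F(u4),
#' Im F(u1), ..., Im F(u4)\] is sign-quantized — component j gives bit
#' q_j = 1 if it is >= 0, else 0 — and binary-encoded as
#' sum_j q_j 2^j, j = 0..7. A component exactly at zero therefore
#' quantizes to 1.
#'
#' @param coeffs Result of [lpq_stft()].
#' @return Integer matrix of codes in 0..255, one per evaluated pixel.
#' @export
lpq_quantize <- function(coeffs) {
  stopifnot(inherits(coeffs, "lpq_stft"))
  comps <- c(lapply(coeffs$planes, Re), lapply(coeffs$planes, Im))
  code <- matrix(0L, nrow(comps[[1]]), ncol(comps[[1]]))
  for (j in seq_along(comps)) {
    code <- code + as.integer(comps[[j]] >= 0) * bitwShiftL(1L, j - 1L)
  }
  code
}

#' LPQ histogram of a real matrix
#'
#' Runs [lpq_stft()] and [lpq_quantize()] and tabulates the codes over
#' the 256 possible values. The output always has length 256 regardless
#' of input size.
#'
#' @inheritParams lpq_stft
#' @param normalized If `TRUE` (default) frequencies summing to 1,
#'   otherwise raw counts summing to the number of evaluated pixels.
#' @return Named numeric vector of length 256 (`bin_000` .. `bin_255`).
#' @export
lpq_histogram <- function(mat, config = lpq_config(), normalized = TRUE) {
  codes <- lpq_quantize(lpq_stft(mat, config))
  h <- tabulate(as.vector(codes) + 1L, nbins = 256L)
  if (normalized) h <- h / sum(h)
  names(h) <- sprintf("bin_%03d", 0:255)
  h
}

#' LPQ feature vector of a PSSM
#'
#' Treats the PSSM score matrix as a grayscale image and summarizes it
#' as a normalized 256-bin LPQ histogram — the per-protein feature
#' vector of the prediction pipeline.
#'
#' @param pssm L x 20 numeric score matrix.
#' @param config An [lpq_config()].
#' @param id Optional protein id, used in error messages.
#' @return Normalized numeric vector of length 256 summing to 1.
#' @export
featurize_pssm <- function(pssm, config = lpq_config(), id = NULL) {
  stopifnot(is.matrix(pssm), ncol(pssm) == 20)
  if (config$border == "valid" && nrow(pssm) < config$window) {
    stop("protein ", if (is.null(id)) "" else paste0("'", id, "' "),
         "has fewer residues (", nrow(pssm), ") than the LPQ window (",
         config$window, ")")
  }
  lpq_histogram(pssm, config, normalized = TRUE)
}

#' LPQ feature matrix for a set of PSSMs
#'
#' @param pssms Named list of L x 20 score matrices.
#' @param config An [lpq_config()].
#' @return Numeric matrix, one row per protein (rownames = ids), 256
#'   columns `bin_000` .. `bin_255`.
#' @export
featurize_pssms <- function(pssms, config = lpq_config()) {
  stopifnot(is.list(pssms), !is.null(names(pssms)))
  out <- t(vapply(names(pssms), function(id) {
    featurize_pssm(pssms[[id]], config, id = id)
  }, numeric(256)))
  rownames(out) <- names(pssms)
  out
}
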