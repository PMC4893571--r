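#' Canonical amino-acid alphabet
#'
#' The 20 standard amino acids in the column order used throughout the
#' package: `"ARNDCQEGHILKMFPSTWYV"`. This is the order PSI-BLAST prints
#' its score columns in, so matrices read from PSI-BLAST output and
#' matrices built internally line up without remapping.
#'
#' @return Character vector of the 20 one-letter amino-acid codes.
#' @export
aa_alphabet <- function() {
  strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
}

# Ambiguity sets for nonstandard one-letter codes. B = Asx (N or D),
# Z = Glx (Q or E); X, U (selenocysteine, no PAM250 column) and the stop
# code * fall back to the full alphabet.
aa_ambiguity <- function() {
  list(
    B = c("N", "D"),
    Z = c("Q", "E"),
    X = aa_alphabet(),
    U = aa_alphabet(),
    "*" = aa_alphabet()
  )
}

#' Dayhoff mutation matrix (PAM250 log-odds)
#'
#' The classic 20x20 Dayhoff PAM250 log-odds substitution table, indexed
#' by [aa_alphabet()] order on both axes. Used as the weighting matrix
#' q(j, k) when turning a positional amino-acid frequency profile into a
#' position specific scoring matrix (see [compute_pssm()]). The table is
#' symmetric; any other 20x20 symmetric scoring table can be passed to
#' [compute_pssm()] in its place.
#'
#' @return A symmetric 20x20 integer matrix with amino-acid dimnames.
#' @export
dayhoff_matrix <- function() {
  aa <- aa_alphabet()
  q <- matrix(c(
    2, -2, 0, 0, -2, 0, 0, 1, -1, -1, -2, -1, -1, -3, 1, 1, 1, -6, -3, 0,
    -2, 6, 0, -1, -4, 1, -1, -3, 2, -2, -3, 3, 0, -4, 0, 0, -1, 2, -4, -2,
    0, 0, 2, 2, -4, 1, 1, 0, 2, -2, -3, 1, -2, -3, 0, 1, 0, -4, -2, -2,
    0, -1, 2, 4, -5, 2, 3, 1, 1, -2, -4, 0, -3, -6, -1, 0, 0, -7, -4, -2,
    -2, -4, -4, -5, 12, -5, -5, -3, -3, -2, -6, -5, -5, -4, -3, 0, -2, -8, 0, -2,
    0, 1, 1, 2, -5, 4, 2, -1, 3, -2, -2, 1, -1, -5, 0, -1, -1, -5, -4, -2,
    0, -1, 1, 3, -5, 2, 4, 0, 1, -2, -3, 0, -2, -5, -1, 0, 0, -7, -4, -2,
    1, -3, 0, 1, -3, -1, 0, 5, -2, -3, -4, -2, -3, -5, 0, 1, 0, -7, -5, -1,
    -1, 2, 2, 1, -3, 3, 1, -2, 6, -2, -2, 0, -2, -2, 0, -1, -1, -3, 0, -2,
    -1, -2, -2, -2, -2, -2, -2, -3, -2, 5, 2, -2, 2, 1, -2, -1, 0, -5, -1, 4,
    -2, -3, -3, -4, -6, -2, -3, -4, -2, 2, 6, -3, 4, 2, -3, -3, -2, -2, -1, 2,
    -1, 3, 1, 0, -5, 1, 0, -2, 0, -2, -3, 5, 0, -5, -1, 0, 0, -3, -4, -2,
    -1, 0, -2, -3, -5, -1, -2, -3, -2, 2, 4, 0, 6, 0, -2, -2, -1, -4, -2, 2,
    -3, -4, -3, -6, -4, -5, -5, -5, -2, 1, 2, -5, 0, 9, -5, -3, -3, 0, 7, -1,
    1, 0, 0, -1, -3, 0, -1, 0, 0, -2, -3, -1, -2, -5, 6, 1, 0, -6, -5, -1,
    1, 0, 1, 0, 0, -1, 0, 1, -1, -1, -3, 0, -2, -3, 1, 2, 1, -2, -3, -1,
    1, -1, 0, 0, -2, -1, 0, 0, -1, 0, -2, 0, -1, -3, 0, 1, 3, -5, -3, 0,
    -6, 2, -4, -7, -8, -5, -7, -7, -3, -5, -2, -3, -4, 0, -6, -2, -5, 17, 0, -6,
    -3, -4, -2, -4, 0, -4, -4, -5, 0, -1, -1, -4, -2, 7, -5, -3, -3, 0, 10, -2,
    0, -2, -2, -2, -2, -2, -2, -1, -2, 4, 2, -2, 2, -1, -1, -1, 0, -6, -2, 4
  ), nrow = 20, byrow = TRUE, dimnames = list(aa, aa))
  q
}
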