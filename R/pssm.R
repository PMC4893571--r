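#' Read protein sequences from a FASTA file
#'
#' Reads a FASTA file into a data frame of protein sequences. Record ids
#' are taken from the header line up to the first whitespace; record
#' order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param strict If `TRUE`, any residue outside the 20 standard
#'   amino-acid codes raises an error naming the offending record.
#'   The default (`FALSE`) additionally accepts the ambiguity codes
#'   B, Z, X, U and `*`, which downstream profile construction spreads
#'   over their ambiguity sets.
#' @return A data frame with character columns `id` and `residues`, one
#'   row per record (zero rows for an empty file).
#' @seealso [profile_from_sequences()], [pssm_from_sequence()]
#' @export
read_fasta <- function(path, strict = FALSE) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  if (file.size(path) == 0) {
    return(data.frame(id = character(), residues = character(),
                      stringsAsFactors = FALSE))
  }
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  res <- toupper(as.character(set))
  allowed <- aa_alphabet()
  if (!strict) allowed <- c(allowed, names(aa_ambiguity()))
  for (i in seq_along(res)) {
    if (nchar(res[[i]]) == 0L) {
      stop("empty sequence in record '", ids[[i]], "'")
    }
    chars <- strsplit(res[[i]], "")[[1]]
    bad <- setdiff(unique(chars), allowed)
    if (length(bad)) {
      stop("illegal residue(s) ", paste(bad, collapse = ", "),
           " in record '", ids[[i]], "'")
    }
  }
  data.frame(id = unname(ids), residues = unname(res),
             stringsAsFactors = FALSE)
}

#' Positional amino-acid frequency profile
#'
#' Builds the per-position frequency table p(i, k) from a set of aligned
#' (equal-length) sequences: the proportion of sequences carrying amino
#' acid k at position i. Each row sums to one. Ambiguity codes are
#' spread uniformly over their ambiguity set (B over N/D, Z over Q/E,
#' X/U/`*` over all 20) unless `strict = TRUE`, in which case they are
#' an error.
#'
#' @param sequences Character vector of equal-length sequences (or a
#'   data frame with a `residues` column as returned by [read_fasta()]).
#' @param strict Error on ambiguity codes instead of spreading them.
#' @return An M x 20 matrix of row-stochastic frequencies, columns in
#'   [aa_alphabet()] order.
#' @export
profile_from_sequences <- function(sequences, strict = FALSE) {
  if (is.data.frame(sequences)) sequences <- sequences$residues
  if (length(sequences) == 0L) stop("no sequences supplied")
  lens <- nchar(sequences)
  if (any(lens == 0L)) stop("empty sequence supplied")
  if (length(unique(lens)) != 1L) {
    stop("sequences must be equal length (got lengths ",
         paste(unique(lens), collapse = ", "), ")")
  }
  aa <- aa_alphabet()
  amb <- aa_ambiguity()
  m <- lens[[1]]
  p <- matrix(0, nrow = m, ncol = 20, dimnames = list(NULL, aa))
  chars <- do.call(rbind, strsplit(toupper(sequences), ""))
  for (i in seq_len(m)) {
    for (ch in chars[, i]) {
      if (ch %in% aa) {
        p[i, ch] <- p[i, ch] + 1
      } else if (ch %in% names(amb)) {
        if (strict) stop("nonstandard residue '", ch, "' at position ", i)
        set <- amb[[ch]]
        p[i, set] <- p[i, set] + 1 / length(set)
      } else {
        stop("unknown residue '", ch, "' at position ", i)
      }
    }
  }
  p / length(sequences)
}

#' Position specific scoring matrix from a profile
#'
#' Scores each position of a frequency profile against every amino acid
#' using a substitution table: X_ij = sum_k p(i, k) q(j, k), where
#' p(i, k) is the profile frequency of amino acid k at position i and
#' q(j, k) is the substitution score between amino acids j and k. With
#' the default Dayhoff PAM250 table a high X_ij marks a position whose
#' observed residues substitute favourably with amino acid j, i.e. a
#' conserved position.
#'
#' @param profile M x 20 row-stochastic matrix from
#'   [profile_from_sequences()].
#' @param dayhoff 20 x 20 symmetric substitution table; defaults to
#'   [dayhoff_matrix()].
#' @return An M x 20 numeric matrix of scores, columns in
#'   [aa_alphabet()] order.
#' @export
compute_pssm <- function(profile, dayhoff = dayhoff_matrix()) {
  stopifnot(is.matrix(profile), ncol(profile) == 20,
            is.matrix(dayhoff), all(dim(dayhoff) == c(20, 20)))
  x <- profile %*% t(dayhoff)
  colnames(x) <- aa_alphabet()
  x
}

#' Dayhoff-formula PSSM of a single sequence
#'
#' Convenience wrapper: the one-hot profile of a single sequence pushed
#' through [compute_pssm()]. Row i of the result is the Dayhoff-matrix
#' row of the residue at position i. This is the internal stand-in used
#' when no PSI-BLAST profile files are supplied; genuine PSI-BLAST
#' PSSMs (e-value 0.001, 3 iterations against a sequence database) carry
#' homology information this formula cannot, and are read with
#' [read_psiblast_pssm()] when available.
#'
#' @param sequence A single sequence string.
#' @inheritParams profile_from_sequences
#' @return An L x 20 numeric score matrix.
#' @export
pssm_from_sequence <- function(sequence, strict = FALSE) {
  compute_pssm(profile_from_sequences(sequence, strict = strict))
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the ASCII matrix dump produced by PSI-BLAST
#' (`-out_ascii_pssm` style): header lines, then one row per residue
#' whose first 20 numeric columns are the log-odds scores. Columns are
#' remapped from the order given in the file's own header line to
#' [aa_alphabet()] order (these normally coincide).
#'
#' @param path Path to the ASCII PSSM file.
#' @return An M x 20 numeric matrix, one row per residue in file order,
#'   with the residue letters as rownames and amino acids as colnames.
#' @export
read_psiblast_pssm <- function(path) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path)
  aa <- aa_alphabet()
  # Header line: >= 20 single-letter tokens (scores block, then often a
  # repeated block for the percentage columns).
  header_idx <- NA_integer_
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(toks) >= 20 && all(nchar(toks) == 1L) &&
        all(toks[1:20] %in% aa) && !anyDuplicated(toks[1:20])) {
      header_idx <- i
      break
    }
  }
  if (is.na(header_idx)) {
    stop("no PSI-BLAST column header line found in ", path)
  }
  col_order <- strsplit(trimws(lines[[header_idx]]), "\\s+")[[1]][1:20]
  if (header_idx >= length(lines)) stop("no PSSM rows found in ", path)
  rows <- list()
  residues <- character()
  for (i in seq(header_idx + 1L, length(lines))) {
    line <- trimws(lines[[i]])
    if (line == "") break
    toks <- strsplit(line, "\\s+")[[1]]
    # Row layout: position index, residue letter, then numeric columns.
    if (length(toks) < 22 || is.na(suppressWarnings(as.integer(toks[[1]])))) {
      if (length(rows)) break  # footer (Lambda/K lines etc.)
      stop("malformed PSSM row at line ", i, ": ", lines[[i]])
    }
    vals <- suppressWarnings(as.numeric(toks[3:22]))
    if (anyNA(vals)) {
      stop("malformed PSSM row at line ", i, ": ", lines[[i]])
    }
    rows[[length(rows) + 1L]] <- vals
    residues[[length(residues) + 1L]] <- toks[[2]]
  }
  if (!length(rows)) stop("no PSSM rows found in ", path)
  x <- do.call(rbind, rows)
  colnames(x) <- col_order
  x <- x[, aa, drop = FALSE]
  rownames(x) <- residues
  x
}

#' Write a score matrix in the PSI-BLAST ASCII layout
#'
#' Writes an M x 20 score matrix in the row/column layout that
#' [read_psiblast_pssm()] accepts, so synthetic fixtures round-trip
#' through the same reader as real PSI-BLAST output. Real-valued scores
#' are written with full precision (PSI-BLAST itself prints integers);
#' the trailing percentage block is filled with zeros.
#'
#' @param scores M x 20 numeric matrix.
#' @param path Output file path.
#' @param residues Optional character vector of M residue letters for
#'   the row labels (defaults to the matrix rownames, else "X").
#' @return `path`, invisibly.
#' @export
write_psiblast_pssm <- function(scores, path, residues = NULL) {
  stopifnot(is.matrix(scores), ncol(scores) == 20)
  if (is.null(residues)) residues <- rownames(scores)
  if (is.null(residues)) residues <- rep("X", nrow(scores))
  aa <- aa_alphabet()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed, weighted, synthetic",
    paste0("           ", paste(c(aa, aa), collapse = "   "))
  ), con)
  for (i in seq_len(nrow(scores))) {
    vals <- formatC(scores[i, ], format = "g", digits = 17)
    writeLines(paste(c(sprintf("%5d %s", i, residues[[i]]), vals,
                       rep("0", 20)), collapse = "  "), con)
  }
  writeLines("", con)
  invisible(path)
}
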