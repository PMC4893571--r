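#' Specification for a synthetic PPI benchmark
#'
#' Parameters of the seeded generators that produce every input the
#' pipeline consumes offline: amino-acid sequences, per-protein L x 20
#' PSSM-like score matrices, and a balanced pair list. Interacting
#' (positive) pairs share an additive rank-one "motif" injected into
#' both partners' matrices, so the positive class carries detectable
#' matrix structure while negatives are independent — the signal lives
#' at the PSSM level, where the LPQ feature chain must pick it up.
#'
#' @param n_proteins Number of proteins for [gen_sequences()].
#' @param length_range Integer range of sequence lengths, drawn
#'   uniformly.
#' @param n_pairs Number of protein pairs for [gen_pair_dataset()];
#'   every pair gets two dedicated proteins.
#' @param pos_fraction Fraction of interacting pairs in (0, 1).
#' @param motif_strength Non-negative scale of the shared rank-one
#'   component, in score units; 0 removes all class signal. The total
#'   per-entry background spread of a generated matrix is about 3 score
#'   units (Dayhoff-row variation across random residues, sd ~2.8, plus
#'   the additive noise), so the default of 15 is a strong signal of
#'   about five times the background — the clearly separable regime.
#' @param noise_sd Standard deviation of the i.i.d. Gaussian
#'   measurement noise added to each score matrix (default 1; note the
#'   Dayhoff base matrix itself contributes most of the background
#'   variation).
#' @param seed Integer seed; all outputs are deterministic given it.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 100, length_range = c(60, 100),
                           n_pairs = 200, pos_fraction = 0.5,
                           motif_strength = 15, noise_sd = 1, seed = 1) {
  stopifnot(n_proteins >= 1, n_pairs >= 1,
            length(length_range) == 2, length_range[1] >= 3,
            length_range[2] >= length_range[1],
            pos_fraction > 0, pos_fraction < 1,
            motif_strength >= 0, noise_sd >= 0)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 n_pairs = as.integer(n_pairs),
                 pos_fraction = pos_fraction,
                 motif_strength = motif_strength,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate random protein sequences
#'
#' I.i.d.-uniform sequences over the 20 standard amino acids, lengths
#' uniform over `spec$length_range`; deterministic per seed.
#'
#' @param spec A [synthetic_spec()].
#' @return Data frame with columns `id`, `residues`.
#' @export
gen_sequences <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_preserved_seed(spec$seed, {
    aa <- aa_alphabet()
    lens <- sample_length(spec$length_range, spec$n_proteins)
    data.frame(
      id = sprintf("SYN%05d", seq_len(spec$n_proteins)),
      residues = vapply(lens, function(l) {
        paste(sample(aa, l, replace = TRUE), collapse = "")
      }, character(1)),
      stringsAsFactors = FALSE
    )
  })
}

# sample() treats a length-1 x as 1:x; guard the degenerate range
sample_length <- function(range, n = 1) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

# Smooth unit-RMS profile along the sequence: a random walk high-pass
# free of abrupt jumps, so the injected motif varies slowly over
# positions the way conserved stretches do.
smooth_profile <- function(l) {
  u <- cumsum(stats::rnorm(l))
  u <- u - mean(u)
  rms <- sqrt(mean(u^2))
  if (rms < .Machine$double.eps) rep(1, l) else u / rms
}

#' Generate a labelled synthetic protein-pair dataset
#'
#' Each of the `n_pairs` pairs receives two dedicated proteins. A
#' protein's score matrix is its Dayhoff-formula PSSM (so rows look
#' like substitution-score rows, as in real profiles) plus i.i.d.
#' Gaussian noise. For interacting pairs, both matrices additionally
#' receive `motif_strength * u v'`, where v is one fixed unit 20-vector
#' per dataset (the shared "interaction motif" over amino-acid columns)
#' and u is a smooth per-protein unit-RMS profile over positions. With
#' `motif_strength = 0` the classes are statistically identical.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `pairs` (data frame `id_a`, `id_b`, `label`),
#'   `sequences` (data frame `id`, `residues`), `pssms` (named list of
#'   L x 20 matrices) and `truth` (generative parameters: `motif_v`,
#'   per-protein motif profiles).
#' @export
gen_pair_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_preserved_seed(spec$seed, {
    aa <- aa_alphabet()
    n_pos <- round(spec$n_pairs * spec$pos_fraction)
    labels <- c(rep(1L, n_pos), rep(0L, spec$n_pairs - n_pos))
    motif_v <- stats::rnorm(20)
    motif_v <- motif_v / sqrt(sum(motif_v^2))
    ids <- sprintf("SYN%05d", seq_len(2L * spec$n_pairs))
    seqs <- character(2L * spec$n_pairs)
    pssms <- vector("list", 2L * spec$n_pairs)
    profiles <- vector("list", 2L * spec$n_pairs)
    make_protein <- function(i, interacting) {
      l <- sample_length(spec$length_range)
      s <- paste(sample(aa, l, replace = TRUE), collapse = "")
      x <- pssm_from_sequence(s)
      if (spec$noise_sd > 0) {
        x <- x + matrix(stats::rnorm(l * 20, sd = spec$noise_sd), l, 20)
      }
      u <- NULL
      if (interacting && spec$motif_strength > 0) {
        u <- smooth_profile(l)
        x <- x + spec$motif_strength * (u %o% motif_v)
      }
      seqs[[i]] <<- s
      pssms[[i]] <<- x
      profiles[[i]] <<- u
      invisible(NULL)
    }
    for (p in seq_len(spec$n_pairs)) {
      make_protein(2L * p - 1L, labels[[p]] == 1L)
      make_protein(2L * p, labels[[p]] == 1L)
    }
    names(pssms) <- ids
    pairs <- data.frame(
      id_a = ids[2L * seq_len(spec$n_pairs) - 1L],
      id_b = ids[2L * seq_len(spec$n_pairs)],
      label = labels,
      stringsAsFactors = FALSE
    )
    # shuffle row order so folds mix classes
    pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
    rownames(pairs) <- NULL
    list(pairs = pairs,
         sequences = data.frame(id = ids, residues = seqs,
                                stringsAsFactors = FALSE),
         pssms = pssms,
         truth = list(motif_v = motif_v, motif_profiles = profiles,
                      spec = spec))
  })
}

#' Write a synthetic fixture bundle to disk
#'
#' Materializes a generated dataset as the same plain-text formats the
#' real pipeline reads: `proteins.fasta`, one ASCII PSSM per protein
#' under `pssm/` (in the PSI-BLAST dialect [read_psiblast_pssm()]
#' accepts), `pairs.tsv` (`id_a<TAB>id_b<TAB>label` with header) and
#' `spec.json`. The bundle lets the full command-line pipeline run
#' offline; reading the PSSM files back reproduces the generated
#' matrices exactly.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if missing).
#' @return The dataset list from [gen_pair_dataset()], invisibly.
#' @export
write_fixture_bundle <- function(spec, out_dir) {
  ds <- gen_pair_dataset(spec)
  dir.create(file.path(out_dir, "pssm"), recursive = TRUE,
             showWarnings = FALSE)
  fasta <- file.path(out_dir, "proteins.fasta")
  writeLines(paste0(">", ds$sequences$id, "\n", ds$sequences$residues),
             fasta)
  for (id in names(ds$pssms)) {
    write_psiblast_pssm(ds$pssms[[id]],
                        file.path(out_dir, "pssm", paste0(id, ".pssm")),
                        residues = strsplit(
                          ds$sequences$residues[ds$sequences$id == id],
                          "")[[1]])
  }
  utils::write.table(ds$pairs, file.path(out_dir, "pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(ds$truth$spec),
                       file.path(out_dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(ds)
}
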