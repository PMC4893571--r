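#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end predictor: LPQ descriptor
#' settings, the number of retained principal components, the
#' classifier and its kernel parameters, and the cross-validation
#' protocol. Defaults follow the reference configuration: Gaussian RVM
#' kernel width 0.6, SVM baseline with cost 0.7 and RBF gamma 0.6,
#' 5-fold cross-validation.
#'
#' @param lpq An [lpq_config()].
#' @param pca_k Principal components retained per protein vector
#'   (default 100; presets of 180 and 172 were used for the Yeast- and
#'   Human-scale datasets respectively). Must not exceed the number of
#'   training proteins or 256.
#' @param classifier `"rvm"` (default) or `"svm"`.
#' @param rvm_width,rvm_form Gaussian kernel width/parameterization for
#'   the RVM (see [gaussian_kernel()]).
#' @param svm_cost,svm_gamma Soft-margin cost and RBF gamma for the SVM
#'   baseline.
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed controlling the fold shuffle.
#' @param pair_encoding `"concat"` (default): a pair's feature vector
#'   is the concatenation of its two reduced protein vectors, length
#'   `2 * pca_k`. `"symmetric"`: sum and absolute difference of the two
#'   halves, invariant to partner order.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(lpq = lpq_config(), pca_k = 100,
                            classifier = c("rvm", "svm"),
                            rvm_width = 0.6, rvm_form = "bandwidth",
                            svm_cost = 0.7, svm_gamma = 0.6,
                            folds = 5, seed = 1,
                            pair_encoding = c("concat", "symmetric")) {
  structure(list(lpq = lpq, pca_k = as.integer(pca_k),
                 classifier = match.arg(classifier),
                 rvm_width = rvm_width, rvm_form = rvm_form,
                 svm_cost = svm_cost, svm_gamma = svm_gamma,
                 folds = as.integer(folds), seed = as.integer(seed),
                 pair_encoding = match.arg(pair_encoding)),
            class = "pipeline_config")
}

#' Build per-pair feature vectors
#'
#' Projects each protein's 256-bin LPQ vector through a fitted PCA
#' model and combines the two partners' reduced vectors into one pair
#' vector (concatenation by default).
#'
#' @param pairs Data frame with columns `id_a`, `id_b`, `label`.
#' @param features Numeric matrix of per-protein LPQ vectors, rownames
#'   = protein ids.
#' @param pca A fitted `pca_model`.
#' @param encoding `"concat"` or `"symmetric"`; see
#'   [pipeline_config()].
#' @return List with `x` (n_pairs x 2k matrix) and integer `y` labels.
#' @export
pair_features <- function(pairs, features, pca,
                          encoding = c("concat", "symmetric")) {
  encoding <- match.arg(encoding)
  missing_ids <- setdiff(unique(c(pairs$id_a, pairs$id_b)),
                         rownames(features))
  if (length(missing_ids)) {
    stop("no feature vector for protein(s): ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  za <- predict(pca, features[pairs$id_a, , drop = FALSE])
  zb <- predict(pca, features[pairs$id_b, , drop = FALSE])
  x <- switch(encoding,
    concat = cbind(za, zb),
    symmetric = cbind(za + zb, abs(za - zb)))
  rownames(x) <- NULL
  list(x = x, y = as.integer(pairs$label))
}

fit_fold_classifier <- function(x, y, config) {
  if (config$classifier == "rvm") {
    rvm_fit(x, y, width = config$rvm_width, form = config$rvm_form)
  } else {
    e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
               cost = config$svm_cost, gamma = config$svm_gamma,
               scale = FALSE)
  }
}

predict_fold_classifier <- function(model, x, config) {
  if (config$classifier == "rvm") {
    predict(model, x)
  } else {
    pred <- predict(model, x, decision.values = TRUE)
    dv <- drop(attr(pred, "decision.values"))
    # orient decision values so larger = class "1"
    if (grepl("^0/", colnames(attr(pred, "decision.values"))[1])) dv <- -dv
    list(score = dv, label = as.integer(as.character(pred)))
  }
}

#' Cross-validated evaluation of the PPI predictor
#'
#' Runs the full protocol on a labelled pair list: shuffled k-fold
#' split of the pairs; per fold, PCA is fitted on the LPQ vectors of
#' the training proteins only, pair vectors are built, the classifier
#' is trained on the training pairs and evaluated on the held-out
#' pairs. Per-fold accuracy, sensitivity, specificity, precision and
#' MCC are aggregated as mean and sample sd, and a ROC is computed over
#' the pooled held-out scores. Fully reproducible given
#' `config$seed`; fold splits depend only on the seed and the number of
#' pairs, so RVM and SVM runs with the same seed are compared on
#' identical folds.
#'
#' @param pairs Data frame `id_a`, `id_b`, `label` (0/1).
#' @param features Per-protein LPQ feature matrix (rownames = ids), as
#'   from [featurize_pssms()].
#' @param config A [pipeline_config()].
#' @return Object of class `ppi_cv`: `fold_reports` (list of
#'   `metric_report`), `summary` (data frame metric/mean/sd),
#'   `roc` (pooled), `scores` (data frame with fold, truth, score,
#'   label per pair), `folds` (the index splits), `train_proteins`
#'   (per-fold ids PCA and classifier were fitted on), `config`.
#' @export
run_cv <- function(pairs, features, config = pipeline_config()) {
  stopifnot(all(c("id_a", "id_b", "label") %in% names(pairs)))
  if (!all(pairs$label %in% c(0, 1))) stop("labels must be 0 or 1")
  folds <- kfold_split(nrow(pairs), config$folds, config$seed)
  fold_reports <- vector("list", length(folds))
  score_rows <- vector("list", length(folds))
  train_proteins <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    tr <- pairs[folds[[f]]$train, , drop = FALSE]
    te <- pairs[folds[[f]]$test, , drop = FALSE]
    if (length(unique(tr$label)) < 2) {
      stop("degenerate fold ", f, ": training labels are one-class")
    }
    tr_ids <- unique(c(tr$id_a, tr$id_b))
    train_proteins[[f]] <- tr_ids
    k <- config$pca_k
    if (k > min(length(tr_ids), ncol(features))) {
      stop("pca_k = ", k, " exceeds min(training proteins, variables) = ",
           min(length(tr_ids), ncol(features)))
    }
    pca <- fit_pca(features[tr_ids, , drop = FALSE], k)
    tr_xy <- pair_features(tr, features, pca, config$pair_encoding)
    te_xy <- pair_features(te, features, pca, config$pair_encoding)
    model <- fit_fold_classifier(tr_xy$x, tr_xy$y, config)
    pred <- predict_fold_classifier(model, te_xy$x, config)
    fold_reports[[f]] <- metric_report(confusion(te_xy$y, pred$label))
    score_rows[[f]] <- data.frame(fold = f, truth = te_xy$y,
                                  score = pred$score, label = pred$label)
  }
  scores <- do.call(rbind, score_rows)
  metrics <- c("ac", "sn", "sp", "pe", "mcc")
  agg <- t(vapply(metrics, function(m) {
    fold_aggregate(vapply(fold_reports, function(r) r[[m]], numeric(1)))
  }, numeric(2)))
  summary_df <- data.frame(metric = metrics, mean = agg[, 1],
                           sd = agg[, 2], row.names = NULL)
  structure(list(fold_reports = fold_reports, summary = summary_df,
                 roc = roc_curve(scores$score, scores$truth),
                 scores = scores, folds = folds,
                 train_proteins = train_proteins, config = config),
            class = "ppi_cv")
}

#' SVM baseline under the identical protocol
#'
#' Convenience wrapper: [run_cv()] with the classifier switched to the
#' radial-basis soft-margin SVM (cost 0.7, gamma 0.6 by default); with
#' the same seed the fold splits match the RVM run exactly, so the two
#' classifiers are compared on the same feature extraction and splits.
#'
#' @inheritParams run_cv
#' @return A `ppi_cv` object.
#' @export
run_svm_baseline <- function(pairs, features, config = pipeline_config()) {
  config$classifier <- "svm"
  run_cv(pairs, features, config)
}

#' @export
print.ppi_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, classifier = %s, %d pairs\n",
              x$config$folds, x$config$classifier, nrow(x$scores)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-4s %6.4f +/- %6.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  cat(sprintf("  pooled AUC %6.4f\n", x$roc$auc))
  invisible(x)
}

#' Plot the pooled ROC curve of a cross-validation run
#'
#' Draws the ROC of the pooled held-out scores; with `add = TRUE`
#' overlays onto an existing plot, so RVM and SVM runs can share one
#' axis set.
#'
#' @param x A `ppi_cv` object.
#' @param add Overlay on the current plot instead of starting one.
#' @param col Line color.
#' @param ... Passed to [graphics::lines()].
#' @return `x`, invisibly.
#' @export
plot.ppi_cv <- function(x, add = FALSE, col = "steelblue", ...) {
  pts <- x$roc$points
  if (!add) {
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "False positive rate",
                   ylab = "True positive rate",
                   main = "Cross-validated ROC")
    graphics::abline(0, 1, lty = 3, col = "grey60")
  }
  graphics::lines(pts$fpr, pts$tpr, col = col, lwd = 2, ...)
  invisible(x)
}

#' Read a pair list from TSV
#'
#' Three tab-separated columns `id_a`, `id_b`, `label` (0/1); a header
#' line is detected and skipped if its third field is not numeric.
#'
#' @param path Path to the TSV file.
#' @return Data frame `id_a`, `id_b`, `label`.
#' @export
read_pair_table <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  header <- length(first) >= 3 &&
    is.na(suppressWarnings(as.numeric(first[[3]])))
  df <- utils::read.table(path, sep = "\t", header = header,
                          col.names = c("id_a", "id_b", "label"),
                          colClasses = c("character", "character",
                                         "integer"))
  df
}

#' Extract LPQ features for proteins given FASTA and optional PSSM files
#'
#' For each FASTA record, uses the PSI-BLAST ASCII PSSM file
#' `<pssm_dir>/<id>.pssm` when present, otherwise falls back to the
#' internal Dayhoff-formula PSSM of the sequence, then computes the
#' normalized LPQ histogram.
#'
#' @param fasta Path to a FASTA file.
#' @param pssm_dir Optional directory of per-protein ASCII PSSM files.
#' @param lpq An [lpq_config()].
#' @return Feature matrix, one row per protein (rownames = ids).
#' @export
featurize_from_files <- function(fasta, pssm_dir = NULL,
                                 lpq = lpq_config()) {
  seqs <- read_fasta(fasta)
  pssms <- lapply(seq_len(nrow(seqs)), function(i) {
    id <- seqs$id[[i]]
    f <- if (!is.null(pssm_dir)) file.path(pssm_dir, paste0(id, ".pssm"))
    if (!is.null(f) && file.exists(f)) {
      read_psiblast_pssm(f)
    } else {
      pssm_from_sequence(seqs$residues[[i]])
    }
  })
  names(pssms) <- seqs$id
  featurize_pssms(pssms, lpq)
}
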