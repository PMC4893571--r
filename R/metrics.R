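#' Confusion counts for binary labels
#'
#' Tallies true/false positives and negatives, with 1 = interacting =
#' positive.
#'
#' @param truth,pred Equal-length vectors with values in \{0, 1\}.
#' @return Object of class `confusion_counts` with fields `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop("truth and pred must have equal length")
  }
  truth <- as.numeric(truth); pred <- as.numeric(pred)
  if (!all(truth %in% c(0, 1)) || !all(pred %in% c(0, 1))) {
    stop("labels must be 0 or 1")
  }
  structure(list(
    tp = sum(truth == 1 & pred == 1),
    tn = sum(truth == 0 & pred == 0),
    fp = sum(truth == 0 & pred == 1),
    fn = sum(truth == 1 & pred == 0)
  ), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy Ac = (TP+TN)/(TP+FP+TN+FN), sensitivity Sn = TP/(TP+FN),
#' specificity Sp = TN/(FP+TN), precision Pe = TP/(FP+TP), and the
#' Matthews correlation coefficient
#' MCC = (TP TN - FP FN) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN)).
#' A metric whose denominator is zero is reported as `NA` and listed in
#' the `undefined` field rather than propagating NaN.
#'
#' @param counts A `confusion_counts` object (or list with tp/tn/fp/fn).
#' @return Object of class `metric_report`: numeric `ac`, `sn`, `sp`,
#'   `pe`, `mcc` plus a character vector `undefined`.
#' @export
metric_report <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  stopifnot(all(c(tp, tn, fp, fn) >= 0))
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion counts")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tp + fp) * sqrt(tn + fn)
  out <- list(
    ac = (tp + tn) / total,
    sn = safe(tp, tp + fn),
    sp = safe(tn, fp + tn),
    pe = safe(tp, fp + tp),
    mcc = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  )
  out$undefined <- names(out)[vapply(out, is.na, logical(1))]
  structure(out, class = "metric_report")
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores, tallying the
#' false and true positive rates at each, and integrates the curve by
#' the trapezoid rule.
#'
#' @param scores Numeric classifier scores (larger = more positive).
#' @param truth Labels in \{0, 1\}; both classes must be present.
#' @return List with `points` (data frame `threshold`, `fpr`, `tpr`
#'   ordered by increasing FPR, including the (0,0) and (1,1)
#'   endpoints) and scalar `auc`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.numeric(truth)
  if (length(scores) != length(truth)) stop("length mismatch")
  if (!all(truth %in% c(0, 1))) stop("labels must be 0 or 1")
  np <- sum(truth == 1); nn <- sum(truth == 0)
  if (np == 0 || nn == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  # cumulative counts just below each distinct threshold
  idx <- which(!duplicated(s, fromLast = TRUE))  # last of each tie group
  tpr <- c(0, cumsum(y)[idx] / np)
  fpr <- c(0, cumsum(1 - y)[idx] / nn)
  thr <- c(Inf, s[idx])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Shuffled k-fold split
#'
#' Partitions `1:n` into k disjoint test folds of near-equal size
#' (differing by at most one), after a seeded shuffle; reproducible for
#' a given seed.
#'
#' @param n Number of samples, `n >= k`.
#' @param k Number of folds, `k >= 2`.
#' @param seed Integer RNG seed.
#' @return List of k elements, each `list(train = ..., test = ...)`
#'   index vectors; the test folds cover `1:n` exactly once.
#' @export
kfold_split <- function(n, k, seed = 1) {
  if (k < 2 || n < k) stop("need k >= 2 and n >= k")
  perm <- with_preserved_seed(seed, sample.int(n))
  fold_id <- sort(rep(seq_len(k), length.out = n))
  lapply(seq_len(k), function(f) {
    test <- perm[fold_id == f]
    list(train = sort(setdiff(seq_len(n), test)), test = sort(test))
  })
}

#' Mean and standard deviation over folds
#'
#' Aggregates per-fold metric values as mean plus sample standard
#' deviation (n - 1 denominator).
#'
#' @param values Numeric vector of per-fold values (NAs dropped).
#' @return Named numeric vector `c(mean, sd)`.
#' @export
fold_aggregate <- function(values) {
  values <- values[!is.na(values)]
  c(mean = mean(values), sd = stats::sd(values))
}
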