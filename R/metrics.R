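#' Confusion-matrix metrics for binary patch predictions
#'
#' Standard definitions with the malignant class as positive: accuracy,
#' precision, recall (sensitivity), specificity, F-measure, and the error
#' rates FNR = 1 - recall, FPR = 1 - specificity. A ratio with a zero
#' denominator is reported as 0 and listed in the `undefined` field.
#'
#' @param predictions 0/1 predictions.
#' @param labels 0/1 reference labels (1 = malignant).
#' @return object of class `octx_metrics`: list with `tp`, `tn`, `fp`,
#'   `fn`, `accuracy`, `precision`, `recall`, `specificity`, `f_measure`,
#'   `fnr`, `fpr`, `undefined` (character vector of flagged metrics).
#' @export
confusion_metrics <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels))
  if (!length(labels)) stop("empty input")
  predictions <- as.integer(predictions)
  labels <- as.integer(labels)
  stopifnot(all(predictions %in% 0:1), all(labels %in% 0:1))
  tp <- sum(predictions == 1 & labels == 1)
  tn <- sum(predictions == 0 & labels == 0)
  fp <- sum(predictions == 1 & labels == 0)
  fn <- sum(predictions == 0 & labels == 1)
  undefined <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(0) }
    num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  specificity <- safe(tn, tn + fp, "specificity")
  f_measure <- safe(2 * precision * recall, precision + recall, "f_measure")
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = (tp + tn) / length(labels),
                 precision = precision, recall = recall,
                 specificity = specificity, f_measure = f_measure,
                 fnr = 1 - recall, fpr = 1 - specificity,
                 undefined = undefined),
            class = "octx_metrics")
}

#' @export
print.octx_metrics <- function(x, ...) {
  cat(sprintf(
    "<octx_metrics> acc %.4f | prec %.4f | recall %.4f | spec %.4f | F1 %.4f\n",
    x$accuracy, x$precision, x$recall, x$specificity, x$f_measure))
  cat(sprintf("  TP %d TN %d FP %d FN %d | FNR %.4f FPR %.4f\n",
              x$tp, x$tn, x$fp, x$fn, x$fnr, x$fpr))
  if (length(x$undefined))
    cat("  undefined (reported as 0):", paste(x$undefined, collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
as.data.frame.octx_metrics <- function(x, ...) {
  data.frame(tp = x$tp, tn = x$tn, fp = x$fp, fn = x$fn,
             accuracy = x$accuracy, precision = x$precision,
             recall = x$recall, specificity = x$specificity,
             f_measure = x$f_measure, fnr = x$fnr, fpr = x$fpr)
}

#' ROC curve and AUC (rank / Mann-Whitney form)
#'
#' AUC is the probability that a uniformly drawn positive outscores a
#' uniformly drawn negative, with ties counted 1/2 — computed from rank
#' sums, which is exact and O(n log n). The curve lists `(FPR, TPR)` at
#' every distinct score threshold (descending), prefixed by `(0, 0)`.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels 0/1 labels, both classes present.
#' @return list with `auc` and `curve` (data.frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n_neg, 0)
  curve <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0),
                 data.frame(threshold = thr, fpr = fpr, tpr = tpr))
  list(auc = auc, curve = curve)
}

#' Unweighted macro-average across channels
#'
#' @param values per-channel numeric values (percentages or fractions).
#' @return arithmetic mean rounded to 2 decimals for reporting.
#' @export
#' @examples
#' macro_average(c(93.26, 96.32, 90.20, 92.75)) # 93.13
macro_average <- function(values) {
  if (!length(values)) stop("no values to average")
  round(mean(values), 2)
}

#' Per-channel dataset summary with class-balance tests
#'
#' Reproduces the shape of a dataset statistics table: per-channel totals,
#' per-split benign/malignant counts, class percentages (1 decimal) and a
#' two-sided exact binomial test of the 50/50 balance null.
#'
#' @param manifest data.frame from [dataset_manifest()] (columns `channel`,
#'   `split`, `label`), possibly covering several channels.
#' @return data.frame, one row per channel: `channel`, `total`,
#'   `n_benign`, `n_malignant`, per-split counts (`train_b`, `train_m`,
#'   `test_b`, `test_m`, `val_b`, `val_m`), `pct_benign`, `pct_malignant`,
#'   `balance_p`.
#' @export
dataset_summary <- function(manifest) {
  stopifnot(all(c("channel", "split", "label") %in% names(manifest)))
  do.call(rbind, lapply(split(manifest, manifest$channel), function(m) {
    nb <- sum(m$label == 0); nm <- sum(m$label == 1)
    cnt <- function(s, l) sum(m$split == s & m$label == l)
    data.frame(channel = m$channel[1], total = nrow(m),
               n_benign = nb, n_malignant = nm,
               train_b = cnt("train", 0), train_m = cnt("train", 1),
               test_b = cnt("test", 0), test_m = cnt("test", 1),
               val_b = cnt("val", 0), val_m = cnt("val", 1),
               pct_benign = round(100 * nb / nrow(m), 1),
               pct_malignant = round(100 * nm / nrow(m), 1),
               balance_p = stats::binom.test(nb, nrow(m), 0.5)$p.value,
               stringsAsFactors = FALSE)
  }))
}
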