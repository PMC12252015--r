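# Confusion-matrix machinery and classification metrics.
#
# Per class: precision = tp / (tp + fp), recall = tp / (tp + fn),
# F1 = 2 P R / (P + R); accuracy = trace / total. Macro values are
# unweighted class means (micro values also reported). 0/0 -> 0.

#' Confusion matrix and one-vs-rest counts
#'
#' @param predicted,truth Equal-length class label vectors: integers in
#'   `1..C`, or factors/characters matched against `classes`.
#' @param C Number of classes (inferred from `classes` when given).
#' @param classes Optional class-name vector used to map labels and label
#'   the matrix.
#' @return A `confusion_counts` object: `matrix` (rows = true class,
#'   columns = predicted class) and per-class `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_matrix <- function(predicted, truth, C = NULL, classes = NULL) {
  if (length(predicted) != length(truth))
    stopf("predicted and truth lengths differ (%d vs %d)",
          length(predicted), length(truth))
  if (!is.null(classes)) {
    C <- length(classes)
    to_idx <- function(v) {
      i <- match(as.character(v), classes)
      if (anyNA(i)) stopf("labels outside the class list: %s",
                          paste(unique(v[is.na(i)]), collapse = ", "))
      i
    }
    predicted <- to_idx(predicted); truth <- to_idx(truth)
  } else {
    predicted <- as.integer(predicted); truth <- as.integer(truth)
    C <- as.integer(C %||% max(predicted, truth, 1L))
  }
  if (any(predicted < 1L | predicted > C) || any(truth < 1L | truth > C))
    stopf("labels out of range 1..%d", C)
  M <- matrix(tabulate((predicted - 1L) * C + truth, nbins = C * C), C, C)
  if (!is.null(classes)) dimnames(M) <- list(truth = classes, predicted = classes)
  tp <- diag(M)
  fp <- colSums(M) - tp
  fn <- rowSums(M) - tp
  tn <- sum(M) - tp - fp - fn
  structure(list(matrix = M, tp = tp, fp = fp, tn = tn, fn = fn,
                 total = sum(M), classes = classes),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' @param counts A `confusion_counts` object from [confusion_matrix()].
#' @return A `metrics_report`: `accuracy`, `macro_precision`,
#'   `macro_recall`, `macro_f1`, their micro counterparts, and a per-class
#'   data frame. All values are percentages.
#' @export
metrics_from_confusion <- function(counts) {
  if (!inherits(counts, "confusion_counts")) stopf("need confusion_counts")
  if (counts$total == 0) stopf("empty confusion counts")
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  P <- safe_div(counts$tp, counts$tp + counts$fp)
  R <- safe_div(counts$tp, counts$tp + counts$fn)
  F1 <- safe_div(2 * P * R, P + R)
  acc <- sum(counts$tp) / counts$total
  microP <- safe_div(sum(counts$tp), sum(counts$tp + counts$fp))
  microR <- safe_div(sum(counts$tp), sum(counts$tp + counts$fn))
  microF1 <- safe_div(2 * microP * microR, microP + microR)
  per_class <- data.frame(
    class = counts$classes %||% seq_along(P),
    precision = 100 * P, recall = 100 * R, f1 = 100 * F1,
    support = rowSums(counts$matrix))
  structure(list(accuracy = 100 * acc,
                 macro_precision = 100 * mean(P),
                 macro_recall = 100 * mean(R),
                 macro_f1 = 100 * mean(F1),
                 micro_precision = 100 * microP,
                 micro_recall = 100 * microR,
                 micro_f1 = 100 * microF1,
                 per_class = per_class),
            class = "metrics_report")
}

#' Harmonic-mean F1 from precision and recall percentages
#'
#' @param precision,recall Percentages.
#' @return F1 percentage, `2 P R / (P + R)` (0 when both are 0).
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}
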