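# Confusion-matrix construction and derived metrics (accuracy, precision,
# recall, F1) per class and aggregate.

#' Confusion counts from predictions and truth
#'
#' Builds the full C x C count matrix (`counts[i, j]` = number of samples
#' with truth class `i-1` predicted as class `j-1`) together with the
#' one-vs-rest TP/FP/FN/TN reductions per class.
#'
#' @param pred,truth Integer vectors of 0-based class ids, equal length.
#' @param n_classes Number of classes C (ids must be `< C`).
#' @return An object of class `confusion_counts` with elements `matrix`,
#'   `tp`, `fp`, `fn`, `tn`, `n`.
#' @export
confusion <- function(pred, truth, n_classes) {
  if (length(pred) != length(truth)) {
    stop_invalid("`pred` and `truth` must have equal length (%d vs %d)",
                 length(pred), length(truth))
  }
  if (length(pred) && (max(pred, truth) >= n_classes || min(pred, truth) < 0)) {
    stop_invalid("class ids must lie in [0, %d)", n_classes)
  }
  lv <- 0:(n_classes - 1L)
  m <- unclass(table(factor(truth, levels = lv), factor(pred, levels = lv)))
  dimnames(m) <- list(truth = lv, pred = lv)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  n <- sum(m)
  structure(list(matrix = m, tp = tp, fp = fp, fn = fn,
                 tn = n - tp - fp - fn, n = n),
            class = "confusion_counts")
}

safe_div <- function(num, den) ifelse(den > 0, num / den, 0)

#' Classification metrics from confusion counts
#'
#' Computes overall accuracy (`trace/n` for the multi-class matrix), the
#' one-vs-rest accuracy `(TP+TN)/(TP+TN+FP+FN)` per class, precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)`, `F1 = 2PR/(P+R)`, their macro
#' averages, and the row-normalized confusion matrix.  Zero-denominator
#' cases yield 0 and are flagged, never an error.
#'
#' @param counts A [confusion()] result, or a prediction vector (with
#'   `truth`/`n_classes` supplied) to tally first.
#' @param truth,n_classes Used only when `counts` is a prediction vector.
#' @return An object of class `eval_report`.
#' @export
eval_metrics <- function(counts, truth = NULL, n_classes = NULL) {
  if (!inherits(counts, "confusion_counts")) {
    counts <- confusion(counts, truth, n_classes)
  }
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  support <- rowSums(counts$matrix)
  norm <- counts$matrix
  zero_rows <- support == 0
  norm[!zero_rows, ] <- norm[!zero_rows, , drop = FALSE] / support[!zero_rows]
  flags <- list(zero_precision_den = which(tp + fp == 0),
                zero_recall_den = which(tp + fn == 0),
                zero_support = which(zero_rows))
  structure(list(
    accuracy = safe_div(sum(tp), counts$n),
    ovr_accuracy = safe_div(tp + tn, tp + tn + fp + fn),
    precision = precision, recall = recall, f1 = f1,
    macro_precision = mean(precision), macro_recall = mean(recall),
    macro_f1 = mean(f1),
    normalized_matrix = norm, support = support,
    counts = counts, flags = flags
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat(sprintf("<eval_report> n=%d  accuracy=%.*f  macro-F1=%.*f\n",
              x$counts$n, digits, x$accuracy, digits, x$macro_f1))
  tab <- data.frame(precision = round(x$precision, digits),
                    recall = round(x$recall, digits),
                    f1 = round(x$f1, digits),
                    support = x$support)
  print(tab)
  invisible(x)
}

#' Segment- and record-level F1 for the AF task
#'
#' Computes the positive-class (AF) F1 at segment level and after
#' majority-vote aggregation of segment predictions per source recording.
#'
#' @param pred Integer 0/1 segment predictions.
#' @param truth Integer 0/1 segment labels.
#' @param source_id Recording identifier per segment.
#' @return List with `segment_f1`, `record_f1`, and the two [eval_metrics()]
#'   reports.
#' @export
af_f1 <- function(pred, truth, source_id) {
  seg <- eval_metrics(pred, truth, 2L)
  vote <- function(v) as.integer(mean(v) > 0.5)
  rp <- vapply(split(pred, source_id), vote, integer(1))
  rt <- vapply(split(truth, source_id), function(v) as.integer(v[1L]), integer(1))
  rec <- eval_metrics(rp, rt, 2L)
  list(segment_f1 = unname(seg$f1[2L]), record_f1 = unname(rec$f1[2L]),
       segment_report = seg, record_report = rec)
}
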