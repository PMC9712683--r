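#' Confusion counts from hard predictions
#'
#' @param predicted Predicted binary labels (0/1).
#' @param truth True binary labels (0/1).
#' @return Named integer vector with elements `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  predicted <- as.integer(predicted)
  truth <- as.integer(truth)
  c(TP = sum(predicted == 1L & truth == 1L),
    TN = sum(predicted == 0L & truth == 0L),
    FP = sum(predicted == 1L & truth == 0L),
    FN = sum(predicted == 0L & truth == 1L))
}

#' Threshold classification metrics from a confusion table
#'
#' Accuracy, sensitivity (recall), specificity, precision, F-measure and
#' Matthews correlation coefficient from TP/TN/FP/FN counts. MCC uses the
#' standard formula (TP*TN - FP*FN) over the square root of the four
#' marginal products; when any marginal is zero MCC is defined as 0.
#' Undefined ratios from a zero denominator (e.g. precision with no
#' positive predictions) are reported as `NA`.
#'
#' @param confusion Named vector or list with `TP`, `TN`, `FP`, `FN`.
#' @return An `afp_eval` object (threshold metrics only; `auroc`/`aupr`
#'   are `NA` until scores are evaluated).
#' @examples
#' compute_metrics(c(TP = 40, TN = 45, FP = 5, FN = 10))
#' @export
compute_metrics <- function(confusion) {
  cc <- unlist(confusion)[c("TP", "TN", "FP", "FN")]
  if (anyNA(cc) || any(cc < 0)) stop("confusion needs non-negative TP, TN, FP, FN")
  n <- sum(cc)
  if (n == 0) stop("all-zero confusion table")
  tp <- as.numeric(cc[["TP"]]); tn <- as.numeric(cc[["TN"]])
  fp <- as.numeric(cc[["FP"]]); fn <- as.numeric(cc[["FN"]])
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  sn <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  marg <- c(tp + fn, tp + fp, tn + fn, tn + fp)
  mcc <- if (any(marg == 0)) 0 else
    (tp * tn - fp * fn) / sqrt(prod(marg))
  f <- if (is.na(prec) || is.na(sn) || prec + sn == 0) NA_real_ else
    2 * prec * sn / (prec + sn)
  structure(
    list(acc = (tp + tn) / n, sn = sn, sp = sp, precision = prec,
         recall = sn, f_measure = f, mcc = mcc,
         auroc = NA_real_, aupr = NA_real_,
         confusion = cc, fold_breakdown = NULL),
    class = "afp_eval"
  )
}

#' ROC and precision-recall curves from scores
#'
#' Sweeps every distinct score as a decision threshold (tied scores are
#' grouped into a single operating point), returning both curves and
#' their areas: ROC area by the trapezoid rule, PR area by step-wise
#' interpolation (each recall increment weighted by the precision at that
#' threshold). When all scores are equal the ROC collapses to the single
#' point (1, 1) and the area is exactly 0.5.
#'
#' @param scores Numeric scores, higher meaning more positive.
#' @param labels Binary labels (0/1); both classes must be present.
#' @return List with `roc` and `pr` data frames, `auroc` and `aupr`.
#' @export
roc_and_pr <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y == 1L); fp <- cumsum(y == 0L)
  idx <- cumsum(rle(s)$lengths)  # last index of each tie group
  tpr <- tp[idx] / P
  fpr <- fp[idx] / N
  prec <- tp[idx] / (tp[idx] + fp[idx])
  roc <- data.frame(threshold = c(Inf, s[idx]),
                    fpr = c(0, fpr), tpr = c(0, tpr))
  pr <- data.frame(threshold = s[idx], recall = tpr, precision = prec)
  auroc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  aupr <- sum(diff(c(0, pr$recall)) * pr$precision)
  list(roc = roc, pr = pr, auroc = auroc, aupr = aupr)
}

#' @export
print.afp_eval <- function(x, digits = 4, ...) {
  cat("afp_eval (", sum(x$confusion), " records)\n", sep = "")
  cat(sprintf("  Acc %6.2f%%  Sn %6.2f%%  Sp %6.2f%%  F %6.2f%%  MCC %.*f\n",
              100 * x$acc, 100 * x$sn, 100 * x$sp, 100 * x$f_measure,
              2, x$mcc))
  if (!is.na(x$auroc)) {
    cat(sprintf("  AuROC %.*f  AuPR %.*f\n", digits, x$auroc, digits, x$aupr))
  }
  cat("  confusion: TP", x$confusion[["TP"]], " TN", x$confusion[["TN"]],
      " FP", x$confusion[["FP"]], " FN", x$confusion[["FN"]], "\n")
  if (!is.null(x$fold_breakdown)) {
    cat("  (", length(x$fold_breakdown), " folds pooled)\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.afp_eval <- function(object, ...) {
  out <- data.frame(
    metric = c("acc", "sn", "sp", "precision", "f_measure", "mcc",
               "auroc", "aupr"),
    value = c(object$acc, object$sn, object$sp, object$precision,
              object$f_measure, object$mcc, object$auroc, object$aupr)
  )
  if (!is.null(object$fold_breakdown)) {
    fold_acc <- vapply(object$fold_breakdown, function(f) f$acc, numeric(1))
    out$fold_mean <- c(mean(fold_acc), rep(NA, nrow(out) - 1L))
  }
  out
}
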