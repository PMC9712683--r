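#' Stratified k-fold assignment
#'
#' Splits records into k folds of near-equal size with per-class counts
#' differing by at most one record across folds. Deterministic given the
#' seed.
#'
#' @param y Binary labels; each class must have at least `k` members.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:k`, one per record.
#' @export
stratified_kfold <- function(y, k = 10, seed = 1) {
  y <- as.integer(y)
  k <- as.integer(k)
  stopifnot(k >= 2L)
  if (k == length(y)) {
    # leave-one-out boundary: singleton folds, stratification vacuous
    return(seq_along(y))
  }
  tab <- table(y)
  if (any(tab < k)) {
    small <- names(tab)[tab < k]
    stop("class ", paste(small, collapse = ", "), " has fewer than k = ",
         k, " members")
  }
  set.seed(as.integer(seed))
  folds <- caret::createFolds(factor(y), k = k, list = TRUE,
                              returnTrain = FALSE)
  assignment <- integer(length(y))
  for (i in seq_along(folds)) assignment[folds[[i]]] <- i
  assignment
}

#' Cross-validated evaluation of a classifier
#'
#' Runs stratified k-fold cross-validation: each fold is held out once,
#' the model is trained on the remainder, and held-out scores are
#' collected. Threshold metrics come from the confusion counts pooled
#' over folds (micro-average); AuROC/AuPR from the pooled scores.
#' Per-fold reports (macro view) are kept in `fold_breakdown`.
#'
#' @param x Named numeric feature matrix.
#' @param y Binary labels.
#' @param config A [model_config()].
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return An `afp_eval` with pooled metrics, curves, pooled `scores`,
#'   the fold assignment, and `fold_breakdown`.
#' @export
cross_validate <- function(x, y, config = model_config(), k = 10, seed = 1) {
  d <- check_xy(x, y)
  folds <- stratified_kfold(d$y, k = k, seed = seed)
  scores <- numeric(length(d$y))
  breakdown <- vector("list", max(folds))
  for (i in seq_len(max(folds))) {
    test <- folds == i
    fit <- afp_train(d$x[!test, , drop = FALSE], d$y[!test], config)
    scores[test] <- predict(fit, d$x[test, , drop = FALSE])
    fold_cc <- confusion_counts(as.integer(scores[test] > 0.5), d$y[test])
    rep_i <- compute_metrics(fold_cc)
    if (length(unique(d$y[test])) == 2L) {
      curves <- roc_and_pr(scores[test], d$y[test])
      rep_i$auroc <- curves$auroc
      rep_i$aupr <- curves$aupr
    }
    breakdown[[i]] <- rep_i
  }
  report <- compute_metrics(confusion_counts(as.integer(scores > 0.5), d$y))
  curves <- roc_and_pr(scores, d$y)
  report$auroc <- curves$auroc
  report$aupr <- curves$aupr
  report$fold_breakdown <- breakdown
  report$scores <- scores
  report$labels <- d$y
  report$folds <- folds
  report
}

#' Class-imbalance ablation
#'
#' Draws seeded subsamples of the dataset at fixed positive:negative
#' counts (defaults 300:300, 300:600 and 300:900), cross-validates the
#' classifier on each draw, and reports the metrics per ratio — the
#' protocol for measuring how class imbalance erodes sensitivity.
#'
#' @param x Named numeric feature matrix.
#' @param y Binary labels.
#' @param ratios Named list of `c(n_pos, n_neg)` draw sizes.
#' @param config A [model_config()].
#' @param k CV folds per ratio.
#' @param seed Seed for both the draws and the fold assignments.
#' @return Named list of `afp_eval` reports, class `afp_ablation`.
#' @export
imbalance_ablation <- function(x, y,
                               ratios = list(`1:1` = c(300, 300),
                                             `1:2` = c(300, 600),
                                             `1:3` = c(300, 900)),
                               config = model_config(), k = 10, seed = 1) {
  d <- check_xy(x, y)
  pos <- which(d$y == 1L); neg <- which(d$y == 0L)
  out <- vector("list", length(ratios))
  names(out) <- names(ratios)
  for (i in seq_along(ratios)) {
    np <- ratios[[i]][1]; nn <- ratios[[i]][2]
    if (length(pos) < np || length(neg) < nn) {
      stop("ratio ", names(ratios)[i], " needs ", np, " positives and ",
           nn, " negatives; have ", length(pos), " and ", length(neg))
    }
    set.seed(as.integer(seed) + i)
    take <- c(sample(pos, np), sample(neg, nn))
    out[[i]] <- cross_validate(d$x[take, , drop = FALSE], d$y[take],
                               config = config, k = k, seed = seed + i)
    out[[i]]$draw <- take
  }
  class(out) <- "afp_ablation"
  out
}

#' @export
print.afp_ablation <- function(x, ...) {
  cat("afp_ablation across", length(x), "ratios\n")
  for (nm in names(x)) {
    r <- x[[nm]]
    cat(sprintf("  %-5s Acc %6.2f%%  Sn %6.2f%%  Sp %6.2f%%  MCC %5.2f  AuROC %.4f  AuPR %.4f\n",
                nm, 100 * r$acc, 100 * r$sn, 100 * r$sp, r$mcc,
                r$auroc, r$aupr))
  }
  invisible(x)
}

#' Plot an evaluation report
#'
#' Draws the pooled ROC curve (and optionally the precision-recall
#' curve) of a cross-validated report.
#'
#' @param x An `afp_eval` carrying pooled `scores`.
#' @param which `"roc"`, `"pr"` or `"both"`.
#' @param ... Passed to [plot()].
#' @export
plot.afp_eval <- function(x, which = c("roc", "pr", "both"), ...) {
  which <- match.arg(which)
  if (is.null(x$scores) || is.null(x$labels)) {
    stop("report carries no pooled scores to plot")
  }
  curves <- roc_and_pr(x$scores, x$labels)
  if (which %in% c("roc", "both")) {
    plot(curves$roc$fpr, curves$roc$tpr, type = "l",
         xlab = "False positive rate", ylab = "True positive rate",
         main = sprintf("ROC (AuROC %.4f)", curves$auroc), ...)
    graphics::abline(0, 1, lty = 3)
  }
  if (which %in% c("pr", "both")) {
    plot(curves$pr$recall, curves$pr$precision, type = "s",
         xlab = "Recall", ylab = "Precision",
         main = sprintf("PR (AuPR %.4f)", curves$aupr), ...)
  }
  invisible(x)
}
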