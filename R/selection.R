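#' Recursive feature elimination with extremely randomized trees (ERT-RFE)
#'
#' At each iteration an extremely-randomized-tree ensemble is fit on the
#' surviving features, impurity importances are computed, the
#' cross-validated accuracy of the subset is recorded, and the lowest-
#' importance features are removed (ties broken lexicographically,
#' dropping the later name first). The loop ends at `min_features`; the
#' subset with the maximal cross-validated accuracy wins, ties going to
#' the smaller subset. The inner scorer is stratified k-fold accuracy
#' with folds fixed once per call, so subset scores are comparable across
#' iterations.
#'
#' @param x Named numeric feature matrix.
#' @param y Binary labels (both classes present).
#' @param step Features removed per iteration: an integer >= 1, or a
#'   fraction in (0, 1) of the surviving count (at least one).
#' @param cv_folds Inner folds for subset scoring (default 5, kept
#'   distinct from the outer 10-fold evaluation protocol).
#' @param min_features Smallest subset to reach.
#' @param n_trees Ensemble size per fit (default 250).
#' @param seed Seed fixing folds and every ensemble; the whole trace is
#'   reproducible.
#' @return An object of class `ert_rfe`: `iterations` (per-iteration
#'   feature names, importances and CV accuracy), `best_iteration`,
#'   `selected` (winning feature names).
#' @seealso [apply_selection()], [select_per_encoder()]
#' @export
ert_rfe <- function(x, y, step = 1, cv_folds = 5, min_features = 1,
                    n_trees = 250, seed = 1) {
  d <- check_xy(x, y)
  stopifnot(step > 0, min_features >= 1)
  df <- as.data.frame(d$x)
  yf <- factor(d$y, levels = c(0L, 1L))
  folds <- stratified_kfold(d$y, k = cv_folds, seed = seed)

  ert_fit <- function(cols, rows = NULL, importance = "none") {
    if (is.null(rows)) rows <- seq_along(yf)
    ranger::ranger(
      x = df[rows, cols, drop = FALSE], y = yf[rows],
      num.trees = n_trees, splitrule = "extratrees",
      num.random.splits = 1, replace = FALSE, sample.fraction = 1,
      importance = importance, seed = seed, num.threads = 1
    )
  }
  cv_accuracy <- function(cols) {
    correct <- 0L
    for (i in seq_len(max(folds))) {
      test <- folds == i
      fit <- ert_fit(cols, rows = which(!test))
      pred <- stats::predict(fit, data = df[test, cols, drop = FALSE],
                             num.threads = 1)$predictions
      correct <- correct + sum(pred == yf[test])
    }
    correct / length(yf)
  }

  surviving <- colnames(d$x)
  iterations <- list()
  repeat {
    fit <- ert_fit(surviving, importance = "impurity")
    imp <- fit$variable.importance[surviving]
    iterations[[length(iterations) + 1L]] <- list(
      size = length(surviving),
      features = surviving,
      importance = imp,
      cv_accuracy = cv_accuracy(surviving)
    )
    if (length(surviving) <= min_features) break
    n_drop <- if (step < 1) max(1L, floor(step * length(surviving)))
              else as.integer(step)
    n_drop <- min(n_drop, length(surviving) - min_features)
    # ascending importance; within ties the lexicographically later
    # name goes first
    ord <- order(imp, xtfrm(surviving), decreasing = c(FALSE, TRUE),
                 method = "radix")
    surviving <- setdiff(surviving, surviving[ord[seq_len(n_drop)]])
  }
  acc <- vapply(iterations, function(it) it$cv_accuracy, numeric(1))
  best <- max(which(acc == max(acc)))  # sizes decrease, so last = smallest
  structure(
    list(iterations = iterations, best_iteration = best,
         selected = iterations[[best]]$features,
         step = step, cv_folds = cv_folds, min_features = min_features,
         n_trees = n_trees, seed = seed),
    class = "ert_rfe"
  )
}

#' @export
print.ert_rfe <- function(x, ...) {
  acc <- vapply(x$iterations, function(it) it$cv_accuracy, numeric(1))
  sizes <- vapply(x$iterations, function(it) it$size, numeric(1))
  cat("ert_rfe: ", sizes[1], " -> ", sizes[length(sizes)], " features over ",
      length(sizes), " iteration(s)\n", sep = "")
  cat(sprintf("  best: %d features at iteration %d (CV accuracy %.4f)\n",
              x$iterations[[x$best_iteration]]$size, x$best_iteration,
              acc[x$best_iteration]))
  invisible(x)
}

#' @export
plot.ert_rfe <- function(x, ...) {
  acc <- vapply(x$iterations, function(it) it$cv_accuracy, numeric(1))
  sizes <- vapply(x$iterations, function(it) it$size, numeric(1))
  plot(sizes, acc, type = "b", xlab = "Surviving features",
       ylab = "CV accuracy", main = "ERT-RFE elimination path", ...)
  graphics::abline(v = sizes[x$best_iteration], lty = 3)
  invisible(x)
}

#' Subset a feature matrix to a selection
#'
#' Name-based column selection in trace order; labels and row order are
#' untouched, so the same trace applies to an independent test matrix
#' with the same feature names.
#'
#' @param x Named numeric feature matrix.
#' @param trace An `ert_rfe` trace (or a character vector of names).
#' @return `x` restricted to the selected columns.
#' @export
apply_selection <- function(x, trace) {
  selected <- if (inherits(trace, "ert_rfe")) trace$selected else
    as.character(trace)
  absent <- setdiff(selected, colnames(x))
  if (length(absent) > 0L) {
    stop("selected feature(s) absent from matrix: ",
         paste(utils::head(absent, 5), collapse = ", "))
  }
  x[, selected, drop = FALSE]
}

#' Per-encoder ERT-RFE
#'
#' Runs [ert_rfe()] independently inside each encoder block (features
#' grouped by the prefix before the first `.` in their name) and fuses
#' the per-block winners — the pathway that reduces each descriptor to
#' its own optimal subset before combining them into one super set.
#'
#' @inheritParams ert_rfe
#' @return List with `traces` (one `ert_rfe` per block), `selected`
#'   (fused winning names) and `matrix` (`x` restricted to them).
#' @export
select_per_encoder <- function(x, y, step = 1, cv_folds = 5,
                               min_features = 1, n_trees = 250, seed = 1) {
  prefixes <- sub("\\..*$", "", colnames(x))
  traces <- list()
  for (tag in unique(prefixes)) {
    block <- x[, prefixes == tag, drop = FALSE]
    traces[[tag]] <- ert_rfe(block, y, step = step, cv_folds = cv_folds,
                             min_features = min(min_features, ncol(block)),
                             n_trees = n_trees, seed = seed)
  }
  selected <- unlist(lapply(traces, function(tr) tr$selected),
                     use.names = FALSE)
  list(traces = traces, selected = selected,
       matrix = apply_selection(x, selected))
}

#' Serialize a selection trace to JSON
#'
#' @param trace An `ert_rfe` trace.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_json <- function(trace, path) {
  stopifnot(inherits(trace, "ert_rfe"))
  payload <- list(
    best_iteration = trace$best_iteration,
    selected = trace$selected,
    iterations = lapply(trace$iterations, function(it) {
      list(size = it$size, cv_accuracy = it$cv_accuracy,
           features = it$features,
           importance = as.list(it$importance))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
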