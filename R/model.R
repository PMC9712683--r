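#' Classifier configuration
#'
#' Hyperparameters for the three supported classifiers. The boosting
#' defaults are the published working point: tree depth 8, L1 penalty
#' (alpha) 1, learning rate (eta) 0.1, L2 penalty (lambda) 1, 500
#' estimators. For the bagged ensembles (`RF`, `ERT`) only
#' `n_estimators` and `seed` apply; their tree count defaults to the same
#' 500 to parallel the boosting estimator count.
#'
#' @param kind `"LXGB"` (leaf-wise gradient boosting), `"RF"` (random
#'   forest) or `"ERT"` (extremely randomized trees).
#' @param max_depth Maximum tree depth (boosting).
#' @param l1_penalty,l2_penalty L1/L2 regularization (boosting).
#' @param learning_rate Shrinkage in (0, 1] (boosting).
#' @param n_estimators Number of boosting rounds or trees.
#' @param seed Integer seed; fixes every fitted model exactly.
#' @return A list of class `model_config`.
#' @export
model_config <- function(kind = c("LXGB", "RF", "ERT"), max_depth = 8,
                         l1_penalty = 1, learning_rate = 0.1,
                         l2_penalty = 1, n_estimators = 500, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n_estimators > 0, learning_rate > 0, learning_rate <= 1,
            max_depth >= 1)
  structure(list(kind = kind, max_depth = as.integer(max_depth),
                 l1_penalty = l1_penalty, learning_rate = learning_rate,
                 l2_penalty = l2_penalty,
                 n_estimators = as.integer(n_estimators),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("model_config: ", x$kind, "\n", sep = "")
  if (x$kind == "LXGB") {
    cat(sprintf("  max_depth %d, eta %.3g, alpha %.3g, lambda %.3g, %d rounds, seed %d\n",
                x$max_depth, x$learning_rate, x$l1_penalty, x$l2_penalty,
                x$n_estimators, x$seed))
  } else {
    cat(sprintf("  %d trees, seed %d\n", x$n_estimators, x$seed))
  }
  invisible(x)
}

check_xy <- function(x, y) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("feature matrix must have column names")
  if (anyDuplicated(colnames(x))) stop("duplicate feature names")
  if (anyNA(x)) stop("missing values in feature matrix")
  y <- as.integer(y)
  stopifnot(length(y) == nrow(x), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2L) stop("both classes must be present for training")
  list(x = x, y = y)
}

#' Train a binary AFP classifier
#'
#' Fits one of the three supported classifiers to a named feature matrix
#' and 0/1 labels. `LXGB` is a leaf-wise (loss-guided) gradient-boosted
#' tree model; `RF` a random forest; `ERT` an extremely randomized tree
#' ensemble (no bootstrap, random split points). All fits are seeded and
#' single-threaded, so identical inputs reproduce identical models.
#'
#' @param x Numeric feature matrix with unique column names, one row per
#'   record.
#' @param y Binary labels (1 = AFP, 0 = non-AFP).
#' @param config A [model_config()].
#' @return An object of class `afp_model`; use [predict.afp_model()] for
#'   scores or hard labels.
#' @examples
#' set.seed(1)
#' x <- cbind(f1 = c(rnorm(20), rnorm(20, 4)), f2 = rnorm(40))
#' fit <- afp_train(x, rep(0:1, each = 20), model_config("ERT", n_estimators = 50))
#' fit
#' @export
afp_train <- function(x, y, config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  d <- check_xy(x, y)
  fit <- switch(
    config$kind,
    LXGB = {
      params <- list(objective = "binary:logistic",
                     max_depth = config$max_depth,
                     eta = config$learning_rate,
                     alpha = config$l1_penalty,
                     lambda = config$l2_penalty,
                     tree_method = "hist", grow_policy = "lossguide",
                     nthread = 1, seed = config$seed)
      xgboost::xgb.train(params = params,
                         data = xgboost::xgb.DMatrix(d$x, label = d$y),
                         nrounds = config$n_estimators, verbose = 0)
    },
    RF = ranger::ranger(
      x = as.data.frame(d$x), y = factor(d$y, levels = c(0L, 1L)),
      num.trees = config$n_estimators, probability = TRUE,
      seed = config$seed, num.threads = 1
    ),
    ERT = ranger::ranger(
      x = as.data.frame(d$x), y = factor(d$y, levels = c(0L, 1L)),
      num.trees = config$n_estimators, probability = TRUE,
      splitrule = "extratrees", num.random.splits = 1,
      replace = FALSE, sample.fraction = 1,
      seed = config$seed, num.threads = 1
    )
  )
  structure(
    list(config = config, fit = fit, feature_names = colnames(d$x),
         n_train = nrow(d$x), class_counts = table(d$y),
         fingerprint = c(n = nrow(d$x), p = ncol(d$x),
                         checksum = sum(d$x) + sum(d$y))),
    class = "afp_model"
  )
}

#' Predict from a fitted AFP classifier
#'
#' Columns of `newdata` are aligned to the training feature names by
#' name, never by position; any mismatch in the name sets is an error
#' listing the difference.
#'
#' @param object An `afp_model`.
#' @param newdata Numeric matrix with the training feature names.
#' @param type `"prob"` for scores in \[0, 1\] or `"class"` for hard 0/1
#'   labels at the 0.5 threshold.
#' @param ... Unused.
#' @return Numeric vector of scores or integer labels (empty input gives
#'   an empty vector).
#' @export
predict.afp_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  nm <- colnames(newdata)
  if (is.null(nm)) stop("newdata must carry feature names")
  extra <- setdiff(nm, object$feature_names)
  absent <- setdiff(object$feature_names, nm)
  if (length(extra) > 0L || length(absent) > 0L) {
    stop("feature-name mismatch; missing: [",
         paste(utils::head(absent, 5), collapse = ", "),
         "], unexpected: [", paste(utils::head(extra, 5), collapse = ", "), "]")
  }
  newdata <- newdata[, object$feature_names, drop = FALSE]
  if (nrow(newdata) == 0L) {
    return(if (type == "prob") numeric(0) else integer(0))
  }
  scores <- if (object$config$kind == "LXGB") {
    stats::predict(object$fit, xgboost::xgb.DMatrix(newdata))
  } else {
    stats::predict(object$fit, data = as.data.frame(newdata),
                   num.threads = 1)$predictions[, "1"]
  }
  scores <- as.numeric(scores)
  if (type == "prob") scores else as.integer(scores > 0.5)
}

#' @export
print.afp_model <- function(x, ...) {
  cat("afp_model (", x$config$kind, "): ", x$n_train, " records x ",
      length(x$feature_names), " features\n", sep = "")
  cat("  classes: ", paste(names(x$class_counts), as.integer(x$class_counts),
                           sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.afp_model <- function(object, ...) {
  print(object)
  print(object$config)
  invisible(object)
}
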