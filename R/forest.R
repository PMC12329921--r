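#' Fit a random-forest classifier on expression features
#'
#' Binary classification forest used throughout the pipeline: CART trees grown
#' on bootstrap resamples with \code{mtry} random split candidates per node and
#' the Gini criterion. Feature importance is the normalized mean decrease in
#' Gini impurity, averaged over trees, so importances are non-negative and sum
#' to one per fitted forest.
#'
#' The forest is self-contained and bit-reproducible for a given \code{seed};
#' it does not touch R's RNG state.
#'
#' @param X numeric matrix, samples in rows, transcript features in columns
#'   (typically \code{log2(TPM + 1)}; see [feature_matrix()]).
#' @param y factor or character vector of class labels, one per row of `X`,
#'   with exactly two levels present.
#' @param positive class treated as positive when computing probabilities and
#'   F1; the pipeline convention is `"wildtype"`.
#' @param n_trees number of trees. The package default is 1000; cross-validation
#'   helpers accept smaller values when runtime matters.
#' @param mtry number of candidate features per split; default
#'   `floor(sqrt(ncol(X)))`.
#' @param min_leaf minimum samples per leaf (default 1, i.e. trees grown to
#'   purity).
#' @param max_depth maximum tree depth, 0 for unlimited.
#' @param seed integer seed controlling bootstrap and feature subsampling.
#' @return object of class `"drf"`: the flattened forest, feature names,
#'   `importance` (named, sums to 1), class levels and the positive class.
#' @export
rf_fit <- function(X, y, positive = "wildtype", n_trees = 1000, mtry = NULL,
                   min_leaf = 1, max_depth = 0, seed = 1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2)
    stop("rf_fit() needs exactly two classes, got: ", paste(lev, collapse = ", "))
  if (!positive %in% lev)
    stop("positive class '", positive, "' absent from y")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  yi <- as.integer(y == positive)
  forest <- .rf_train_cpp(X, yi, as.integer(n_trees), as.integer(mtry),
                          as.integer(min_leaf), as.integer(max_depth),
                          as.integer(seed))
  imp <- as.numeric(forest$importance)
  names(imp) <- colnames(X)
  structure(
    list(forest = forest, features = colnames(X), importance = imp,
         levels = lev, positive = positive, n_trees = n_trees, mtry = mtry,
         min_leaf = min_leaf, max_depth = max_depth, seed = seed),
    class = "drf")
}

#' Predict from a fitted forest
#'
#' @param object a `"drf"` model from [rf_fit()].
#' @param newdata numeric matrix with the model's features as columns. Columns
#'   are matched by name when names are present; a mismatch is a hard error
#'   listing the differing identifiers.
#' @param type `"class"` for predicted labels, `"prob"` for the positive-class
#'   probability (mean leaf class fraction over trees).
#' @param ... unused.
#' @export
predict.drf <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    missing_f <- setdiff(object$features, colnames(newdata))
    if (length(missing_f))
      stop("newdata lacks model features: ",
           paste(head(missing_f, 5), collapse = ", "),
           if (length(missing_f) > 5) ", ...")
    newdata <- newdata[, object$features, drop = FALSE]
  } else if (ncol(newdata) != length(object$features)) {
    stop("newdata has ", ncol(newdata), " unnamed columns; model expects ",
         length(object$features))
  }
  prob <- .rf_predict_cpp(object$forest, newdata)
  if (type == "prob") return(prob)
  negative <- setdiff(object$levels, object$positive)
  ifelse(prob >= 0.5, object$positive, negative)
}

#' @export
print.drf <- function(x, ...) {
  cat("Random forest (", x$n_trees, " trees, mtry ", x$mtry, ", ",
      length(x$features), " features)\n", sep = "")
  cat("positive class:", x$positive, "\n")
  invisible(x)
}

#' Per-sample decision-path feature attributions
#'
#' Decomposes each tree prediction along its decision path: the change in
#' positive-class probability at every split is credited to the split feature
#' and averaged over trees. Row sums equal the predicted probability minus the
#' mean root probability, so positive values push a sample toward the positive
#' (wild-type) class.
#'
#' @inheritParams predict.drf
#' @return numeric matrix, samples x features, in the model's feature order.
#' @export
rf_path_attribution <- function(object, newdata) {
  stopifnot(inherits(object, "drf"))
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)))
    newdata <- newdata[, object$features, drop = FALSE]
  out <- .rf_contrib_cpp(object$forest, newdata)
  colnames(out) <- object$features
  rownames(out) <- rownames(newdata)
  out
}

#' F1 score for a designated positive class
#'
#' Harmonic mean of precision and recall. When the model never predicts the
#' positive class (undefined precision) the score is reported as 0 with a
#' warning, matching common tooling.
#'
#' @param truth true labels.
#' @param pred predicted labels.
#' @param positive label counted as positive; pipeline convention `"wildtype"`.
#' @export
f1_score <- function(truth, pred, positive = "wildtype") {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  if (tp + fp == 0) {
    warning("no positive predictions; F1 reported as 0")
    return(0)
  }
  if (tp + fn == 0) stop("no positive-class samples in truth")
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}
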