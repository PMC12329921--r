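#' Build the classifier feature matrix from a cohort
#'
#' Features are log2(TPM + 1), samples in rows, transcripts in columns. The
#' log transform stabilises the heavy right tail of TPM values; trees are
#' invariant to monotone transforms, so this choice matters only for the
#' attribution and plotting helpers.
#'
#' @param cohort a `"driver_cohort"`.
#' @param coding_only restrict to protein-coding transcripts.
#' @return numeric matrix, samples x transcripts.
#' @export
feature_matrix <- function(cohort, coding_only = FALSE) {
  stopifnot(inherits(cohort, "driver_cohort"))
  expr <- cohort$expr
  if (coding_only) expr <- expr[cohort$genes$coding, , drop = FALSE]
  t(log2(expr + 1))
}

# internal: fit on a row subset of a prebinned matrix (avoids re-sorting all
# columns for every fold/permutation refit)
.rf_fit_rows <- function(bin, features, y, rows, positive, n_trees, mtry,
                         min_leaf, max_depth, seed) {
  lev <- sort(unique(y[rows]))
  if (length(lev) != 2) stop("training rows must contain both classes")
  yi <- as.integer(y == positive)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(features))))
  forest <- .rf_train_binned_cpp(bin, yi, as.integer(rows - 1L),
                                 as.integer(n_trees), as.integer(mtry),
                                 as.integer(min_leaf), as.integer(max_depth),
                                 as.integer(seed))
  imp <- as.numeric(forest$importance)
  names(imp) <- features
  structure(list(forest = forest, features = features, importance = imp,
                 levels = lev, positive = positive, n_trees = n_trees,
                 mtry = mtry, min_leaf = min_leaf, max_depth = max_depth,
                 seed = seed), class = "drf")
}

# stratified fold assignment: within each class, shuffled round-robin
.stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

#' Stratified k-fold cross-validation of the expression classifier
#'
#' Refits the forest in each fold and scores out-of-fold predictions with the
#' wild-type class as positive. Deterministic for a given seed (folds come
#' from R's RNG seeded here; tree growth from the forest's own RNG).
#'
#' @param X feature matrix (samples x transcripts), see [feature_matrix()];
#'   restricted to labelled (mutant/wildtype) samples by the caller.
#' @param y class labels, two classes.
#' @param k number of folds (default 5); must not exceed the minority class
#'   size.
#' @param seed integer seed.
#' @param positive positive class for F1 (default `"wildtype"`).
#' @param n_trees,mtry,min_leaf,max_depth forest hyperparameters (see
#'   [rf_fit()]).
#' @param bin optional prebinned matrix from an earlier call (internal reuse).
#' @return object of class `"cv_result"`: `fold_f1`, `mean_f1`, out-of-fold
#'   predictions `oof` and probabilities `oof_prob` (named by sample when `X`
#'   has rownames), per-feature mean Gini `importance`, and the inputs needed
#'   to reproduce the run.
#' @export
run_cv <- function(X, y, k = 5, seed = 1, positive = "wildtype",
                   n_trees = 1000, mtry = NULL, min_leaf = 1, max_depth = 0,
                   bin = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  tab <- table(y)
  if (length(tab) != 2)
    stop("run_cv() needs exactly two classes, got: ",
         paste(names(tab), collapse = ", "))
  if (min(tab) < k)
    stop("minority class has ", min(tab), " samples < k = ", k,
         "; use smaller k or balance classes first")
  if (!positive %in% names(tab)) stop("positive class absent from y")

  if (is.null(bin)) bin <- .rf_bin_cpp(X)
  .cv_rows(bin, X, y, seq_along(y), k, seed, positive,
           list(n_trees = n_trees, mtry = mtry, min_leaf = min_leaf,
                max_depth = max_depth))
}

# CV on a row subset of a prebinned matrix; workhorse behind run_cv and the
# permutation loops of mode comparison. y and X span the full binned matrix;
# rows selects the samples entering this CV.
.cv_rows <- function(bin, X, y, rows, k, seed, positive, params) {
  ysub <- y[rows]
  tab <- table(ysub)
  if (length(tab) != 2) stop("rows must contain both classes")
  if (min(tab) < k)
    stop("minority class has ", min(tab), " samples < k = ", k,
         "; use smaller k or balance classes first")
  fold <- .stratified_folds(ysub, k, seed)
  oof <- character(length(rows))
  oof_prob <- numeric(length(rows))
  fold_f1 <- numeric(k)
  imp <- matrix(0, ncol(X), k)
  negative <- setdiff(names(tab), positive)

  for (f in seq_len(k)) {
    test <- rows[fold == f]
    train <- rows[fold != f]
    fit <- .rf_fit_rows(bin, colnames(X), y, train, positive, params$n_trees,
                        params$mtry, params$min_leaf, params$max_depth,
                        seed = seed * 1000L + f)
    prob <- .rf_predict_cpp(fit$forest, X[test, , drop = FALSE])
    sel <- fold == f
    oof_prob[sel] <- prob
    oof[sel] <- ifelse(prob >= 0.5, positive, negative)
    fold_f1[f] <- suppressWarnings(f1_score(y[test], oof[sel], positive))
    imp[, f] <- fit$importance
  }
  importance <- rowMeans(imp)
  names(importance) <- colnames(X)
  names(oof) <- names(oof_prob) <- rownames(X)[rows]

  structure(list(fold_f1 = fold_f1, mean_f1 = mean(fold_f1), oof = oof,
                 oof_prob = oof_prob, importance = importance, y = ysub,
                 positive = positive, k = k, seed = seed, rows = rows,
                 params = params),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(x$k, "-fold CV: mean F1 ", round(x$mean_f1, 3), " (folds: ",
      paste(round(x$fold_f1, 3), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Overfit screen: cross-validated versus held-out F1
#'
#' Stratified split into a training fraction and a holdout; 5-fold CV on the
#' training part and a single fit evaluated on the holdout. A large gap
#' between the two F1 scores flags overfitting.
#'
#' @inheritParams run_cv
#' @param train_frac fraction of samples used for training, in (0, 1).
#' @return list with `cv_f1`, `test_f1`, `gap`, and the holdout predictions.
#' @export
holdout_check <- function(X, y, train_frac = 0.9, seed = 1,
                          positive = "wildtype", k = 5, n_trees = 1000,
                          mtry = NULL, min_leaf = 1, max_depth = 0) {
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1)
    stop("train_frac must lie strictly between 0 and 1")
  X <- as.matrix(X)
  y <- as.character(y)
  set.seed(seed)
  test <- unlist(lapply(split(seq_along(y), y), function(idx)
    sample(idx, max(1, round((1 - train_frac) * length(idx))))),
    use.names = FALSE)
  train <- setdiff(seq_along(y), test)

  cv <- run_cv(X[train, , drop = FALSE], y[train], k = k, seed = seed,
               positive = positive, n_trees = n_trees, mtry = mtry,
               min_leaf = min_leaf, max_depth = max_depth)
  fit <- rf_fit(X[train, , drop = FALSE], y[train], positive = positive,
                n_trees = n_trees, mtry = mtry, min_leaf = min_leaf,
                max_depth = max_depth, seed = seed)
  pred <- predict(fit, X[test, , drop = FALSE])
  test_f1 <- suppressWarnings(f1_score(y[test], pred, positive))
  list(cv_f1 = cv$mean_f1, test_f1 = test_f1, gap = abs(cv$mean_f1 - test_f1),
       test_pred = stats::setNames(pred, rownames(X)[test]))
}

#' Per-tumour-type F1 from out-of-fold predictions
#'
#' @param cv a `"cv_result"`.
#' @param tumour_type tumour-type label per sample, aligned with the rows used
#'   in [run_cv()].
#' @return data.frame: tumour_type, f1 (NA when the type holds a single
#'   class), ratio = minority/majority class size, n_mut, n_wt, n.
#' @export
per_type_f1 <- function(cv, tumour_type) {
  stopifnot(inherits(cv, "cv_result"), length(tumour_type) == length(cv$y))
  types <- sort(unique(tumour_type))
  rows <- lapply(types, function(tt) {
    idx <- which(tumour_type == tt)
    n_wt <- sum(cv$y[idx] == cv$positive)
    n_mut <- length(idx) - n_wt
    f1 <- if (n_wt == 0 || n_mut == 0) NA_real_ else
      suppressWarnings(f1_score(cv$y[idx], cv$oof[idx], cv$positive))
    data.frame(tumour_type = tt, f1 = f1,
               ratio = min(n_mut, n_wt) / max(n_mut, n_wt),
               n_mut = n_mut, n_wt = n_wt, n = length(idx),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit the final model on all labelled samples
#'
#' The forest is trained on every labelled sample; the reported `final_f1` is
#' the cross-validated score, never resubstitution. The returned object keeps
#' the training data so it can be retrained on a feature subset for
#' cross-cohort application.
#'
#' @inheritParams run_cv
#' @param cv optionally a precomputed `"cv_result"` for these samples; run
#'   otherwise.
#' @return object of class `"driver_fit"`: `model` (a `"drf"`), `cv`,
#'   `final_f1`, `train_pred` (stored training predictions), plus the training
#'   `X` and `y`.
#' @export
fit_final <- function(X, y, seed = 1, positive = "wildtype", n_trees = 1000,
                      mtry = NULL, min_leaf = 1, max_depth = 0, k = 5,
                      cv = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (is.null(cv))
    cv <- run_cv(X, y, k = k, seed = seed, positive = positive,
                 n_trees = n_trees, mtry = mtry, min_leaf = min_leaf,
                 max_depth = max_depth)
  model <- rf_fit(X, y, positive = positive, n_trees = n_trees, mtry = mtry,
                  min_leaf = min_leaf, max_depth = max_depth, seed = seed)
  structure(list(model = model, cv = cv, final_f1 = cv$mean_f1,
                 train_pred = stats::setNames(predict(model, X), rownames(X)),
                 X = X, y = stats::setNames(y, rownames(X)), seed = seed),
            class = "driver_fit")
}

#' @export
print.driver_fit <- function(x, ...) {
  cat("Final model: F1 (CV) ", round(x$final_f1, 3), ", top Gini ",
      signif(max(x$model$importance), 3), "\n", sep = "")
  invisible(x)
}

#' Small hyperparameter grid search on a stratified holdout
#'
#' @inheritParams holdout_check
#' @param grid data.frame of candidate settings with any of the columns
#'   `n_trees`, `mtry`, `min_leaf`, `max_depth`.
#' @return list: `best` (row of `grid` with highest holdout F1, ties to the
#'   first row) and `results` (grid plus `test_f1`).
#' @export
tune_rf <- function(X, y, grid = expand.grid(mtry = c(15, 45, 90),
                                             min_leaf = c(1, 5)),
                    train_frac = 0.9, seed = 1, positive = "wildtype",
                    n_trees = 500) {
  defaults <- list(n_trees = n_trees, mtry = NULL, min_leaf = 1, max_depth = 0)
  f1s <- vapply(seq_len(nrow(grid)), function(i) {
    par <- modifyList(defaults, as.list(grid[i, , drop = FALSE]))
    hc <- holdout_check(X, y, train_frac = train_frac, seed = seed,
                        positive = positive, n_trees = par$n_trees,
                        mtry = par$mtry, min_leaf = par$min_leaf,
                        max_depth = par$max_depth)
    hc$test_f1
  }, numeric(1))
  results <- cbind(grid, test_f1 = f1s)
  list(best = grid[which.max(f1s), , drop = FALSE], results = results)
}
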