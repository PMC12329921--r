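test_that("F1 agrees with brute-force confusion-count arithmetic", {
  # TP=5, FP=1, FN=1 with wildtype positive
  truth <- c(rep("wildtype", 6), rep("mutant", 3))
  pred <- c(rep("wildtype", 5), "mutant", "wildtype", "mutant", "mutant")
  expect_equal(f1_score(truth, pred), oracle_f1(5, 1, 1))
  expect_equal(f1_score(truth, pred), 5 / 6, tolerance = 1e-12)
  # swapping the positive-class convention is predicted by the same counts:
  # mutant-positive confusion is TP=2, FP=1, FN=1
  expect_equal(f1_score(truth, pred, positive = "mutant"), oracle_f1(2, 1, 1))
  # no positive predictions -> 0 with a warning
  expect_warning(
    f0 <- f1_score(c("wildtype", "mutant"), c("mutant", "mutant")),
    "no positive predictions")
  expect_equal(f0, 0)
})

test_that("a perfectly separable duplicated feature gives F1 = 1 everywhere", {
  set.seed(9)
  n <- 80
  y <- rep(c("mutant", "wildtype"), each = n / 2)
  sep <- ifelse(y == "wildtype", 5, 0) + runif(n, 0, 0.5)
  X <- cbind(f1 = sep, f2 = sep)
  rownames(X) <- paste0("s", seq_len(n))
  cv <- run_cv(X, y, n_trees = 30, seed = 1)
  expect_equal(cv$mean_f1, 1)
  hc <- holdout_check(X, y, n_trees = 30, seed = 1)
  expect_equal(hc$test_f1, 1)
  expect_equal(hc$cv_f1, 1)
})

test_that("cross-validation satisfies its structural invariants", {
  co <- small_cohort()
  lx <- labelled_xy(co, "PANX")
  cv <- run_cv(lx$X, lx$y, n_trees = 40, seed = 7)
  # out-of-fold predictions cover every sample exactly once
  expect_setequal(names(cv$oof), names(lx$y))
  expect_false(anyNA(cv$oof))
  expect_length(cv$fold_f1, 5)
  expect_true(all(cv$fold_f1 >= 0 & cv$fold_f1 <= 1))
  # per-feature importances are non-negative and sum to 1
  expect_true(all(cv$importance >= 0))
  # seed determinism
  cv2 <- run_cv(lx$X, lx$y, n_trees = 40, seed = 7)
  expect_identical(cv[c("fold_f1", "oof", "importance")],
                   cv2[c("fold_f1", "oof", "importance")])
  cv3 <- run_cv(lx$X, lx$y, n_trees = 40, seed = 8)
  expect_false(identical(cv$oof, cv3$oof))
})

test_that("fitted forests respect the importance contract", {
  set.seed(4)
  n <- 100
  y <- rep(c("mutant", "wildtype"), each = n / 2)
  X <- cbind(matrix(rnorm(n * 20), n), const = rep(1, n))
  colnames(X) <- c(paste0("f", 1:20), "const")
  X[y == "wildtype", 1] <- X[y == "wildtype", 1] + 3
  fit <- rf_fit(X, y, n_trees = 50, seed = 2)
  expect_equal(sum(fit$importance), 1, tolerance = 1e-6)
  expect_equal(unname(fit$importance["const"]), 0)
  expect_gt(fit$importance["f1"], 0.3)
  # reapplying the model to its training data reproduces stored predictions
  ff <- fit_final(X, y, n_trees = 50, seed = 2, k = 3)
  expect_identical(unname(ff$train_pred), unname(predict(ff$model, X)))
})

test_that("argument and feasibility errors are informative", {
  set.seed(1)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("s", 1:20), c("a", "b")))
  y <- c(rep("mutant", 3), rep("wildtype", 17))
  expect_error(run_cv(X, y, k = 5), "minority class has 3")
  expect_error(holdout_check(X, y, train_frac = 1.0), "strictly between")
  expect_error(run_cv(X, rep("wildtype", 20)), "two classes")
  expect_error(rf_fit(X, y, mtry = 10), "mtry out of range")
})

test_that("per-type F1 handles ratios, perfection and missingness", {
  co <- small_cohort()
  lx <- labelled_xy(co, "PANX")
  cv <- run_cv(lx$X, lx$y, n_trees = 40, seed = 3)
  tab <- per_type_f1(cv, lx$tumour_type)
  expect_setequal(tab$tumour_type, unique(lx$tumour_type))
  expect_equal(tab$n_mut + tab$n_wt, tab$n)
  expect_equal(tab$ratio,
               pmin(tab$n_mut, tab$n_wt) / pmax(tab$n_mut, tab$n_wt))
  # a type with all-correct predictions scores F1 = 1
  cv_fake <- cv
  cv_fake$oof <- cv_fake$y
  expect_true(all(per_type_f1(cv_fake, lx$tumour_type)$f1 == 1))
  # a single-class type is missing, never 0
  y2 <- lx$y
  y2[lx$tumour_type == "TTA"] <- "wildtype"
  cv2 <- list(y = unname(y2), oof = unname(y2), positive = "wildtype")
  class(cv2) <- "cv_result"
  tab2 <- per_type_f1(cv2, lx$tumour_type)
  expect_true(is.na(tab2$f1[tab2$tumour_type == "TTA"]))
})

test_that("shuffled labels drop CV F1 to the majority baseline band", {
  co <- small_cohort()
  lx <- labelled_xy(co, "PANX")
  set.seed(5)
  ysh <- stats::setNames(sample(unname(lx$y)), names(lx$y))
  cv <- run_cv(lx$X, ysh, n_trees = 40, seed = 5)
  base <- oracle_f1(sum(ysh == "wildtype"), sum(ysh == "mutant"), 0)
  expect_lt(abs(cv$mean_f1 - base), 0.1)
  # and stays far below the true-label score
  cv_true <- run_cv(lx$X, lx$y, n_trees = 40, seed = 5)
  expect_gt(cv_true$mean_f1 - cv$mean_f1, 0.05)
})
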