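#' Predict mutational status of samples carrying only non-impactful variants
#'
#' The final model, trained on impactful-mutant versus wild-type samples, is
#' applied to the excluded group. Samples predicted mutant despite nominally
#' silent annotations are candidates for cryptic impact (e.g. intron
#' retention). Predictions are summarised per consequence term; terms whose
#' samples are predominantly predicted mutant (> 50% with n >= 5) are flagged
#' for inspection.
#'
#' @param fit a `"driver_fit"` (or `"drf"`).
#' @param cohort the `"driver_cohort"` the labels came from.
#' @param labels the `"label_set"` used for training.
#' @param vocab consequence vocabulary.
#' @return object of class `"nonimpactful_report"`: `predictions` (sample_id,
#'   predicted class, wild-type probability), `by_term` (term, n, fraction
#'   predicted mutant, flagged), `gene`.
#' @export
predict_excluded <- function(fit, cohort, labels,
                             vocab = impact_vocabulary()) {
  model <- if (inherits(fit, "driver_fit")) fit$model else fit
  stopifnot(inherits(model, "drf"), inherits(labels, "label_set"))
  excl <- names(labels$label)[labels$label == "excluded_non_impactful"]
  if (length(excl) == 0) {
    return(structure(list(
      gene = labels$gene,
      predictions = data.frame(sample_id = character(), pred = character(),
                               prob_wildtype = numeric(),
                               stringsAsFactors = FALSE),
      by_term = data.frame(term = character(), n = integer(),
                           frac_mutant = numeric(), flagged = logical(),
                           stringsAsFactors = FALSE)),
      class = "nonimpactful_report"))
  }
  Xe <- feature_matrix(cohort)[excl, , drop = FALSE]
  missing_f <- setdiff(model$features, colnames(Xe))
  if (length(missing_f))
    stop("expression matrix lacks model features: ",
         paste(head(missing_f, 5), collapse = ", "))
  Xe <- Xe[, model$features, drop = FALSE]
  prob <- predict(model, Xe, type = "prob")
  pred <- ifelse(prob >= 0.5, model$positive,
                 setdiff(model$levels, model$positive))
  predictions <- data.frame(sample_id = excl, pred = unname(pred),
                            prob_wildtype = unname(prob),
                            stringsAsFactors = FALSE)

  v <- cohort$variants[cohort$variants$gene_id == labels$gene &
                         cohort$variants$sample_id %in% excl, , drop = FALSE]
  v$impact <- classify_consequence(v$consequence, vocab)
  v <- v[v$impact == "non_impactful", , drop = FALSE]
  v <- unique(v[, c("sample_id", "consequence")])
  pred_of <- stats::setNames(predictions$pred, predictions$sample_id)
  by_term <- do.call(rbind, lapply(split(v, v$consequence), function(d) {
    fm <- mean(pred_of[d$sample_id] == "mutant")
    data.frame(term = d$consequence[1], n = nrow(d), frac_mutant = fm,
               flagged = fm > 0.5 && nrow(d) >= 5, stringsAsFactors = FALSE)
  }))
  rownames(by_term) <- NULL
  structure(list(gene = labels$gene, predictions = predictions,
                 by_term = by_term[order(-by_term$frac_mutant), ]),
            class = "nonimpactful_report")
}

#' @export
print.nonimpactful_report <- function(x, ...) {
  cat("Non-impactful predictions for ", x$gene, ": ",
      nrow(x$predictions), " samples\n", sep = "")
  print(x$by_term, row.names = FALSE)
  invisible(x)
}

#' Apply a trained model to an external cohort
#'
#' Checks feature coverage; when the external cohort lacks some model
#' features (or `restrict_coding` narrows the space, as when validating on a
#' coding-only expression resource), the forest is retrained on the shared
#' subset using the stored training data before predicting.
#'
#' @param fit a `"driver_fit"` (training data retained).
#' @param X_ext external feature matrix (samples x transcripts, log2(TPM+1)).
#' @param y_ext external labels (`"mutant"`/`"wildtype"`).
#' @param restrict_coding optional character vector of coding transcripts to
#'   intersect the feature space with (NULL = no restriction).
#' @param min_overlap minimum fraction of model features that must be present
#'   externally (default 0.5).
#' @return list: `f1`, `pred`, `coverage`, `retrained`, `n_features`.
#' @export
cross_cohort_predict <- function(fit, X_ext, y_ext, restrict_coding = NULL,
                                 min_overlap = 0.5) {
  stopifnot(inherits(fit, "driver_fit"))
  X_ext <- as.matrix(X_ext)
  shared <- intersect(fit$model$features, colnames(X_ext))
  coverage <- length(shared) / length(fit$model$features)
  if (coverage < min_overlap)
    stop("insufficient feature overlap: ", round(100 * coverage, 1),
         "% of model features present (minimum ",
         round(100 * min_overlap), "%)")
  if (!is.null(restrict_coding)) shared <- intersect(shared, restrict_coding)
  if (length(shared) == 0) stop("no usable shared features")

  retrained <- length(shared) < length(fit$model$features)
  model <- if (retrained) {
    rf_fit(fit$X[, shared, drop = FALSE], fit$y,
           positive = fit$model$positive, n_trees = fit$model$n_trees,
           mtry = min(fit$model$mtry, length(shared)),
           min_leaf = fit$model$min_leaf, max_depth = fit$model$max_depth,
           seed = fit$model$seed)
  } else fit$model
  pred <- predict(model, X_ext[, shared, drop = FALSE])
  f1 <- suppressWarnings(f1_score(y_ext, pred, model$positive))
  list(f1 = f1, pred = stats::setNames(pred, rownames(X_ext)),
       coverage = coverage, retrained = retrained,
       n_features = length(shared))
}

#' Principal-component QC of an expression matrix
#'
#' Used to audit cohort merging: if two cohorts separate on the leading
#' components, batch structure dominates biology.
#'
#' @param X feature matrix (samples x transcripts, log scale).
#' @param n_components components to return (default 2).
#' @return list: `coords` (samples x components), `var_explained` (fraction
#'   per component), `degenerate` (TRUE for a constant matrix).
#' @export
qc_pca <- function(X, n_components = 2) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 samples")
  tot <- sum(apply(X, 2, stats::var))
  if (tot == 0)
    return(list(coords = matrix(0, nrow(X), n_components,
                                dimnames = list(rownames(X), NULL)),
                var_explained = rep(0, n_components), degenerate = TRUE))
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
  list(coords = pc$x, var_explained = (pc$sdev^2 / tot)[seq_len(n_components)],
       degenerate = FALSE)
}

#' Mean silhouette of a grouping in a coordinate space
#'
#' Small helper for PCA QC: values near 0 mean the grouping does not separate
#' (exchangeable labels), values toward 1 mean strong separation.
#'
#' @param coords numeric matrix of coordinates (samples x dims).
#' @param groups group label per sample.
#' @return mean silhouette width across samples.
#' @export
group_silhouette <- function(coords, groups) {
  coords <- as.matrix(coords)
  groups <- as.character(groups)
  d <- as.matrix(stats::dist(coords))
  s <- vapply(seq_along(groups), function(i) {
    own <- groups == groups[i]
    own[i] <- FALSE
    if (!any(own)) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(groups), groups[i]),
                    function(g) mean(d[i, groups == g]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# assemble the per-mode training rows for the final fit
.mode_rows <- function(decision, y, tumour_type, seed) {
  tt <- as.character(tumour_type)
  switch(decision$chosen,
    pan_cancer = seq_along(y),
    specific_types = which(tt %in% decision$selected_types),
    balanced_all = balance_types(y, tt, seed = seed),
    balanced_specific = {
      sel <- which(tt %in% decision$selected_types)
      sel[balance_types(y[sel], tt[sel], seed = seed)]
    })
}

#' Run the full per-gene analysis pipeline
#'
#' For every driver gene: label samples under each alteration setting and
#' choose the setting; compute per-tumour-type F1 and derive the
#' type-selection threshold; compare the four analysis modes and prune
#' under-performing types; fit the final model; apply the chromosomal
#' proximity filter; calibrate feature significance against a permutation
#' null; extract the signed top features; and predict the excluded
#' (non-impactful) samples. Gene failures are isolated: an error aborts that
#' gene only and is recorded in the ledger. With at least three genes (or
#' explicit `thresholds`) the per-gene reports are categorised.
#'
#' @param cohort a `"driver_cohort"`.
#' @param genes driver gene ids (default: all drivers in the cohort's truth,
#'   or an error if no truth is attached).
#' @param settings alteration settings compared per gene.
#' @param n_perm_modes permutations per analysis mode (default 30; tests
#'   use fewer).
#' @param n_perm_gini label permutations for the Gini null (default 50).
#' @param alpha_type z-test alpha for tumour-type selection (default 0.1).
#' @param alpha_gini tail probability of the Gini null envelope.
#' @param epsilon minimum absolute F1 gain to adopt CNA labelling.
#' @param improve minimum relative gain to adopt a narrower mode (default 5%).
#' @param delta tolerated per-type F1 shortfall before pruning.
#' @param top_k top features extracted and screened by the proximity filter.
#' @param thresholds optional explicit categorisation thresholds
#'   (`list(f1 =, gini =)`).
#' @param seed master seed; every stage derives its seed from it.
#' @param k CV folds.
#' @param n_trees,mtry,min_leaf,max_depth forest controls.
#' @return object of class `"pipeline_result"`: `reports` (per gene),
#'   `categories` (data.frame or NULL), `ledger` (config echo, seeds,
#'   per-stage timings, decisions, failures).
#' @export
run_pipeline <- function(cohort, genes = NULL,
                         settings = c("snv", "snv_cna"),
                         n_perm_modes = 30, n_perm_gini = 50,
                         alpha_type = 0.1, alpha_gini = 0.05,
                         epsilon = 0.01, improve = 0.05, delta = 0.05,
                         top_k = 15, thresholds = NULL, seed = 1, k = 5,
                         n_trees = 1000, mtry = NULL, min_leaf = 1,
                         max_depth = 0) {
  stopifnot(inherits(cohort, "driver_cohort"))
  if (is.null(genes)) {
    if (is.null(cohort$truth))
      stop("no truth attached; pass `genes` explicitly")
    genes <- names(cohort$truth$drivers)
  }
  X <- feature_matrix(cohort)
  bin <- .rf_bin_cpp(X)
  tt_all <- stats::setNames(cohort$samples$tumour_type,
                            cohort$samples$sample_id)
  params <- list(n_trees = n_trees, mtry = mtry, min_leaf = min_leaf,
                 max_depth = max_depth)

  reports <- list()
  ledger <- list(seed = seed,
                 settings = settings,
                 params = c(params, list(
                   n_perm_modes = n_perm_modes, n_perm_gini = n_perm_gini,
                   alpha_type = alpha_type, alpha_gini = alpha_gini,
                   epsilon = epsilon, improve = improve, delta = delta,
                   top_k = top_k, k = k)),
                 genes = list(), failures = list())

  for (gi in seq_along(genes)) {
    g <- genes[gi]
    g_seed <- seed + 101L * gi
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      .run_gene(cohort, g, X, bin, tt_all, settings, params,
                n_perm_modes, n_perm_gini, alpha_type, alpha_gini,
                epsilon, improve, delta, top_k, g_seed, k),
      error = function(e) e)
    elapsed <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      ledger$failures[[g]] <- conditionMessage(res)
      next
    }
    reports[[g]] <- res$report
    ledger$genes[[g]] <- c(res$ledger, list(elapsed_s = round(elapsed, 2)))
  }

  categories <- NULL
  if (length(reports) >= 3 || !is.null(thresholds)) {
    categories <- categorize_pattern(
      lapply(reports, function(r)
        r[c("gene", "final_f1", "top_gini", "n_significant", "mode",
            "n_selected_types")]),
      thresholds = thresholds)
  }
  structure(list(reports = reports, categories = categories, ledger = ledger),
            class = "pipeline_result")
}

.run_gene <- function(cohort, g, X, bin, tt_all, settings, params,
                      n_perm_modes, n_perm_gini, alpha_type, alpha_gini,
                      epsilon, improve, delta, top_k, seed, k) {
  led <- list()

  ## 1. alteration setting
  sett <- choose_alteration_setting(
    cohort, g, X = X, settings = settings, epsilon = epsilon, seed = seed,
    k = k, n_trees = params$n_trees, mtry = params$mtry,
    min_leaf = params$min_leaf, max_depth = params$max_depth, bin = bin)
  labels <- sett$labels[[sett$chosen]]
  cv0 <- sett$cv[[sett$chosen]]
  led$setting <- list(chosen = sett$chosen, f1 = as.list(sett$f1),
                      infeasible = as.list(sett$infeasible))

  lab_ids <- names(labels$label)[labels$label %in% c("mutant", "wildtype")]
  y <- stats::setNames(
    ifelse(labels$label[lab_ids] == "mutant", "mutant", "wildtype"), lab_ids)
  tt <- tt_all[lab_ids]

  ## 2. tumour-type selection threshold from this gene's per-type F1s
  ptab <- per_type_f1(cv0, unname(tt))
  vals <- ptab$f1[!is.na(ptab$f1)]
  thr <- if (length(vals) >= 3) derive_threshold(vals, alpha_type, "upper")
         else list(threshold = max(vals), degenerate = TRUE)
  selected <- select_tumour_types(ptab, thr$threshold)
  led$type_selection <- list(per_type = ptab, threshold = thr$threshold,
                             selected = selected)

  ## 3. mode comparison
  decision <- compare_modes(
    X, y, tt, selected, n_perm = n_perm_modes, improve = improve,
    seed = seed + 1L, k = k, n_trees = params$n_trees, mtry = params$mtry,
    min_leaf = params$min_leaf, max_depth = params$max_depth, bin = bin)

  ## 4. pruning within a multi-type specific mode
  if (decision$chosen %in% c("specific_types", "balanced_specific") &&
      length(decision$selected_types) >= 2) {
    pr <- prune_types(
      X, y, unname(tt), decision$selected_types,
      balanced = decision$chosen == "balanced_specific", delta = delta,
      seed = seed + 2L, k = k, n_trees = params$n_trees, mtry = params$mtry,
      min_leaf = params$min_leaf, max_depth = params$max_depth, bin = bin)
    decision$selected_types <- pr$types
    led$pruning <- pr$history
  }
  led$mode <- list(chosen = decision$chosen,
                   selected_types = decision$selected_types,
                   stats = decision$stats, margins = as.list(decision$margins))

  ## 5. final fit on the chosen mode's samples
  rows <- .mode_rows(decision, y, tt, seed = seed + 3L)
  Xf <- X[lab_ids[rows], , drop = FALSE]
  yf <- y[rows]
  fit <- fit_final(Xf, yf, seed = seed + 4L, k = k,
                   n_trees = params$n_trees, mtry = params$mtry,
                   min_leaf = params$min_leaf, max_depth = params$max_depth)

  ## 6. proximity filter around the driver locus
  drow <- match(g, cohort$genes$gene_id)
  if (is.na(drow)) stop("gene ", g, " has no annotation record")
  target <- list(chrom = cohort$genes$chrom[drow],
                 start = cohort$genes$start[drow])
  filt <- proximity_filter(Xf, yf, fit$model, cohort$genes, target,
                           top_k = top_k)
  led$proximity <- list(iterations = filt$iterations, excised = filt$excised)
  if (filt$iterations > 0) {
    fit <- fit_final(filt$X, yf, seed = seed + 4L, k = k,
                     n_trees = params$n_trees, mtry = params$mtry,
                     min_leaf = params$min_leaf, max_depth = params$max_depth)
    Xf <- filt$X
  }

  ## 7. permutation-calibrated feature significance
  gn <- gini_null(Xf, yf, n_perm = n_perm_gini, alpha = alpha_gini,
                  seed = seed + 5L, model = fit$model,
                  n_trees = params$n_trees, mtry = params$mtry,
                  min_leaf = params$min_leaf, max_depth = params$max_depth)

  ## 8. top features with direction
  tf <- top_features(fit$model, cohort$genes, k = top_k)
  sa <- signed_attribution(fit$model, Xf, tf$feature)
  tf$direction <- sa$direction
  tf$significant <- tf$rank <= gn$n_significant

  ## 9. excluded-sample prediction
  nir <- predict_excluded(fit, cohort, labels)

  report <- list(
    gene = g, setting = sett$chosen, mode = decision$chosen,
    selected_types = decision$selected_types,
    n_selected_types = length(decision$selected_types),
    final_f1 = fit$final_f1,
    top_gini = unname(max(fit$model$importance)),
    n_significant = gn$n_significant,
    top_features = tf,
    mode_stats = decision$stats,
    nonimpactful = nir,
    n_train = length(yf), seed = seed)
  list(report = report, ledger = led)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline over", length(x$reports), "gene(s)\n")
  for (r in x$reports)
    cat(sprintf("  %-10s %-18s F1 %.3f  top Gini %.4f  %d significant\n",
                r$gene, r$mode, r$final_f1, r$top_gini, r$n_significant))
  if (!is.null(x$categories)) {
    cat("Categories:\n")
    print(x$categories[, c("gene", "category")], row.names = FALSE)
  }
  if (length(x$ledger$failures))
    cat("Failures:", paste(names(x$ledger$failures), collapse = ", "), "\n")
  invisible(x)
}
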