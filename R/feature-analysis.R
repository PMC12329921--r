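#' Remove chromosomally proximal features that confound driver signatures
#'
#' Copy-number events at the driver locus drag the expression of chromosomal
#' neighbours with them (cis dosage), so transcripts near the driver can
#' dominate the importance ranking without saying anything about the driver's
#' downstream program. This filter inspects the top-`top_k` features; if at
#' least `cluster_min` of them lie on the driver's chromosome within
#' `window_mb` of its locus and form a physical cluster (pairwise gaps at most
#' `gap_mb`), the contiguous block of transcripts containing that cluster
#' (inter-transcript gaps at most `gap_mb`, clipped to the window) is excised
#' from the feature space and the model is refit. Iterates until no such cluster
#' remains or `max_iter` is reached. Excision is capped at `max_frac` of all
#' features; the cap aborts further excision with a warning (runaway-excision
#' guard). All excised regions are logged.
#'
#' @param X feature matrix used to fit `model` (samples x transcripts).
#' @param y training labels for the refit.
#' @param model fitted `"drf"` whose importances are screened.
#' @param genes transcript annotation (gene_id, chrom, start, end); every
#'   screened feature must have coordinates — a missing coordinate is a hard
#'   error, since silently keeping the transcript would defeat the filter.
#' @param target list or one-row data.frame with the driver locus (`chrom`,
#'   `start`).
#' @param top_k number of top-ranked features inspected per iteration.
#' @param window_mb maximum distance (Mb) from the driver locus.
#' @param gap_mb maximum pairwise gap (Mb) within a cluster.
#' @param cluster_min minimum clustered top features triggering excision.
#' @param max_iter iteration cap.
#' @param max_frac excised-feature cap as a fraction of all features.
#' @return list: `model` (refit on the filtered space, or the input model if
#'   nothing was excised), `X` (filtered), `excised` (data.frame of regions
#'   with transcript counts), `iterations`.
#' @export
proximity_filter <- function(X, y, model, genes, target, top_k = 15,
                             window_mb = 10, gap_mb = 1, cluster_min = 3,
                             max_iter = 5, max_frac = 0.05) {
  stopifnot(inherits(model, "drf"))
  X <- as.matrix(X)
  if (is.data.frame(target)) target <- as.list(target[1, ])
  p0 <- ncol(X)
  excised <- list()
  iterations <- 0L
  budget <- floor(max_frac * p0)

  repeat {
    if (iterations >= max_iter) break
    imp <- sort(model$importance, decreasing = TRUE)
    top <- names(imp)[seq_len(min(top_k, length(imp)))]
    ann <- genes[match(top, genes$gene_id), , drop = FALSE]
    if (anyNA(ann$start))
      stop("missing coordinates for top-ranked feature(s): ",
           paste(top[is.na(ann$start)], collapse = ", "))
    near <- which(ann$chrom == target$chrom &
                    abs(ann$start - target$start) <= window_mb * 1e6)
    if (length(near) < cluster_min) break

    # physical clusters among the near features: runs with gaps <= gap_mb
    ord <- near[order(ann$start[near])]
    gaps <- diff(ann$start[ord])
    cl_id <- cumsum(c(1, gaps > gap_mb * 1e6))
    sizes <- table(cl_id)
    big <- names(sizes)[sizes >= cluster_min]
    if (!length(big)) break

    # a qualifying cluster marks a gene-dense physical block; excise the
    # whole contiguous run of remaining transcripts (inter-gene gaps
    # <= gap_mb) containing it, clipped to the window around the target
    chr_tab <- genes[genes$chrom == target$chrom &
                       genes$gene_id %in% colnames(X), , drop = FALSE]
    chr_tab <- chr_tab[order(chr_tab$start), , drop = FALSE]
    block_id <- cumsum(c(1, diff(chr_tab$start) > gap_mb * 1e6))
    in_window <- abs(chr_tab$start - target$start) <= window_mb * 1e6

    drop_ids <- character()
    for (b in big) {
      members <- ord[cl_id == b]
      blocks <- unique(block_id[match(top[members], chr_tab$gene_id)])
      sel <- block_id %in% blocks & in_window
      region <- setdiff(chr_tab$gene_id[sel], drop_ids)  # clusters may share a block
      if (!length(region)) next
      drop_ids <- union(drop_ids, region)
      pos <- chr_tab$start[chr_tab$gene_id %in% region]
      excised[[length(excised) + 1]] <- data.frame(
        chrom = target$chrom, start = min(pos), end = max(pos),
        n_transcripts = length(region), stringsAsFactors = FALSE)
    }
    n_gone <- (p0 - ncol(X)) + length(drop_ids)
    if (n_gone > budget) {
      warning("proximity filter would excise ", n_gone, " of ", p0,
              " features (cap ", budget, "); stopping early")
      break
    }
    X <- X[, setdiff(colnames(X), drop_ids), drop = FALSE]
    iterations <- iterations + 1L
    model <- rf_fit(X, y, positive = model$positive, n_trees = model$n_trees,
                    mtry = min(model$mtry, ncol(X)),
                    min_leaf = model$min_leaf, max_depth = model$max_depth,
                    seed = model$seed + iterations)
  }

  list(model = model, X = X,
       excised = if (length(excised)) do.call(rbind, excised) else
         data.frame(chrom = character(), start = numeric(), end = numeric(),
                    n_transcripts = integer(), stringsAsFactors = FALSE),
       iterations = iterations)
}

#' Permutation null for Gini importances
#'
#' Labels are shuffled `n_perm` times and the forest refit each time; for
#' every rank r the (1 - alpha) empirical quantile of the r-th largest null
#' importance forms a rank-matched null envelope. Features of the true fit
#' are counted significant from rank 1 downwards while their rank-r Gini
#' exceeds the rank-r null quantile, stopping at the first failure.
#'
#' @param X feature matrix.
#' @param y two-class labels.
#' @param n_perm number of label permutations (>= 1 required, >= 10
#'   recommended; default 50).
#' @param alpha envelope tail probability (default 0.05).
#' @param seed integer seed for both the shuffles and the forests.
#' @param model optional prefit `"drf"` on (X, y) to reuse as the true fit.
#' @param n_trees,mtry,min_leaf,max_depth forest controls for the refits.
#' @return list: `n_significant`, `significant_features`, `true_sorted`
#'   (descending true importances), `null_quantiles` (per rank), `alpha`,
#'   `n_perm`.
#' @export
gini_null <- function(X, y, n_perm = 50, alpha = 0.05, seed = 1, model = NULL,
                      n_trees = 1000, mtry = NULL, min_leaf = 1,
                      max_depth = 0) {
  if (!is.numeric(n_perm) || n_perm < 1)
    stop("n_perm must be a positive integer")
  if (n_perm < 10)
    warning("n_perm < 10 gives a very coarse null envelope")
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) < 2) stop("y has a single class; null is undefined")

  bin <- .rf_bin_cpp(X)
  positive <- if ("wildtype" %in% y) "wildtype" else sort(unique(y))[1]
  if (is.null(model)) {
    model <- .rf_fit_rows(bin, colnames(X), y, seq_along(y), positive,
                          n_trees, mtry, min_leaf, max_depth, seed)
  }
  true_sorted <- sort(model$importance, decreasing = TRUE)

  p <- ncol(X)
  null_sorted <- matrix(0, n_perm, p)
  for (i in seq_len(n_perm)) {
    set.seed(seed + 7717L * i)
    ys <- sample(y)
    fit <- .rf_fit_rows(bin, colnames(X), ys, seq_along(ys), positive,
                        n_trees, mtry, min_leaf, max_depth,
                        seed = seed + 7717L * i)
    null_sorted[i, ] <- sort(fit$importance, decreasing = TRUE)
  }
  qs <- apply(null_sorted, 2, quantile, probs = 1 - alpha, names = FALSE)

  n_sig <- 0L
  while (n_sig < p && true_sorted[n_sig + 1L] > qs[n_sig + 1L])
    n_sig <- n_sig + 1L

  list(n_significant = n_sig,
       significant_features = names(true_sorted)[seq_len(n_sig)],
       true_sorted = true_sorted, null_quantiles = qs, alpha = alpha,
       n_perm = n_perm, seed = seed)
}

#' Categorise per-gene transcriptional patterns
#'
#' Cohort-level thresholds separate genuine patterns from weak or spurious
#' ones: a lower z-threshold (`alpha_f1`) on the distribution of final F1
#' scores across genes, and a lower empirical percentile (`alpha_gini`) of
#' the top Gini scores. A gene is `no_or_weak` when its F1 or top Gini falls
#' below threshold or it has no significant features; `potential_overfit`
#' when F1 clears the threshold but the top Gini does not and the analysis
#' used balanced sets of at most two tumour types (high F1 earned on a small
#' balanced cohort with no strong feature is an overfitting signature);
#' otherwise `pan_cancer` or `tumour_specific` according to the gene's mode
#' decision.
#'
#' @param reports list of per-gene reports, each with `gene`, `final_f1`,
#'   `top_gini`, `n_significant`, `mode` (chosen mode string) and
#'   `n_selected_types`.
#' @param alpha_f1 z-test alpha for the F1 lower threshold (default 0.1).
#' @param alpha_gini lower-percentile alpha for the top-Gini threshold
#'   (default 0.25).
#' @param thresholds optional list `list(f1 = , gini = )` overriding the
#'   cohort-derived thresholds; required when fewer than 3 genes were
#'   analysed.
#' @return data.frame: gene, final_f1, top_gini, n_significant, category;
#'   thresholds attached as attribute `"thresholds"`.
#' @export
categorize_pattern <- function(reports, alpha_f1 = 0.1, alpha_gini = 0.25,
                               thresholds = NULL) {
  f1s <- vapply(reports, `[[`, numeric(1), "final_f1")
  ginis <- vapply(reports, `[[`, numeric(1), "top_gini")
  if (is.null(thresholds)) {
    if (length(reports) < 3)
      stop("fewer than 3 genes: supply thresholds = list(f1 =, gini =) explicitly")
    f1_thr <- derive_threshold(f1s, alpha_f1, "lower")$threshold
    gini_thr <- quantile(ginis, alpha_gini, names = FALSE)
  } else {
    f1_thr <- thresholds$f1
    gini_thr <- thresholds$gini
  }

  cat_of <- function(r) {
    balanced_small <- r$mode %in% c("balanced_specific", "balanced_all") &&
      r$n_selected_types <= 2
    if (r$final_f1 >= f1_thr && r$top_gini < gini_thr && balanced_small)
      return("potential_overfit")
    if (r$final_f1 < f1_thr || r$top_gini < gini_thr ||
        r$n_significant == 0)
      return("no_or_weak")
    if (r$mode %in% c("specific_types", "balanced_specific"))
      "tumour_specific" else "pan_cancer"
  }
  out <- data.frame(
    gene = vapply(reports, `[[`, "", "gene"),
    final_f1 = f1s, top_gini = ginis,
    n_significant = as.integer(vapply(reports, function(r)
      as.numeric(r$n_significant), numeric(1))),
    category = vapply(reports, cat_of, ""),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "thresholds") <- list(f1 = f1_thr, gini = gini_thr,
                                  alpha_f1 = alpha_f1,
                                  alpha_gini = alpha_gini)
  out
}

#' Top-ranked features of a fitted model
#'
#' @param model a `"drf"` or `"driver_fit"`.
#' @param genes optional transcript annotation to attach coordinates.
#' @param k number of features (default 15); if fewer exist, all are returned
#'   with a warning. Importance ties are broken lexicographically by
#'   transcript id, so the table is stable across runs.
#' @return data.frame: feature, gini, rank (+ chrom/start/end when `genes`
#'   given).
#' @export
top_features <- function(model, genes = NULL, k = 15) {
  if (inherits(model, "driver_fit")) model <- model$model
  stopifnot(inherits(model, "drf"))
  imp <- model$importance
  ord <- order(-imp, names(imp))
  if (length(imp) < k) {
    warning("only ", length(imp), " features available (k = ", k, ")")
    k <- length(imp)
  }
  sel <- ord[seq_len(k)]
  out <- data.frame(feature = names(imp)[sel], gini = unname(imp[sel]),
                    rank = seq_len(k), stringsAsFactors = FALSE)
  if (!is.null(genes)) {
    m <- match(out$feature, genes$gene_id)
    out$chrom <- genes$chrom[m]
    out$start <- genes$start[m]
    out$end <- genes$end[m]
  }
  out
}

#' Direction of association for top features
#'
#' Aggregates per-sample decision-path attributions (see
#' [rf_path_attribution()]) into a sign per feature: `"wildtype"` when higher
#' expression pushes predictions toward the wild-type (positive) class,
#' `"mutant"` when it pushes toward the mutant class — the
#' oncogene-like versus tumour-suppressor-like signature directions. As an
#' internal consistency audit, a model-free fallback (rank correlation of
#' expression with the predicted wild-type probability) is reported alongside;
#' signs should agree for the vast majority of genuinely informative features.
#'
#' @param model fitted `"drf"`.
#' @param X feature matrix the attributions are computed on.
#' @param features character vector of features to annotate.
#' @return data.frame: feature, direction (`"wildtype"`/`"mutant"`, NA for
#'   constant features), attr_rho (rank correlation of expression with its
#'   attribution), prob_rho (fallback), agree (sign agreement flag).
#' @export
signed_attribution <- function(model, X, features) {
  if (inherits(model, "driver_fit")) model <- model$model
  stopifnot(inherits(model, "drf"))
  X <- as.matrix(X)
  contrib <- rf_path_attribution(model, X)
  prob <- predict(model, X, type = "prob")
  rows <- lapply(features, function(f) {
    xv <- X[, f]
    if (sd(xv) == 0)
      return(data.frame(feature = f, direction = NA_character_,
                        attr_rho = NA_real_, prob_rho = NA_real_,
                        agree = NA, stringsAsFactors = FALSE))
    a_rho <- suppressWarnings(cor(xv, contrib[, f], method = "spearman"))
    p_rho <- suppressWarnings(cor(xv, prob, method = "spearman"))
    if (is.na(a_rho) || a_rho == 0)
      return(data.frame(feature = f, direction = NA_character_,
                        attr_rho = a_rho, prob_rho = p_rho, agree = NA,
                        stringsAsFactors = FALSE))
    data.frame(feature = f,
               direction = if (a_rho > 0) "wildtype" else "mutant",
               attr_rho = a_rho, prob_rho = p_rho,
               agree = !is.na(p_rho) && sign(a_rho) == sign(p_rho),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank-sum comparison of expression between two groups
#'
#' Two-sided Mann-Whitney-Wilcoxon test per gene with Bonferroni correction
#' (p multiplied by the number of tests, capped at 1), plus per-group TPM
#' medians. Groups smaller than 3 give missing p-values.
#'
#' @param tpm expression matrix, transcripts x samples, TPM scale.
#' @param grouping two-level factor (or coercible) over the samples.
#' @param genes transcripts to test.
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @return data.frame: gene, p_raw, p_adj, median and n per group.
#' @export
expression_test <- function(tpm, grouping, genes,
                            correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  grouping <- as.factor(grouping)
  stopifnot(length(grouping) == ncol(tpm), nlevels(grouping) == 2)
  lv <- levels(grouping)
  miss <- setdiff(genes, rownames(tpm))
  if (length(miss)) stop("genes not in matrix: ", paste(miss, collapse = ", "))
  m <- length(genes)
  rows <- lapply(genes, function(g) {
    a <- tpm[g, grouping == lv[1]]
    b <- tpm[g, grouping == lv[2]]
    p <- if (length(a) < 3 || length(b) < 3) NA_real_ else
      suppressWarnings(wilcox.test(a, b, alternative = "two.sided")$p.value)
    p_adj <- if (correction == "bonferroni") pmin(1, p * m) else p
    out <- data.frame(gene = g, p_raw = p, p_adj = p_adj,
                      median_1 = median(a), median_2 = median(b),
                      n_1 = length(a), n_2 = length(b),
                      stringsAsFactors = FALSE)
    names(out)[4:7] <- c(paste0("median_", lv), paste0("n_", lv))
    out
  })
  do.call(rbind, rows)
}
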