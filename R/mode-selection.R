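#' Choose the alteration setting for a driver gene
#'
#' Compares cross-validated F1 between the SNV/INDEL-only labelling and
#' labellings that add CNA (and optionally SV) mutants. Copy-number mutants
#' are adopted only when they buy a substantial improvement; `epsilon` is the
#' minimum absolute F1 gain (default 0.01). SV-containing settings are
#' evaluated and reported when requested but never chosen over `snv_cna`
#' unless they beat the current best by the same margin.
#'
#' @param cohort a `"driver_cohort"`.
#' @param gene driver gene id.
#' @param X feature matrix for the full cohort (defaults to
#'   [feature_matrix()]); rows are subset per setting internally.
#' @param settings alteration settings to compare (see [build_labels()]).
#' @param epsilon minimum absolute F1 improvement to adopt a richer setting.
#' @param seed,k,n_trees,mtry,min_leaf,max_depth CV and forest controls.
#' @param vocab consequence vocabulary.
#' @param bin optional prebinned `X` for reuse across calls.
#' @return list: `chosen` setting, `f1` (named vector over feasible settings),
#'   `labels` and `cv` per feasible setting, `infeasible` (named character of
#'   failures), `epsilon`.
#' @export
choose_alteration_setting <- function(cohort, gene, X = feature_matrix(cohort),
                                      settings = c("snv", "snv_cna"),
                                      epsilon = 0.01, seed = 1, k = 5,
                                      n_trees = 1000, mtry = NULL,
                                      min_leaf = 1, max_depth = 0,
                                      vocab = impact_vocabulary(),
                                      bin = NULL) {
  stopifnot(inherits(cohort, "driver_cohort"))
  if (is.null(bin)) bin <- .rf_bin_cpp(X)
  params <- list(n_trees = n_trees, mtry = mtry, min_leaf = min_leaf,
                 max_depth = max_depth)
  labels <- list(); cvs <- list(); f1 <- c(); infeasible <- c()
  for (s in settings) {
    lab <- tryCatch(build_labels(cohort, gene, s, vocab = vocab),
                    error = function(e) e)
    if (inherits(lab, "error")) {
      infeasible[s] <- conditionMessage(lab)
      next
    }
    rows <- which(lab$label %in% c("mutant", "wildtype"))
    cv <- tryCatch(.cv_rows(bin, X, stats::setNames(
      ifelse(lab$label == "mutant", "mutant", "wildtype"),
      names(lab$label)), rows, k, seed, "wildtype", params),
      error = function(e) e)
    if (inherits(cv, "error")) {
      infeasible[s] <- conditionMessage(cv)
      next
    }
    labels[[s]] <- lab
    cvs[[s]] <- cv
    f1[s] <- cv$mean_f1
  }
  if (!length(f1))
    stop("gene ", gene, " is not analyzable under any requested setting: ",
         paste(names(infeasible), infeasible, sep = ": ", collapse = "; "))

  chosen <- if ("snv" %in% names(f1)) "snv" else names(f1)[1]
  for (s in intersect(c("snv_cna", "snv_sv", "snv_cna_sv"), names(f1)))
    if (f1[s] - f1[chosen] > epsilon) chosen <- s
  list(chosen = chosen, f1 = f1, labels = labels, cv = cvs,
       infeasible = infeasible, epsilon = epsilon)
}

#' Gaussian z-threshold on an empirical score distribution
#'
#' `threshold = mean + z(1 - alpha) * sd` for `side = "upper"`, or
#' `mean - z(1 - alpha) * sd` for `side = "lower"`, with the sample SD (n-1).
#' The stored population makes every threshold recomputable after the fact.
#'
#' @param values numeric scores (at least 3).
#' @param alpha tail probability.
#' @param side `"upper"` or `"lower"`.
#' @return object of class `"threshold_spec"`: `threshold`, `mean`, `sd`,
#'   `alpha`, `side`, `degenerate` (TRUE when the population has zero
#'   variance), and `population`.
#' @export
derive_threshold <- function(values, alpha = 0.1, side = c("upper", "lower")) {
  side <- match.arg(side)
  values <- as.numeric(values[!is.na(values)])
  if (length(values) < 3)
    stop("need at least 3 values to derive a threshold, got ", length(values))
  m <- mean(values)
  s <- sd(values)
  degenerate <- s == 0
  z <- qnorm(1 - alpha)
  thr <- if (degenerate) m else if (side == "upper") m + z * s else m - z * s
  structure(list(threshold = thr, mean = m, sd = s, alpha = alpha,
                 side = side, degenerate = degenerate, population = values),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat("z-threshold (", x$side, ", alpha ", x$alpha, "): ",
      round(x$threshold, 4), if (x$degenerate) " [degenerate]", "\n", sep = "")
  invisible(x)
}

#' Select tumour types exceeding an F1 threshold
#'
#' Types whose F1 exceeds the threshold are selected; if none do, the single
#' best type is chosen (ties broken by larger sample count, then
#' lexicographically). Types with undefined F1 (one class only) never qualify.
#'
#' @param type_table data.frame from [per_type_f1()].
#' @param threshold a `"threshold_spec"` or a plain number.
#' @return character vector of selected tumour types.
#' @export
select_tumour_types <- function(type_table, threshold) {
  stopifnot(nrow(type_table) > 0)
  thr <- if (inherits(threshold, "threshold_spec")) threshold$threshold
         else as.numeric(threshold)
  ok <- !is.na(type_table$f1) & type_table$f1 > thr
  if (any(ok)) return(sort(type_table$tumour_type[ok]))
  cand <- type_table[!is.na(type_table$f1), , drop = FALSE]
  if (nrow(cand) == 0)
    stop("no tumour type has a defined F1; cannot select")
  ord <- order(-cand$f1, -cand$n, cand$tumour_type)
  cand$tumour_type[ord[1]]
}

#' Down-sample to balanced classes within tumour types
#'
#' Within each type the majority class is randomly down-sampled without
#' replacement to the minority size. Types carrying a single class are dropped
#' with a warning.
#'
#' @param y class labels for all candidate samples.
#' @param tumour_type tumour type per sample, aligned with `y`.
#' @param types types to balance over (default: all present).
#' @param seed integer seed; the draw is deterministic given it.
#' @return integer vector of retained positions (ascending).
#' @export
balance_types <- function(y, tumour_type, types = NULL, seed = 1) {
  stopifnot(length(y) == length(tumour_type))
  if (is.null(types)) types <- sort(unique(tumour_type))
  set.seed(seed)
  keep <- integer()
  for (tt in types) {
    idx <- which(tumour_type == tt)
    cls <- split(idx, y[idx])
    if (length(cls) < 2) {
      warning("type ", tt, " has a single class; dropped from balanced set")
      next
    }
    m <- min(lengths(cls))
    for (cc in cls)
      keep <- c(keep, if (length(cc) == m) cc else sample(cc, m))
  }
  sort(keep)
}

#' Compare the four analysis modes for one driver gene
#'
#' Evaluates (1) all samples, (2) samples of selected tumour types, (3)
#' class-balanced sets across all types, and (4) balanced sets of the
#' selected types; each as mean and SD of F1 over `n_perm` permutations of
#' stratified 5-fold CV (folds re-randomized each permutation; balanced modes
#' also re-draw the down-sample). Tumour-type-specific analysis is adopted
#' over pan-cancer only when it improves mean F1 by more than `improve`
#' (relative, default 5%); balancing the selected types is adopted over the
#' current best under the same rule. Infeasible modes are recorded and
#' skipped.
#'
#' @param X feature matrix over all cohort samples.
#' @param y named class labels (`"mutant"`/`"wildtype"`) over the labelled
#'   samples; names must match rownames of `X`.
#' @param tumour_type named tumour-type vector over the same samples.
#' @param selected_types tumour types entering the type-specific modes,
#'   usually from [select_tumour_types()].
#' @param n_perm permutations per mode (default 30).
#' @param improve minimum improvement to adopt a narrower mode; interpreted as
#'   relative when `relative = TRUE`.
#' @param relative interpret `improve` as a relative gain (default) rather
#'   than absolute F1 points.
#' @param seed,k,n_trees,mtry,min_leaf,max_depth CV and forest controls.
#' @param bin optional prebinned `X`.
#' @return object of class `"mode_decision"`: `chosen` mode, `selected_types`,
#'   `stats` (per-mode mean/sd/n_perm), `margins`, `infeasible`, `seed`.
#' @export
compare_modes <- function(X, y, tumour_type, selected_types, n_perm = 30,
                          improve = 0.05, relative = TRUE, seed = 1, k = 5,
                          n_trees = 1000, mtry = NULL, min_leaf = 1,
                          max_depth = 0, bin = NULL) {
  X <- as.matrix(X)
  stopifnot(!is.null(names(y)), all(names(y) %in% rownames(X)))
  if (is.null(bin)) bin <- .rf_bin_cpp(X)
  params <- list(n_trees = n_trees, mtry = mtry, min_leaf = min_leaf,
                 max_depth = max_depth)
  # align y/tumour_type to X row positions
  pos <- match(names(y), rownames(X))
  yfull <- rep(NA_character_, nrow(X))
  yfull[pos] <- y
  tt_of <- stats::setNames(as.character(tumour_type), names(y))

  labelled <- pos
  in_sel <- pos[tt_of[names(y)] %in% selected_types]

  mode_rows <- list(
    pan_cancer = function(i) labelled,
    specific_types = function(i) in_sel,
    balanced_all = function(i) {
      kp <- suppressWarnings(
        balance_types(y, tt_of[names(y)], seed = seed + 7919L * i))
      labelled[kp]
    },
    balanced_specific = function(i) {
      sel <- which(tt_of[names(y)] %in% selected_types)
      kp <- suppressWarnings(
        balance_types(y[sel], tt_of[names(y)][sel], seed = seed + 104729L * i))
      labelled[sel[kp]]
    })

  stats_tab <- data.frame(mode = character(), mean_f1 = numeric(),
                          sd_f1 = numeric(), n_perm = integer(),
                          stringsAsFactors = FALSE)
  per_mode_f1 <- list()
  infeasible <- c()
  for (mode in names(mode_rows)) {
    f1s <- numeric(0)
    err <- NULL
    for (i in seq_len(n_perm)) {
      rows <- mode_rows[[mode]](i)
      cv <- tryCatch(
        .cv_rows(bin, X, yfull, rows, k, seed + 31L * i, "wildtype", params),
        error = function(e) e)
      if (inherits(cv, "error")) { err <- conditionMessage(cv); break }
      f1s <- c(f1s, cv$mean_f1)
    }
    if (!is.null(err)) {
      infeasible[mode] <- err
      next
    }
    per_mode_f1[[mode]] <- f1s
    stats_tab <- rbind(stats_tab, data.frame(
      mode = mode, mean_f1 = mean(f1s), sd_f1 = sd(f1s), n_perm = n_perm,
      stringsAsFactors = FALSE))
  }
  if (!"pan_cancer" %in% stats_tab$mode)
    stop("pan-cancer mode infeasible: ", infeasible["pan_cancer"])

  gain <- function(candidate, incumbent) {
    if (relative) (candidate - incumbent) / incumbent
    else candidate - incumbent
  }
  m_of <- stats::setNames(stats_tab$mean_f1, stats_tab$mode)
  chosen <- "pan_cancer"
  margins <- c()
  if ("specific_types" %in% names(m_of)) {
    margins["specific_vs_pan"] <- gain(m_of["specific_types"], m_of["pan_cancer"])
    if (margins["specific_vs_pan"] > improve) chosen <- "specific_types"
  }
  if ("balanced_specific" %in% names(m_of)) {
    margins["balanced_specific_vs_best"] <- gain(m_of["balanced_specific"],
                                                 m_of[chosen])
    if (margins["balanced_specific_vs_best"] > improve)
      chosen <- "balanced_specific"
  }

  structure(list(chosen = chosen, selected_types = sort(selected_types),
                 stats = stats_tab, per_mode_f1 = per_mode_f1,
                 margins = margins, infeasible = infeasible,
                 improve = improve, relative = relative, n_perm = n_perm,
                 seed = seed),
            class = "mode_decision")
}

#' @export
print.mode_decision <- function(x, ...) {
  cat("Mode decision:", x$chosen,
      if (x$chosen != "pan_cancer")
        paste0("(types: ", paste(x$selected_types, collapse = ", "), ")"),
      "\n")
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Iteratively prune under-performing tumour types
#'
#' Within a multi-type analysis, repeatedly drops the worst tumour type while
#' its per-type F1 falls more than `delta` below the pooled F1, re-evaluating
#' after each removal; stops at a single type. The pruning history is
#' recorded.
#'
#' @inheritParams compare_modes
#' @param types current selection (at least 1).
#' @param balanced evaluate on balanced sets (when the chosen mode is a
#'   balanced one).
#' @param delta tolerated per-type shortfall in absolute F1 (default 0.05).
#' @return list: `types` (revised selection), `history` (one row per
#'   iteration: pooled F1, worst type, its F1, action).
#' @export
prune_types <- function(X, y, tumour_type, types, balanced = FALSE,
                        delta = 0.05, seed = 1, k = 5, n_trees = 1000,
                        mtry = NULL, min_leaf = 1, max_depth = 0, bin = NULL) {
  X <- as.matrix(X)
  stopifnot(!is.null(names(y)), all(names(y) %in% rownames(X)))
  if (is.null(bin)) bin <- .rf_bin_cpp(X)
  params <- list(n_trees = n_trees, mtry = mtry, min_leaf = min_leaf,
                 max_depth = max_depth)
  pos <- match(names(y), rownames(X))
  yfull <- rep(NA_character_, nrow(X))
  yfull[pos] <- y
  tt <- as.character(tumour_type)

  history <- list()
  types <- sort(types)
  repeat {
    if (length(types) < 2) break
    sel <- which(tt %in% types)
    use <- if (balanced)
      sel[balance_types(y[sel], tt[sel], seed = seed)] else sel
    cv <- .cv_rows(bin, X, yfull, pos[use], k, seed + length(history),
                   "wildtype", params)
    ptab <- per_type_f1(cv, tt[use])
    pooled <- cv$mean_f1
    cand <- ptab[!is.na(ptab$f1), , drop = FALSE]
    worst <- cand[which.min(cand$f1), , drop = FALSE]
    drop_it <- nrow(worst) == 1 && worst$f1 < pooled - delta
    history[[length(history) + 1]] <- data.frame(
      pooled_f1 = pooled, worst_type = worst$tumour_type,
      worst_f1 = worst$f1,
      action = if (drop_it) "dropped" else "kept", stringsAsFactors = FALSE)
    if (!drop_it) break
    types <- setdiff(types, worst$tumour_type)
  }
  list(types = types,
       history = if (length(history)) do.call(rbind, history) else
         data.frame())
}
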