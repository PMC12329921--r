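test_that("gini_null validates arguments and counts planted signal", {
  co <- small_cohort()
  lx <- labelled_xy(co, "PANX")
  expect_error(gini_null(lx$X, lx$y, n_perm = 0), "positive integer")
  expect_error(gini_null(lx$X, rep("wildtype", length(lx$y)), n_perm = 10),
               "single class")
  gn <- gini_null(lx$X, lx$y, n_perm = 10, n_trees = 40, seed = 3)
  # 20 planted signature genes at effect 1.5: at least half are recovered
  expect_gte(gn$n_significant, 10)
  sig_true <- co$truth$drivers$PANX$signature_genes
  expect_gt(mean(gn$significant_features %in% sig_true), 0.5)
  # ranks: true importances are sorted descending, quantiles per rank
  expect_false(is.unsorted(rev(gn$true_sorted)))
  expect_length(gn$null_quantiles, ncol(lx$X))
})

test_that("pattern categorisation follows the rule table", {
  mk <- function(gene, f1, gini, nsig, mode = "pan_cancer", ntypes = 4)
    list(gene = gene, final_f1 = f1, top_gini = gini, n_significant = nsig,
         mode = mode, n_selected_types = ntypes)
  # cohort-level floors: strong genes sit well above a weak tail whose top
  # Gini is the cohort floor
  reports <- list(
    mk("STRONG1", 0.87, 0.0424, 12),
    mk("STRONG2", 0.84, 0.0519, 9, mode = "specific_types", ntypes = 1),
    mk("MID", 0.75, 0.0109, 5),
    mk("WEAK1", 0.64, 0.0021, 0),
    mk("WEAK2", 0.71, 0.0014, 1),
    mk("OVERFIT", 0.85, 0.0015, 1, mode = "balanced_specific", ntypes = 2))
  cats <- categorize_pattern(reports)
  got <- stats::setNames(cats$category, cats$gene)
  expect_equal(unname(got["WEAK1"]), "no_or_weak")
  expect_equal(unname(got["WEAK2"]), "no_or_weak")
  expect_equal(unname(got["OVERFIT"]), "potential_overfit")
  expect_equal(unname(got["STRONG1"]), "pan_cancer")
  expect_equal(unname(got["STRONG2"]), "tumour_specific")
  thr <- attr(cats, "thresholds")
  expect_lt(thr$gini, 0.0424)
  # fewer than 3 genes requires explicit thresholds
  expect_error(categorize_pattern(reports[1:2]), "supply thresholds")
  cats2 <- categorize_pattern(reports[1:2],
                              thresholds = list(f1 = 0.7, gini = 0.002))
  expect_equal(cats2$category, c("pan_cancer", "tumour_specific"))
  # zero significant features is no_or_weak even above both thresholds
  cats3 <- categorize_pattern(list(mk("A", 0.9, 0.05, 0)),
                              thresholds = list(f1 = 0.7, gini = 0.002))
  expect_equal(cats3$category, "no_or_weak")
})

test_that("top_features is stable, annotated and warns when short", {
  set.seed(2)
  X <- matrix(rnorm(300), 30, 10,
              dimnames = list(NULL, paste0("tx", 10:1)))
  y <- rep(c("mutant", "wildtype"), 15)
  fit <- rf_fit(X, y, n_trees = 20, seed = 1)
  expect_warning(tf <- top_features(fit, k = 15), "only 10 features")
  expect_equal(nrow(tf), 10)
  expect_equal(tf$rank, 1:10)
  # exact ties (here: zero importance) are ordered lexicographically
  zero <- tf$feature[tf$gini == 0]
  expect_identical(zero, sort(zero))
  co <- small_cohort()
  lx <- labelled_xy(co, "PANX")
  fit2 <- rf_fit(lx$X, lx$y, n_trees = 40, seed = 1)
  tf2 <- top_features(fit2, genes = co$genes, k = 15)
  expect_true(all(c("chrom", "start") %in% names(tf2)))
  expect_false(anyNA(tf2$chrom))
})

test_that("signed attribution recovers planted directions", {
  co <- small_cohort()
  lx <- labelled_xy(co, "PANX")
  fit <- rf_fit(lx$X, lx$y, n_trees = 60, seed = 2)
  tr <- co$truth$drivers$PANX
  sa <- signed_attribution(fit, lx$X, tr$signature_genes)
  # up-in-mutant genes: higher expression pushes toward the mutant class;
  # down-in-mutant genes: higher expression means wild-type
  expected <- ifelse(tr$signature_sign > 0, "mutant", "wildtype")
  expect_gt(mean(sa$direction == expected, na.rm = TRUE), 0.9)
  # the rank-correlation fallback agrees in sign for most features
  expect_gt(mean(sa$agree, na.rm = TRUE), 0.9)
  # constant feature: undefined direction, flagged
  Xc <- cbind(lx$X, constx = 1)
  fitc <- rf_fit(Xc, lx$y, n_trees = 20, seed = 2)
  sac <- signed_attribution(fitc, Xc, "constx")
  expect_true(is.na(sac$direction))
})

test_that("expression_test matches exact rank-sum enumeration and corrects", {
  co <- small_cohort()
  # enumeration oracle on tiny tie-free groups
  set.seed(8)
  for (i in 1:5) {
    a <- round(rnorm(sample(4:8, 1), 10, 3), 6)
    b <- round(rnorm(sample(4:8, 1), 12, 3), 6)
    tpm <- rbind(g1 = c(a, b))
    colnames(tpm) <- paste0("s", seq_along(c(a, b)))
    grp <- rep(c("A", "B"), c(length(a), length(b)))
    got <- expression_test(tpm, grp, "g1", correction = "none")
    expect_equal(got$p_raw, oracle_ranksum_p(a, b), tolerance = 1e-12)
  }
  # identical groups -> p = 1 after correction
  tpm <- rbind(g1 = rep(c(1, 2, 3, 4), 2))
  colnames(tpm) <- paste0("s", 1:8)
  got <- expression_test(tpm, rep(c("A", "B"), each = 4), "g1")
  expect_equal(got$p_adj, 1)
  # planted shift d = 2, n = 100/100: far below the **** band
  set.seed(3)
  tpm2 <- rbind(g1 = c(rnorm(100, 8), rnorm(100, 10)))
  colnames(tpm2) <- paste0("s", 1:200)
  got2 <- expression_test(tpm2, rep(c("A", "B"), each = 100), "g1")
  expect_lt(got2$p_adj, 1e-4)
  # Bonferroni multiplies by the number of tests
  tpm3 <- rbind(g1 = tpm2[1, ], g2 = sample(tpm2[1, ]),
                g3 = sample(tpm2[1, ]))
  colnames(tpm3) <- colnames(tpm2)
  gr <- rep(c("A", "B"), each = 100)
  raw <- expression_test(tpm3, gr, c("g1", "g2", "g3"), correction = "none")
  adj <- expression_test(tpm3, gr, c("g1", "g2", "g3"))
  expect_equal(adj$p_adj, pmin(1, raw$p_raw * 3))
  # group below 3 samples -> missing p
  tpm4 <- rbind(g1 = c(1, 2, 9, 8, 7, 6))
  colnames(tpm4) <- paste0("s", 1:6)
  got4 <- expression_test(tpm4, c("A", "A", "B", "B", "B", "B"), "g1")
  expect_true(is.na(got4$p_raw))
})

test_that("proximity filter leaves trans signals alone and needs coordinates", {
  co <- small_cohort()
  lx <- labelled_xy(co, "SPEC", setting = "snv")  # no CNA, no cis confound
  fit <- rf_fit(lx$X, lx$y, n_trees = 40, seed = 1)
  drow <- match("SPEC", co$genes$gene_id)
  target <- list(chrom = co$genes$chrom[drow], start = co$genes$start[drow])
  out <- proximity_filter(lx$X, lx$y, fit, co$genes, target)
  expect_equal(out$iterations, 0L)
  expect_identical(out$X, lx$X)
  expect_equal(nrow(out$excised), 0)
  # missing coordinates are a hard error
  genes_bad <- co$genes[co$genes$gene_id != "SPEC", ]
  fit2 <- fit
  expect_error(
    proximity_filter(lx$X, lx$y, local({
      f <- fit; imp <- f$importance
      imp["SPEC"] <- max(imp) * 2; f$importance <- imp; f
    }), genes_bad, target),
    "missing coordinates")
})
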