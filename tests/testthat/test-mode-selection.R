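test_that("z-thresholds match an independent quantile computation", {
  v <- c(0.6, 0.6, 0.6, 0.6, 0.9)
  spec <- derive_threshold(v, alpha = 0.1, side = "upper")
  z <- oracle_z_quantile(0.9)
  expect_equal(spec$threshold, mean(v) + z * sd(v), tolerance = 1e-9)
  expect_equal(spec$threshold, 0.832, tolerance = 0.001)
  expect_false(spec$degenerate)
  # lower side mirrors
  lo <- derive_threshold(v, alpha = 0.1, side = "lower")
  expect_equal(lo$threshold, mean(v) - z * sd(v), tolerance = 1e-9)
  # alpha 0.5 collapses to the mean
  expect_equal(derive_threshold(v, 0.5, "upper")$threshold, mean(v))
  # degenerate population
  dg <- derive_threshold(rep(0.7, 4), 0.1, "upper")
  expect_true(dg$degenerate)
  expect_equal(dg$threshold, 0.7)
  expect_error(derive_threshold(c(0.1, 0.2), 0.1), "at least 3")
  # threshold recomputable from the stored population
  expect_equal(derive_threshold(spec$population, spec$alpha,
                                spec$side)$threshold, spec$threshold)
})

test_that("tumour-type selection applies the threshold and fallback rules", {
  tab <- data.frame(tumour_type = c("AA", "BB", "CC"),
                    f1 = c(0.50, 0.81, 0.85), n = c(50, 40, 30),
                    stringsAsFactors = FALSE)
  expect_equal(select_tumour_types(tab, 0.8), c("BB", "CC"))
  # none above -> single argmax
  expect_equal(select_tumour_types(tab, 0.9), "CC")
  # tie on F1 broken by larger n, then lexicographic
  tab2 <- data.frame(tumour_type = c("ZZ", "AA", "BB"),
                     f1 = c(0.7, 0.7, 0.7), n = c(60, 60, 30),
                     stringsAsFactors = FALSE)
  expect_equal(select_tumour_types(tab2, 0.9), "AA")
  # undefined F1 never qualifies
  tab3 <- data.frame(tumour_type = c("AA", "BB"), f1 = c(NA, 0.6),
                     n = c(90, 10), stringsAsFactors = FALSE)
  expect_equal(select_tumour_types(tab3, 0.9), "BB")
})

test_that("balancing down-samples the majority class per type", {
  y <- c(rep("mutant", 30), rep("wildtype", 70), rep("mutant", 20),
         rep("wildtype", 20))
  tt <- c(rep("AA", 100), rep("BB", 40))
  keep <- balance_types(y, tt, seed = 1)
  expect_equal(sum(y[keep] == "mutant" & tt[keep] == "AA"), 30)
  expect_equal(sum(y[keep] == "wildtype" & tt[keep] == "AA"), 30)
  # already balanced type is untouched
  expect_true(all(which(tt == "BB") %in% keep))
  # deterministic given the seed
  expect_identical(keep, balance_types(y, tt, seed = 1))
  expect_false(identical(keep, balance_types(y, tt, seed = 2)))
  # single-class type dropped with a warning
  y2 <- c(y, rep("mutant", 10))
  tt2 <- c(tt, rep("CC", 10))
  expect_warning(keep2 <- balance_types(y2, tt2, seed = 1), "single class")
  expect_false(any(tt2[keep2] == "CC"))
})

test_that("CNA labelling is adopted only when it buys F1", {
  co <- small_cohort()
  # PANX has cna_fraction 0.4: the snv-only setting loses those mutants
  cs <- choose_alteration_setting(co, "PANX", n_trees = 40, seed = 1)
  expect_equal(cs$chosen, "snv_cna")
  expect_gt(cs$f1["snv_cna"] - cs$f1["snv"], cs$epsilon)
  # SPEC has no CNAs: identical label sets, identical F1, snv retained
  cs2 <- choose_alteration_setting(co, "SPEC", n_trees = 40, seed = 1)
  expect_equal(cs2$chosen, "snv")
  expect_equal(unname(cs2$f1["snv"]), unname(cs2$f1["snv_cna"]))
  # with an empty SV table the snv_sv setting equals snv exactly
  cs3 <- choose_alteration_setting(co, "SPEC",
                                   settings = c("snv", "snv_sv"),
                                   n_trees = 40, seed = 1)
  expect_equal(unname(cs3$f1["snv"]), unname(cs3$f1["snv_sv"]))
  expect_equal(cs3$chosen, "snv")
})

test_that("mode comparison records margins consistent with its decision", {
  co <- small_cohort()
  lx <- labelled_xy(co, "SPEC", setting = "snv")
  cv <- run_cv(lx$X, lx$y, n_trees = 40, seed = 2)
  ptab <- per_type_f1(cv, lx$tumour_type)
  thr <- derive_threshold(ptab$f1[!is.na(ptab$f1)], 0.1, "upper")
  sel <- select_tumour_types(ptab, thr)
  expect_equal(sel, "TTB")  # the planted affected type

  dec <- compare_modes(feature_matrix(co), lx$y, lx$tumour_type, sel,
                       n_perm = 3, n_trees = 40, seed = 2)
  expect_s3_class(dec, "mode_decision")
  expect_true(all(c("pan_cancer", "specific_types") %in% dec$stats$mode))
  m <- stats::setNames(dec$stats$mean_f1, dec$stats$mode)
  expect_equal(unname(dec$margins["specific_vs_pan"]),
               unname((m["specific_types"] - m["pan_cancer"]) / m["pan_cancer"]))
  # a tumour-specific driver picks a type-restricted mode
  expect_true(dec$chosen %in% c("specific_types", "balanced_specific"))
  if (dec$chosen == "specific_types")
    expect_gt(dec$margins["specific_vs_pan"], dec$improve)
  # determinism of the full decision
  dec2 <- compare_modes(feature_matrix(co), lx$y, lx$tumour_type, sel,
                        n_perm = 3, n_trees = 40, seed = 2)
  expect_identical(dec[c("chosen", "stats", "margins")],
                   dec2[c("chosen", "stats", "margins")])
})

test_that("the 5% rule is arithmetic on recorded means", {
  # margin example: pan 0.70, specific 0.76 -> +8.6% relative, adopted
  expect_gt((0.76 - 0.70) / 0.70, 0.05)
  co <- small_cohort()
  lx <- labelled_xy(co, "PANX")
  # a pan-cancer driver shows no 5% gain from restricting types
  cv <- run_cv(lx$X, lx$y, n_trees = 40, seed = 4)
  ptab <- per_type_f1(cv, lx$tumour_type)
  sel <- select_tumour_types(ptab, derive_threshold(ptab$f1, 0.1, "upper"))
  dec <- compare_modes(feature_matrix(co), lx$y, lx$tumour_type, sel,
                       n_perm = 3, n_trees = 40, seed = 4)
  expect_equal(dec$chosen, "pan_cancer")
})

test_that("pruning drops the unaffected type and re-evaluates", {
  # driver affecting 2 of 3 selected types: the unaffected one is pruned
  cfg <- cohort_config(
    n_samples = 400, n_genes = 400, n_coding = 160, seed = 19,
    drivers = list(driver_spec("SP2", "tumour_specific",
                               affected_types = c("TTA", "TTB"),
                               effect_size = 1.5)))
  co <- generate_cohort(cfg)
  lx <- labelled_xy(co, "SP2", setting = "snv")
  pr <- prune_types(feature_matrix(co), lx$y, lx$tumour_type,
                    c("TTA", "TTB", "TTC"), n_trees = 40, seed = 2)
  expect_equal(pr$types, c("TTA", "TTB"))
  expect_equal(pr$history$action, c("dropped", "kept"))
  expect_equal(pr$history$worst_type[1], "TTC")
  # all types within delta of the pooled score: selection unchanged
  pr2 <- prune_types(feature_matrix(co), lx$y, lx$tumour_type,
                     c("TTA", "TTB"), n_trees = 40, seed = 2)
  expect_equal(pr2$types, c("TTA", "TTB"))
  expect_equal(pr2$history$action, "kept")
})
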