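test_that("config validation rejects inconsistent worlds", {
  expect_error(cohort_config(tumour_types = c(A = 0.5, B = 0.4)),
               "sum to 1")
  expect_error(cohort_config(n_coding = 5000), "n_coding")
  expect_error(driver_spec("G", "null", effect_size = 1), "effect_size = 0")
  expect_error(driver_spec("G", "tumour_specific"), "affected_types")
  expect_error(driver_spec("G", "pan_cancer", affected_types = "TTB"),
               "only valid for tumour_specific")
  expect_error(driver_spec("G", "pan_cancer", cna_fraction = 1.2), "\\[0, 1\\]")
  expect_error(
    cohort_config(drivers = list(driver_spec("G", "tumour_specific",
                                             affected_types = "NOPE"))),
    "unknown affected_types")
})

test_that("generation is deterministic and class counts are conserved", {
  co1 <- generate_cohort(small_cfg())
  co2 <- generate_cohort(small_cfg())
  expect_identical(co1$expr, co2$expr)
  expect_identical(co1$variants, co2$variants)
  expect_identical(co1$truth, co2$truth)

  co <- small_cohort()
  # counts per tumour type follow the configured fractions exactly
  d <- small_cfg()$drivers[[1]]
  for (tt in unique(co$samples$tumour_type)) {
    in_tt <- co$samples$tumour_type == tt
    cls <- co$truth$sample_class$PANX[in_tt]
    expect_equal(sum(cls == "mutant"), round(d$mutant_fraction * sum(in_tt)))
    expect_equal(sum(cls == "excluded"), round(d$silent_fraction * sum(in_tt)))
  }
  # every mutant sample has at least one alteration record for the driver
  for (g in names(co$truth$drivers)) {
    muts <- co$samples$sample_id[co$truth$sample_class[[g]] == "mutant"]
    recorded <- unique(c(
      co$variants$sample_id[co$variants$gene_id == g],
      co$cna$sample_id[co$cna$gene_id == g],
      co$sv$sample_id[co$sv$gene_id == g]))
    expect_true(all(muts %in% recorded))
  }
})

test_that("planted effect size is recovered from the emitted matrix", {
  # pan-cancer driver, 20 signature genes, effect 1.5, noise 1, n = 600
  cfg <- cohort_config(
    n_samples = 600, n_genes = 800, n_coding = 300, seed = 5,
    drivers = list(driver_spec("DRV", "pan_cancer", effect_size = 1.5)))
  co <- generate_cohort(cfg)
  tr <- co$truth$drivers$DRV
  lg <- log2(co$expr + 1)
  mut <- co$truth$sample_class$DRV == "mutant"
  wt <- co$truth$sample_class$DRV == "wildtype"
  diffs <- vapply(seq_along(tr$signature_genes), function(i) {
    g <- tr$signature_genes[i]
    (mean(lg[g, mut]) - mean(lg[g, wt])) * tr$signature_sign[i]
  }, numeric(1))
  expect_equal(mean(diffs), 1.5, tolerance = 0.15 / 1.5)
})

test_that("null driver leaves signature slots distribution-identical", {
  cfg <- cohort_config(
    n_samples = 400, n_genes = 400, n_coding = 150, seed = 21,
    drivers = list(driver_spec("DRV", "null", effect_size = 0,
                               n_signature = 40)))
  co <- generate_cohort(cfg)
  tr <- co$truth$drivers$DRV
  lg <- log2(co$expr + 1)
  mut <- co$truth$sample_class$DRV == "mutant"
  wt <- co$truth$sample_class$DRV == "wildtype"
  pvals <- vapply(tr$signature_genes, function(g)
    wilcox.test(lg[g, mut], lg[g, wt])$p.value, numeric(1))
  # ~5% rejections at alpha 0.05; allow a generous binomial band for 40 genes
  expect_lte(sum(pvals < 0.05), 7)
})

test_that("cis dosage correlates copy number with in-window expression only", {
  cfg <- cohort_config(
    n_samples = 400, n_genes = 600, n_coding = 250, seed = 31,
    drivers = list(driver_spec("DRV", "pan_cancer", cna_fraction = 0.8,
                               cis_dosage_coef = 0.5)))
  co <- generate_cohort(cfg)
  tr <- co$truth$drivers$DRV
  lg <- log2(co$expr + 1)
  cn <- tr$copy_number
  cis <- setdiff(tr$cis_genes, "DRV")
  r_cis <- vapply(cis, function(g) cor(cn, lg[g, ]), numeric(1))
  expect_gt(mean(r_cis), 0.2)
  # out-of-window genes on other chromosomes: no dosage correlation
  far <- setdiff(co$genes$gene_id[co$genes$chrom == "chr10"],
                 tr$signature_genes)[1:20]
  r_far <- vapply(far, function(g) cor(cn, lg[g, ]), numeric(1))
  expect_lt(max(abs(r_far)), 0.25)
  expect_lt(abs(mean(r_far)), 0.05)
})

test_that("signature genes stay clear of the cis window by construction", {
  co <- small_cohort()
  for (g in names(co$truth$drivers)) {
    tr <- co$truth$drivers[[g]]
    expect_length(intersect(tr$signature_genes, tr$cis_genes), 0)
    # stronger: signature genes sit on driver-free chromosomes
    sig_chr <- co$genes$chrom[match(tr$signature_genes, co$genes$gene_id)]
    expect_false(any(sig_chr %in% paste0("chr", seq_along(co$truth$drivers))))
  }
})

test_that("zero-effect, zero-dosage cohort is independent of alterations", {
  cfg <- cohort_config(
    n_samples = 300, n_genes = 300, n_coding = 120, seed = 41,
    drivers = list(driver_spec("DRV", "null", effect_size = 0,
                               cna_fraction = 0.5, cis_dosage_coef = 0)))
  co <- generate_cohort(cfg)
  lg <- log2(co$expr + 1)
  mut <- co$truth$sample_class$DRV == "mutant"
  wt <- co$truth$sample_class$DRV == "wildtype"
  # permutation test on the mean signature-slot difference
  tr <- co$truth$drivers$DRV
  sig_mean <- colMeans(lg[tr$signature_genes, ])
  obs <- mean(sig_mean[mut]) - mean(sig_mean[wt])
  set.seed(1)
  null <- replicate(200, {
    sh <- sample(which(mut | wt))
    m2 <- sh[seq_len(sum(mut))]
    mean(sig_mean[m2]) - mean(sig_mean[setdiff(sh, m2)])
  })
  expect_gt(mean(abs(null) >= abs(obs)), 0.05)
})
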