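# Shared synthetic fixtures, generated in code and cached per test session.
# Forest sizes in tests are scaled down from the 1000-tree package default for
# runtime; generator parameters stay at the stated defaults.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- make()
  .fixture_cache[[key]]
}

# small cohort for unit tests: one of each driver kind
small_cfg <- function(seed = 11) {
  cohort_config(
    n_samples = 300, n_genes = 500, n_coding = 200, seed = seed,
    drivers = list(
      driver_spec("PANX", "pan_cancer", effect_size = 1.5, cna_fraction = 0.4,
                  cis_dosage_coef = 0.5, cryptic_fraction = 0.3),
      driver_spec("SPEC", "tumour_specific", affected_types = "TTB",
                  effect_size = 1.5),
      driver_spec("NULLG", "null", effect_size = 0)))
}

small_cohort <- function() cached("small", function() generate_cohort(small_cfg()))

# default acceptance-scale cohort: 600 samples x 2000 transcripts, 4 tumour
# types, one pan-cancer + one tumour-specific + one null driver, effect 1.5
acceptance_cfg <- function(seed) {
  cohort_config(
    n_samples = 600, n_genes = 2000, n_coding = 600, seed = seed,
    drivers = list(
      driver_spec("PANX", "pan_cancer", effect_size = 1.5,
                  cna_fraction = 0.3, cis_dosage_coef = 0.5,
                  cryptic_fraction = 0.3),
      driver_spec("SPEC", "tumour_specific", affected_types = "TTB",
                  effect_size = 1.5),
      driver_spec("NULLG", "null", effect_size = 0)))
}

# labelled mutant/wildtype feature matrix for one gene of a cohort
labelled_xy <- function(cohort, gene, setting = "snv_cna") {
  lab <- build_labels(cohort, gene, setting)
  ids <- names(lab$label)[lab$label %in% c("mutant", "wildtype")]
  X <- feature_matrix(cohort)[ids, , drop = FALSE]
  y <- stats::setNames(
    ifelse(lab$label[ids] == "mutant", "mutant", "wildtype"), ids)
  list(X = X, y = y, labels = lab,
       tumour_type = cohort$samples$tumour_type[
         match(ids, cohort$samples$sample_id)])
}

# hand-built minimal cohort for labelling edge cases: explicit alteration
# tables, expression is irrelevant noise
toy_cohort <- function(variants = NULL, cna = NULL, sv = NULL, n = 8) {
  ids <- sprintf("T%02d", seq_len(n))
  genes <- data.frame(
    gene_id = c("GENE", paste0("tx", 1:4)),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(5e6, 1e6, 9e6, 2e6, 4e6), end = c(5e6, 1e6, 9e6, 2e6, 4e6) + 999,
    coding = TRUE, stringsAsFactors = FALSE)
  set.seed(42)
  expr <- matrix(runif(nrow(genes) * n, 0, 100), nrow(genes), n,
                 dimnames = list(genes$gene_id, ids))
  empty <- function(cols) stats::setNames(
    as.data.frame(rep(list(character(0)), length(cols))), cols)
  structure(list(
    expr = expr, genes = genes,
    samples = data.frame(sample_id = ids, cohort = "TOY",
                         tumour_type = rep(c("AA", "BB"), length.out = n),
                         site_class = "primary", stringsAsFactors = FALSE),
    variants = if (is.null(variants))
      empty(c("sample_id", "gene_id", "consequence", "origin")) else variants,
    cna = if (is.null(cna)) {
      z <- empty(c("sample_id", "gene_id", "copy_number"))
      z$copy_number <- integer(0); z
    } else cna,
    sv = if (is.null(sv)) empty(c("sample_id", "gene_id", "sv_type")) else sv,
    truth = NULL, config = NULL), class = "driver_cohort")
}
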