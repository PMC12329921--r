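#' Specify a synthetic driver gene
#'
#' Describes one driver gene planted in a synthetic cohort: where it sits in
#' the genome, which samples are mutated, what its mutation does to the
#' transcriptome, and how its alterations are split between small variants,
#' copy-number events and structural variants.
#'
#' `pattern_kind` encodes the transcriptional-pattern ground truth:
#' `"pan_cancer"` shifts the signature genes in mutant samples of every tumour
#' type, `"tumour_specific"` only in `affected_types`, and `"null"` plants no
#' signature at all (`effect_size` must then be 0).
#'
#' @param gene_id driver identifier, becomes a transcript id in the cohort.
#' @param pattern_kind one of `"pan_cancer"`, `"tumour_specific"`, `"null"`.
#' @param affected_types tumour types carrying the signature; required for
#'   (and only allowed with) `pattern_kind = "tumour_specific"`.
#' @param n_signature number of signature transcripts; the generator picks them
#'   from coding transcripts on chromosomes that carry no driver, so signature
#'   and cis-dosage confound are separable by construction.
#' @param effect_size shift, in log2(TPM+1) units, applied to signature genes
#'   in mutant (and cryptic) samples.
#' @param direction_mix fraction of signature genes shifted up in mutants; the
#'   rest are shifted down.
#' @param mutant_fraction fraction of samples mutated per tumour type; either a
#'   single number or a named vector over tumour types.
#' @param cna_fraction fraction of mutant samples whose alteration is a
#'   high-level copy-number event (copy number 0 or 4) instead of an SNV/INDEL.
#' @param sv_fraction fraction of mutant samples whose alteration is a
#'   structural variant instead of an SNV/INDEL.
#' @param cis_window_mb genes on the driver chromosome within this distance
#'   (Mb) of the driver locus receive the copy-number cis-dosage effect.
#' @param cis_dosage_coef expression change in log2(TPM+1) units per copy
#'   deviation from diploid for genes inside the cis window.
#' @param silent_fraction fraction of samples per tumour type carrying only a
#'   non-impactful variant (synonymous/UTR/intron class); these are the
#'   "excluded" group downstream.
#' @param cryptic_fraction fraction of the silent group that is cryptically
#'   impactful: annotated with an intron variant but carrying the full mutant
#'   expression shift (intron-retention-like events).
#' @return object of class `"driver_spec"`.
#' @seealso [cohort_config()], [generate_cohort()]
#' @export
driver_spec <- function(gene_id,
                        pattern_kind = c("pan_cancer", "tumour_specific", "null"),
                        affected_types = character(),
                        n_signature = 20,
                        effect_size = 1.5,
                        direction_mix = 0.5,
                        mutant_fraction = 0.3,
                        cna_fraction = 0,
                        sv_fraction = 0,
                        cis_window_mb = 3,
                        cis_dosage_coef = 0,
                        silent_fraction = 0.1,
                        cryptic_fraction = 0) {
  pattern_kind <- match.arg(pattern_kind)
  fracs <- c(direction_mix = direction_mix, cna_fraction = cna_fraction,
             sv_fraction = sv_fraction, silent_fraction = silent_fraction,
             cryptic_fraction = cryptic_fraction, mutant_fraction)
  if (any(fracs < 0 | fracs > 1))
    stop("driver_spec('", gene_id, "'): all fractions must lie in [0, 1]")
  if (cna_fraction + sv_fraction > 1)
    stop("driver_spec('", gene_id, "'): cna_fraction + sv_fraction > 1")
  if (pattern_kind == "null" && effect_size != 0)
    stop("driver_spec('", gene_id, "'): pattern_kind 'null' requires effect_size = 0")
  if (pattern_kind == "tumour_specific" && length(affected_types) == 0)
    stop("driver_spec('", gene_id, "'): tumour_specific needs affected_types")
  if (pattern_kind != "tumour_specific" && length(affected_types) > 0)
    stop("driver_spec('", gene_id, "'): affected_types only valid for tumour_specific")
  if (n_signature < 1 || cis_window_mb < 0)
    stop("driver_spec('", gene_id, "'): counts and windows must be positive")
  structure(list(
    gene_id = gene_id, pattern_kind = pattern_kind,
    affected_types = affected_types, n_signature = as.integer(n_signature),
    effect_size = effect_size, direction_mix = direction_mix,
    mutant_fraction = mutant_fraction, cna_fraction = cna_fraction,
    sv_fraction = sv_fraction, cis_window_mb = cis_window_mb,
    cis_dosage_coef = cis_dosage_coef, silent_fraction = silent_fraction,
    cryptic_fraction = cryptic_fraction), class = "driver_spec")
}

#' Configure a synthetic tumour cohort
#'
#' The stated world of all tests: a pan-cancer cohort of bulk expression
#' profiles with tumour-type baseline structure, planted driver signatures,
#' copy-number cis-dosage of chromosomal neighbours, per-type class imbalance,
#' and a group of nominally silent variants, some cryptically impactful.
#'
#' Expression is additive in log2(TPM+1): per-transcript baseline +
#' tumour-type offset + driver signature shift (mutants of affected types) +
#' cis-dosage term + Gaussian noise; TPM = 2^x - 1 clipped at zero.
#'
#' @param n_samples total samples (default 600).
#' @param tumour_types named numeric vector of tumour-type proportions; must
#'   sum to 1 within 1e-9.
#' @param n_genes total transcripts simulated (default 2000).
#' @param n_coding number of transcripts flagged protein-coding (default 600).
#' @param drivers list of [driver_spec()] objects, at most one per chromosome
#'   (each driver occupies its own chromosome).
#' @param noise_sd per-observation Gaussian noise SD in log2(TPM+1) units.
#' @param baseline_sd SD of per-tumour-type, per-transcript baseline offsets.
#' @param seed master seed for the cohort draw; all sample-level tables derive
#'   child seeds from it by fixed offsets, so the cohort is fully
#'   reproducible. The world itself — genome layout, per-transcript baselines,
#'   tumour-type offsets, signature assignments — is a deterministic function
#'   of the config's structural fields and does not change with `seed`:
#'   different seeds draw new patients from the same biology, which is what
#'   cross-cohort validation assumes.
#' @return object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_samples = 600,
                          tumour_types = c(TTA = 0.25, TTB = 0.25,
                                           TTC = 0.25, TTD = 0.25),
                          n_genes = 2000, n_coding = 600,
                          drivers = list(), noise_sd = 1, baseline_sd = 1,
                          seed = 1) {
  if (abs(sum(tumour_types) - 1) > 1e-9)
    stop("tumour_type proportions must sum to 1 (got ", sum(tumour_types), ")")
  if (is.null(names(tumour_types)) || anyDuplicated(names(tumour_types)))
    stop("tumour_types must have unique names")
  if (n_samples < 1 || n_genes < 1 || n_coding < 1)
    stop("all counts must be positive")
  if (n_coding > n_genes) stop("n_coding must not exceed n_genes")
  if (length(drivers) > 22)
    stop("at most 22 drivers (one per chromosome)")
  for (d in drivers) {
    if (!inherits(d, "driver_spec")) stop("drivers must be driver_spec objects")
    bad <- setdiff(d$affected_types, names(tumour_types))
    if (length(bad))
      stop("driver ", d$gene_id, ": unknown affected_types ",
           paste(bad, collapse = ", "))
    if (!is.null(names(d$mutant_fraction))) {
      bad <- setdiff(names(d$mutant_fraction), names(tumour_types))
      if (length(bad))
        stop("driver ", d$gene_id, ": unknown tumour types in mutant_fraction")
    }
  }
  ids <- vapply(drivers, `[[`, "", "gene_id")
  if (anyDuplicated(ids)) stop("duplicate driver gene_ids")
  structure(list(n_samples = as.integer(n_samples),
                 tumour_types = tumour_types, n_genes = as.integer(n_genes),
                 n_coding = as.integer(n_coding), drivers = drivers,
                 noise_sd = noise_sd, baseline_sd = baseline_sd,
                 seed = as.integer(seed)), class = "cohort_config")
}

# simulated genome scale: 22 chromosomes x 14 Mb, i.e. one transcript per
# ~150 kb at the default 2000 transcripts -- the gene density of a real
# genome, scaled down, so Mb-scale proximity rules behave realistically
.SIM_N_CHROM <- 22L
.SIM_CHROM_MB <- 14

.impactful_terms <- c("stop_gained", "missense", "frameshift", "splice_site")
.silent_terms <- c("synonymous", "5_prime_UTR", "3_prime_UTR",
                   "upstream", "downstream")

# fixed seed of the world stage of generate_cohort (see there)
.WORLD_SEED <- 424243L

# integer counts per group matching fractions as closely as possible
.exact_counts <- function(n, props) {
  cnt <- floor(n * props)
  rem <- n - sum(cnt)
  if (rem > 0) {
    frac <- n * props - cnt
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    cnt[add] <- cnt[add] + 1
  }
  cnt
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Emits the full input set of the analysis pipeline -- expression matrix,
#' sample metadata, variant, CNA and SV call tables -- together with a
#' `truth` record of every planted pattern, sample class and cryptic flag.
#' Deterministic: the same config (including its seed) yields byte-identical
#' output.
#'
#' @param config a [cohort_config()].
#' @return object of class `"driver_cohort"`: list with elements `expr`
#'   (transcripts x samples TPM matrix), `genes` (transcript annotation:
#'   gene_id, chrom, start, end, coding), `samples` (sample_id, cohort,
#'   tumour_type, site_class), `variants`, `cna`, `sv`, `truth`, `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_samples
  p <- config$n_genes
  types <- names(config$tumour_types)

  ## world stage: genome layout, baselines, tumour-type structure and
  ## signature assignments are properties of the simulated biology, fixed for
  ## a given config regardless of its seed -- so cohorts drawn with different
  ## seeds are new samples from the SAME world (a requirement for
  ## cross-cohort transfer and cohort-merging QC to be meaningful)
  set.seed(.WORLD_SEED)
  chrom_of <- rep(seq_len(.SIM_N_CHROM), length.out = p)
  chrom_of <- sort(chrom_of)
  pos <- unlist(lapply(split(seq_len(p), chrom_of), function(i)
    sort(sample.int(.SIM_CHROM_MB * 1e6 - 1000, length(i)))), use.names = FALSE)
  genes <- data.frame(
    gene_id = sprintf("tx%05d", seq_len(p)),
    chrom = paste0("chr", chrom_of),
    start = pos, end = pos + 999L,
    coding = seq_len(p) %in% sample.int(p, config$n_coding),
    stringsAsFactors = FALSE)

  # each driver takes over the transcript nearest the centre of its own chrom
  drv_row <- integer(length(config$drivers))
  for (k in seq_along(config$drivers)) {
    on_chr <- which(chrom_of == k)
    row <- on_chr[which.min(abs(genes$start[on_chr] - .SIM_CHROM_MB * 5e5))]
    genes$gene_id[row] <- config$drivers[[k]]$gene_id
    genes$coding[row] <- TRUE
    drv_row[k] <- row
  }

  # still world stage: per-driver signature transcripts (coding, on
  # driver-free chromosomes), shift directions and cis-window membership
  driver_chroms <- paste0("chr", seq_along(config$drivers))
  world <- vector("list", length(config$drivers))
  for (k in seq_along(config$drivers)) {
    d <- config$drivers[[k]]
    drow <- drv_row[k]
    eligible <- which(genes$coding & !(genes$chrom %in% driver_chroms))
    if (length(eligible) < d$n_signature)
      stop("configuration error: not enough off-driver coding transcripts ",
           "for the signature of ", d$gene_id)
    sig <- sort(sample(eligible, d$n_signature))
    n_up <- round(d$direction_mix * d$n_signature)
    sig_sign <- rep(-1, d$n_signature)
    if (n_up > 0) sig_sign[seq_len(n_up)] <- 1
    sig_sign <- sample(sig_sign)
    cis <- which(genes$chrom == genes$chrom[drow] &
                   abs(genes$start - genes$start[drow]) <= d$cis_window_mb * 1e6)
    if (length(intersect(sig, cis)))
      stop("configuration error: signature genes of ", d$gene_id,
           " fall inside its cis window")
    world[[k]] <- list(sig = sig, sig_sign = sig_sign, cis = cis,
                       drow = drow)
  }
  baseline <- runif(p, 3, 8)
  type_offset <- matrix(rnorm(length(types) * p, 0, config$baseline_sd),
                        nrow = length(types),
                        dimnames = list(types, NULL))

  ## samples (child seed +2)
  set.seed(config$seed + 2L)
  type_counts <- .exact_counts(n, config$tumour_types)
  samples <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    cohort = "SIM",
    tumour_type = sample(rep(types, type_counts)),
    site_class = sample(c("primary", "metastatic"), n, TRUE, c(0.8, 0.2)),
    stringsAsFactors = FALSE)

  ## per-driver sample classes and alteration assignments (child seed +3)
  set.seed(config$seed + 3L)
  truth_drivers <- list()
  sample_class <- matrix("wildtype", n, length(config$drivers),
                         dimnames = list(samples$sample_id,
                                         vapply(config$drivers, `[[`, "", "gene_id")))
  cryptic_flag <- matrix(FALSE, n, length(config$drivers),
                         dimnames = dimnames(sample_class))
  var_rows <- list(); cna_rows <- list(); sv_rows <- list()

  for (k in seq_along(config$drivers)) {
    d <- config$drivers[[k]]
    drow <- drv_row[k]
    cna_carrier <- rep(FALSE, n)
    cn_state <- rep(2L, n)
    for (tt in types) {
      idx <- which(samples$tumour_type == tt)
      mf <- if (!is.null(names(d$mutant_fraction)))
        unname(d$mutant_fraction[tt]) else d$mutant_fraction
      if (is.na(mf)) mf <- 0
      n_mut <- round(mf * length(idx))
      n_sil <- round(d$silent_fraction * length(idx))
      pick <- sample(idx, n_mut + n_sil)
      mut <- pick[seq_len(n_mut)]
      sil <- pick[n_mut + seq_len(n_sil)]
      sample_class[mut, k] <- "mutant"
      sample_class[sil, k] <- "excluded"

      # partition mutants by alteration type: CNA / SV / SNV-INDEL
      n_cna <- round(d$cna_fraction * n_mut)
      n_sv <- round(d$sv_fraction * n_mut)
      shuf <- sample(mut)
      mut_cna <- shuf[seq_len(n_cna)]
      mut_sv <- shuf[n_cna + seq_len(n_sv)]
      mut_snv <- if (n_cna + n_sv > 0) shuf[-seq_len(n_cna + n_sv)] else shuf
      if (length(mut_snv))
        var_rows[[length(var_rows) + 1]] <- data.frame(
          sample_id = samples$sample_id[mut_snv], gene_id = d$gene_id,
          consequence = sample(.impactful_terms, length(mut_snv), TRUE),
          origin = sample(c("somatic", "germline"), length(mut_snv), TRUE,
                          c(0.9, 0.1)),
          stringsAsFactors = FALSE)
      if (length(mut_cna)) {
        cn <- sample(c(0L, 4L), length(mut_cna), TRUE)
        cn_state[mut_cna] <- cn
        cna_carrier[mut_cna] <- TRUE
        cna_rows[[length(cna_rows) + 1]] <- data.frame(
          sample_id = samples$sample_id[mut_cna], gene_id = d$gene_id,
          copy_number = cn, stringsAsFactors = FALSE)
      }
      if (length(mut_sv))
        sv_rows[[length(sv_rows) + 1]] <- data.frame(
          sample_id = samples$sample_id[mut_sv], gene_id = d$gene_id,
          sv_type = sample(c("deletion", "translocation", "inversion"),
                           length(mut_sv), TRUE),
          stringsAsFactors = FALSE)

      # silent group: cryptic subset carries intron variants + mutant shift
      n_cry <- round(d$cryptic_fraction * n_sil)
      cry <- sil[seq_len(n_cry)]
      plain <- sil[-seq_len(n_cry)]
      if (n_cry == 0) { cry <- integer(); plain <- sil }
      cryptic_flag[cry, k] <- TRUE
      if (length(cry))
        var_rows[[length(var_rows) + 1]] <- data.frame(
          sample_id = samples$sample_id[cry], gene_id = d$gene_id,
          consequence = "intron", origin = "somatic",
          stringsAsFactors = FALSE)
      if (length(plain))
        var_rows[[length(var_rows) + 1]] <- data.frame(
          sample_id = samples$sample_id[plain], gene_id = d$gene_id,
          consequence = sample(.silent_terms, length(plain), TRUE),
          origin = sample(c("somatic", "germline"), length(plain), TRUE,
                          c(0.9, 0.1)),
          stringsAsFactors = FALSE)
    }

    truth_drivers[[d$gene_id]] <- list(
      gene_id = d$gene_id, pattern_kind = d$pattern_kind,
      affected_types = d$affected_types,
      locus = list(chrom = genes$chrom[drow], start = genes$start[drow],
                   end = genes$end[drow]),
      signature_genes = genes$gene_id[world[[k]]$sig],
      signature_sign = world[[k]]$sig_sign,
      cis_genes = genes$gene_id[world[[k]]$cis],
      cna_carriers = samples$sample_id[cna_carrier],
      copy_number = cn_state)
  }

  ## expression noise (child seed +4)
  set.seed(config$seed + 4L)
  x <- matrix(baseline, p, n) + t(type_offset[samples$tumour_type, ])
  for (k in seq_along(config$drivers)) {
    d <- config$drivers[[k]]
    tr <- truth_drivers[[d$gene_id]]
    sig <- match(tr$signature_genes, genes$gene_id)
    shifted <- sample_class[, k] == "mutant" | cryptic_flag[, k]
    if (d$pattern_kind == "tumour_specific")
      shifted <- shifted & samples$tumour_type %in% d$affected_types
    if (d$pattern_kind != "null" && any(shifted))
      x[sig, shifted] <- x[sig, shifted] + tr$signature_sign * d$effect_size
    if (d$cis_dosage_coef != 0) {
      cis <- match(tr$cis_genes, genes$gene_id)
      carrier <- which(tr$copy_number != 2L)
      for (s in carrier)
        x[cis, s] <- x[cis, s] + d$cis_dosage_coef * (tr$copy_number[s] - 2)
    }
  }
  x <- x + matrix(rnorm(p * n, 0, config$noise_sd), p, n)
  expr <- pmax(2^x - 1, 0)
  dimnames(expr) <- list(genes$gene_id, samples$sample_id)

  truth <- list(
    drivers = truth_drivers,
    sample_class = as.data.frame(sample_class, stringsAsFactors = FALSE),
    cryptic = as.data.frame(cryptic_flag))

  empty_var <- data.frame(sample_id = character(), gene_id = character(),
                          consequence = character(), origin = character(),
                          stringsAsFactors = FALSE)
  empty_cna <- data.frame(sample_id = character(), gene_id = character(),
                          copy_number = integer(), stringsAsFactors = FALSE)
  empty_sv <- data.frame(sample_id = character(), gene_id = character(),
                         sv_type = character(), stringsAsFactors = FALSE)

  structure(list(
    expr = expr, genes = genes, samples = samples,
    variants = if (length(var_rows)) do.call(rbind, var_rows) else empty_var,
    cna = if (length(cna_rows)) do.call(rbind, cna_rows) else empty_cna,
    sv = if (length(sv_rows)) do.call(rbind, sv_rows) else empty_sv,
    truth = truth, config = config), class = "driver_cohort")
}

#' @export
print.driver_cohort <- function(x, ...) {
  cat("Synthetic tumour cohort: ", ncol(x$expr), " samples x ", nrow(x$expr),
      " transcripts, ", length(unique(x$samples$tumour_type)),
      " tumour types, ", length(x$config$drivers), " driver(s)\n", sep = "")
  invisible(x)
}
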