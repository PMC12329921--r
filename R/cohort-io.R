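#' Write a cohort to a directory of tab-separated files
#'
#' Emits `expression.tsv` (rows = transcripts: gene_id, chrom, start, end,
#' coding, then one TPM column per sample), `metadata.tsv`, `variants.tsv`,
#' `cna.tsv`, `sv.tsv` and `truth.json`. Numeric values are written with 17
#' significant digits so that [read_cohort()] restores them bit-exactly.
#'
#' @param cohort a `"driver_cohort"` from [generate_cohort()] or
#'   [read_cohort()].
#' @param dir output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "driver_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  tpm <- apply(cohort$expr, 2, function(v) sprintf("%.17g", v))
  expr_tab <- cbind(cohort$genes, tpm)
  data.table::fwrite(expr_tab, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE)
  data.table::fwrite(cohort$samples, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(cohort$variants, file.path(dir, "variants.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(cohort$cna, file.path(dir, "cna.tsv"), sep = "\t",
                     quote = FALSE)
  data.table::fwrite(cohort$sv, file.path(dir, "sv.tsv"), sep = "\t",
                     quote = FALSE)
  if (!is.null(cohort$truth))
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

.req_cols <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("malformed header in ", file, ": missing column(s) ",
         paste(miss, collapse = ", "))
}

#' Read a cohort from a directory written by [write_cohort()]
#'
#' Validates structure on the way in: headers must carry the expected columns,
#' sample and transcript identifiers must be unique, expression values must be
#' non-negative, and every variant/CNA/SV record must refer to a known sample.
#' An empty variant/CNA/SV file (header only) is valid. Parse errors name the
#' offending row or identifier.
#'
#' @param dir directory containing the cohort files.
#' @return a `"driver_cohort"` object; `truth` is `NULL` when `truth.json` is
#'   absent (real cohorts have no ground truth).
#' @export
read_cohort <- function(dir) {
  f_expr <- file.path(dir, "expression.tsv")
  for (f in c(f_expr, file.path(dir, c("metadata.tsv", "variants.tsv",
                                       "cna.tsv", "sv.tsv"))))
    if (!file.exists(f)) stop("missing cohort file: ", f)

  expr_tab <- as.data.frame(data.table::fread(f_expr, sep = "\t"))
  .req_cols(expr_tab, c("gene_id", "chrom", "start", "end", "coding"),
            "expression.tsv")
  genes <- expr_tab[, c("gene_id", "chrom", "start", "end", "coding")]
  if (anyDuplicated(genes$gene_id))
    stop("parse error in expression.tsv: duplicate gene_id '",
         genes$gene_id[duplicated(genes$gene_id)][1], "'")
  expr <- as.matrix(expr_tab[, setdiff(names(expr_tab), names(genes)),
                             drop = FALSE])
  if (!is.numeric(expr)) stop("parse error in expression.tsv: non-numeric TPM")
  bad <- which(expr < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("parse error in expression.tsv: negative TPM at transcript '",
         genes$gene_id[bad[1, 1]], "', sample '", colnames(expr)[bad[1, 2]], "'")
  rownames(expr) <- genes$gene_id

  samples <- as.data.frame(data.table::fread(file.path(dir, "metadata.tsv"),
                                             sep = "\t", colClasses = "character"))
  .req_cols(samples, c("sample_id", "cohort", "tumour_type", "site_class"),
            "metadata.tsv")
  if (anyDuplicated(samples$sample_id))
    stop("parse error in metadata.tsv: duplicate sample_id '",
         samples$sample_id[duplicated(samples$sample_id)][1], "'")
  if (!setequal(samples$sample_id, colnames(expr)) ||
      nrow(samples) != ncol(expr))
    stop("metadata.tsv samples do not match expression.tsv columns")
  expr <- expr[, samples$sample_id, drop = FALSE]

  read_calls <- function(file, cols, int_cols = character()) {
    df <- as.data.frame(data.table::fread(file.path(dir, file), sep = "\t"))
    if (nrow(df) == 0 && ncol(df) == 0)  # header-only empty file
      df <- stats::setNames(as.data.frame(rep(list(character(0)), length(cols))),
                            cols)
    .req_cols(df, cols, file)
    for (cc in setdiff(cols, int_cols)) df[[cc]] <- as.character(df[[cc]])
    for (cc in int_cols) df[[cc]] <- as.integer(df[[cc]])
    unknown <- setdiff(df$sample_id, samples$sample_id)
    if (length(unknown))
      stop("parse error in ", file, ": unknown sample_id '", unknown[1], "'")
    df
  }
  variants <- read_calls("variants.tsv",
                         c("sample_id", "gene_id", "consequence", "origin"))
  cna <- read_calls("cna.tsv", c("sample_id", "gene_id", "copy_number"),
                    int_cols = "copy_number")
  sv <- read_calls("sv.tsv", c("sample_id", "gene_id", "sv_type"))

  truth <- NULL
  f_truth <- file.path(dir, "truth.json")
  if (file.exists(f_truth)) {
    truth <- jsonlite::read_json(f_truth, simplifyVector = TRUE)
    truth$sample_class <- as.data.frame(truth$sample_class)
    truth$cryptic <- as.data.frame(truth$cryptic)
    rownames(truth$sample_class) <- rownames(truth$cryptic) <- samples$sample_id
    truth$drivers <- lapply(truth$drivers, function(d) {
      d$signature_sign <- as.numeric(d$signature_sign)
      d$copy_number <- as.integer(d$copy_number)
      d
    })
  }

  structure(list(expr = expr, genes = genes, samples = samples,
                 variants = variants, cna = cna, sv = sv, truth = truth,
                 config = NULL), class = "driver_cohort")
}
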