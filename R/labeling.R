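#' Default consequence-impact vocabulary
#'
#' Maps variant consequence terms to `"impactful"` (expected to disrupt the
#' protein: nonsense, missense, frameshift, splice, inframe indels, stop/start
#' loss) or `"non_impactful"` (synonymous, UTR, intronic, up/downstream,
#' intergenic). Shipped as `consequence_impact.yaml` in the package's
#' `extdata`; pass a custom file to cope with other MAF dialects. Unknown
#' terms are a hard error in [classify_consequence()], never silently dropped.
#'
#' @param file YAML file with `impactful:` and `non_impactful:` term lists;
#'   default is the packaged vocabulary.
#' @return named character vector, term -> impact class.
#' @export
impact_vocabulary <- function(file = system.file("extdata",
                                                 "consequence_impact.yaml",
                                                 package = "drivertx")) {
  v <- yaml::read_yaml(file)
  if (!all(c("impactful", "non_impactful") %in% names(v)))
    stop("vocabulary file must define 'impactful' and 'non_impactful' lists")
  out <- c(stats::setNames(rep("impactful", length(v$impactful)),
                           unlist(v$impactful)),
           stats::setNames(rep("non_impactful", length(v$non_impactful)),
                           unlist(v$non_impactful)))
  if (anyDuplicated(names(out)))
    stop("vocabulary assigns a term to both classes: ",
         names(out)[duplicated(names(out))][1])
  out
}

#' Classify variant consequence terms by expected impact
#'
#' @param term character vector of consequence terms.
#' @param vocab vocabulary from [impact_vocabulary()].
#' @return character vector, `"impactful"` or `"non_impactful"`.
#' @examples
#' classify_consequence(c("missense", "synonymous", "intron"))
#' @export
classify_consequence <- function(term, vocab = impact_vocabulary()) {
  unknown <- setdiff(unique(term), names(vocab))
  if (length(unknown))
    stop("unknown consequence term(s): ", paste(unknown, collapse = ", "),
         "; extend the vocabulary file rather than dropping them")
  unname(vocab[term])
}

#' Label every sample for one driver gene under an alteration setting
#'
#' Partitions the cohort into `mutant`, `wildtype` and
#' `excluded_non_impactful` for classifier training. A sample is mutant iff it
#' carries at least one qualifying alteration under the setting: an impactful
#' SNV/INDEL always qualifies; a high-level copy-number event qualifies when
#' the setting includes `cna`; any SV record qualifies when the setting
#' includes `sv`. Wild-type samples have no alteration record for the gene at
#' all. Samples whose only records are non-impactful SNVs/INDELs are excluded,
#' as are samples whose only alteration is of a type the setting ignores
#' (their status is ambiguous, and keeping them out keeps the wild-type class
#' clean).
#'
#' @param cohort a `"driver_cohort"`.
#' @param gene driver gene id.
#' @param setting `"snv"`, `"snv_cna"`, `"snv_sv"` or `"snv_cna_sv"`.
#' @param vocab consequence vocabulary, see [impact_vocabulary()].
#' @param origins variant origins that count; default both somatic and
#'   germline.
#' @param cna_qualifies function mapping copy numbers to a logical "high-level
#'   event" flag; default complete loss (0) or amplification to at least twice
#'   diploid (>= 4).
#' @return object of class `"label_set"`: gene, setting, and `label`, a named
#'   character vector over all samples.
#' @export
build_labels <- function(cohort, gene,
                         setting = c("snv_cna", "snv", "snv_sv", "snv_cna_sv"),
                         vocab = impact_vocabulary(),
                         origins = c("somatic", "germline"),
                         cna_qualifies = function(cn) cn == 0 | cn >= 4) {
  stopifnot(inherits(cohort, "driver_cohort"))
  setting <- match.arg(setting)
  ids <- cohort$samples$sample_id

  v <- cohort$variants[cohort$variants$gene_id == gene &
                         cohort$variants$origin %in% origins, , drop = FALSE]
  impact <- if (nrow(v)) classify_consequence(v$consequence, vocab) else character()
  has_impactful <- ids %in% v$sample_id[impact == "impactful"]
  has_silent <- ids %in% v$sample_id[impact == "non_impactful"]

  cn <- cohort$cna[cohort$cna$gene_id == gene, , drop = FALSE]
  has_cna_high <- ids %in% cn$sample_id[cna_qualifies(cn$copy_number)]
  has_cna_any <- ids %in% cn$sample_id
  sv <- cohort$sv[cohort$sv$gene_id == gene, , drop = FALSE]
  has_sv <- ids %in% sv$sample_id

  use_cna <- setting %in% c("snv_cna", "snv_cna_sv")
  use_sv <- setting %in% c("snv_sv", "snv_cna_sv")

  mutant <- has_impactful |
    (use_cna & has_cna_high) |
    (use_sv & has_sv)
  any_record <- has_impactful | has_silent | has_cna_any | has_sv
  label <- ifelse(mutant, "mutant",
                  ifelse(any_record, "excluded_non_impactful", "wildtype"))
  names(label) <- ids

  if (!any(label == "mutant") || !any(label == "wildtype"))
    stop("gene ", gene, " not analyzable under setting '", setting,
         "': empty ", if (any(label == "mutant")) "wildtype" else "mutant",
         " class")
  structure(list(gene = gene, setting = setting, label = label),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat("Labels for ", x$gene, " [", x$setting, "]: ", sep = "")
  print(table(x$label))
  invisible(x)
}
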