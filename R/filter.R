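#' Variant prioritization cascade
#'
#' Predicates for the category-specific rare-variant prioritization
#' cascade, applied over an annotated variant table whose columns are:
#' `CHROM POS REF ALT GENE CATEGORY KG_EUR GNOMAD_NFE EXAC_NFE CADD_PHRED
#' GWAVA GERP SPIDEX SPLICE_AI SIFT POLYPHEN MUTATION_TASTER
#' MUTATION_ASSESSOR FATHMM CARRIERS` (carriers comma-separated). Each
#' predicate is independent; a variant survives the cascade iff it passes
#' every applicable stage.
#'
#' @name variant_filter
NULL

variant_categories <- c("missense", "synonymous", "splicing",
                        "frameshift_indel", "nonframeshift_indel",
                        "stopgain", "stoploss", "ncRNA", "UTR",
                        "intronic", "upstream")
high_impact <- c("splicing", "frameshift_indel", "nonframeshift_indel",
                 "stopgain", "stoploss")
noncoding <- c("ncRNA", "UTR", "intronic", "upstream")

carriers_list <- function(x) {
  if (is.list(x)) return(x)
  strsplit(ifelse(is.na(x), "", as.character(x)), ",", fixed = TRUE)
}

#' Read an annotated variant table
#'
#' Tab-separated table with the columns documented in [variant_filter];
#' `col_map` lets ANNOVAR-style headers be renamed on the way in
#' (`c(theirs = "OURS")`).
#'
#' @param path file path.
#' @param col_map optional named character vector renaming input columns.
#' @return annotated variant data frame with normalized coordinates.
#' @export
read_annotated_variants <- function(path, col_map = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    hit <- match(names(col_map), names(tab))
    names(tab)[stats::na.omit(hit)] <- col_map[!is.na(hit)]
  }
  need <- c("CHROM", "POS", "REF", "ALT", "GENE", "CATEGORY", "CARRIERS")
  if (!all(need %in% names(tab)))
    stop("annotated table must have columns ", paste(need, collapse = ", "))
  bad <- setdiff(unique(tab$CATEGORY), variant_categories)
  if (length(bad)) stop("unknown variant categories: ", paste(bad, collapse = ", "))
  nk <- normalize_variant_keys(tab$CHROM, tab$POS, tab$REF, tab$ALT)
  tab$CHROM <- nk$chrom; tab$POS <- nk$pos; tab$REF <- nk$ref; tab$ALT <- nk$alt
  tab
}

#' Segregation among affected members
#'
#' A variant segregates iff every affected member is a carrier; additional
#' healthy carriers do not exclude a variant (healthy carriage is a
#' prioritization note, not a filter).
#'
#' @param variants annotated variant data frame.
#' @param affected non-empty character vector of affected ids.
#' @return logical vector, one per variant.
#' @export
shared_by_affected <- function(variants, affected) {
  if (!length(affected)) stop("affected set must be non-empty")
  vapply(carriers_list(variants$CARRIERS),
         function(cc) all(affected %in% cc), logical(1))
}

#' Population-frequency filter
#'
#' Rarity rule: with `mode = "all"` (default) every populated frequency
#' among the 1000G-EUR / GnomAD-NFE / ExAC-NFE columns must be strictly
#' below the threshold (no populated source may contradict rarity); with
#' `mode = "any"` one populated source below threshold suffices. A variant
#' absent from all three databases passes either way.
#'
#' @param variants annotated variant data frame.
#' @param threshold MAF threshold in (0, 1); default 0.05.
#' @param mode `"all"` or `"any"`.
#' @return logical vector.
#' @export
frequency_pass <- function(variants, threshold = 0.05, mode = c("all", "any")) {
  mode <- match.arg(mode)
  F <- cbind(variants$KG_EUR, variants$GNOMAD_NFE, variants$EXAC_NFE)
  n_pop <- rowSums(!is.na(F))
  below <- rowSums(!is.na(F) & F < threshold)
  if (mode == "all") n_pop == 0 | below == n_pop else n_pop == 0 | below > 0
}

damaging_labels <- list(
  SIFT = c("damaging", "deleterious", "D"),
  POLYPHEN = c("damaging", "probably_damaging", "possibly_damaging", "D", "P"),
  MUTATION_TASTER = c("damaging", "disease_causing",
                      "disease_causing_automatic", "A", "D"),
  MUTATION_ASSESSOR = c("damaging", "high", "medium", "H", "M"),
  FATHMM = c("damaging", "D")
)

#' Functional-impact filter
#'
#' Category dispatch: high-impact categories (splicing, frameshift /
#' non-frameshift indels, stopgain, stoploss) always pass. Missense
#' variants pass with CADD_Phred > 10 or when at least 2 of the 5 missense
#' tools (SIFT, PolyPhen, MutationTaster, MutationAssessor, FATHMM) call
#' damaging. Synonymous variants — and, in the WES context, non-coding ones
#' (ncRNA / UTR / intronic / upstream) — pass with any of CADD_Phred > 10,
#' GWAVA > 0.5, GERP > 4, |SPIDEX| > 4, SpliceAI > 0.4. In the WGS context
#' non-coding variants pass only with SpliceAI > 0.4. A missing score never
#' satisfies a criterion.
#'
#' @param variants annotated variant data frame.
#' @param context `"wes"` or `"wgs"`.
#' @return logical vector.
#' @export
functional_pass <- function(variants, context = c("wes", "wgs")) {
  context <- match.arg(context)
  cat_v <- variants$CATEGORY
  bad <- setdiff(unique(cat_v), variant_categories)
  if (length(bad)) stop("unknown variant categories: ", paste(bad, collapse = ", "))

  gt <- function(x, thr) !is.na(x) & x > thr
  dmg <- vapply(names(damaging_labels), function(tool) {
    x <- variants[[tool]]
    !is.na(x) & x %in% damaging_labels[[tool]]
  }, logical(nrow(variants)))
  if (is.null(dim(dmg))) dmg <- matrix(dmg, nrow = nrow(variants))
  n_damaging <- rowSums(dmg)
  score_any <- gt(variants$CADD_PHRED, 10) | gt(variants$GWAVA, 0.5) |
    gt(variants$GERP, 4) | gt(abs(variants$SPIDEX), 4) |
    gt(variants$SPLICE_AI, 0.4)

  out <- logical(nrow(variants))
  out[cat_v %in% high_impact] <- TRUE
  mis <- cat_v == "missense"
  out[mis] <- gt(variants$CADD_PHRED, 10)[mis] | n_damaging[mis] >= 2
  syn <- cat_v == "synonymous"
  out[syn] <- score_any[syn]
  nc <- cat_v %in% noncoding
  out[nc] <- if (context == "wes") score_any[nc]
             else gt(variants$SPLICE_AI, 0.4)[nc]
  out
}

#' External-cohort association-evidence filter
#'
#' A variant is retained iff it is at least nominally significant
#' (`p < alpha`) in one or more external cohorts where its key is present,
#' or its key is absent from every cohort; it is removed when present
#' somewhere and never significant.
#'
#' @param variants annotated variant data frame.
#' @param stats a [summary_stats()] table.
#' @param alpha nominal significance threshold.
#' @return logical vector.
#' @export
association_evidence_pass <- function(variants, stats, alpha = 0.05) {
  keys <- normalize_variant_keys(variants$CHROM, variants$POS,
                                 variants$REF, variants$ALT)$key
  vapply(keys, function(k) {
    pv <- stats$P[stats$key == k]
    !length(pv) || any(pv < alpha, na.rm = TRUE)
  }, logical(1), USE.NAMES = FALSE)
}

#' Keep variants inside linkage regions
#'
#' @param variants annotated variant data frame.
#' @param regions a `linkage_regions` data frame (1-based inclusive
#'   endpoints).
#' @return logical vector (`FALSE` everywhere when `regions` is empty).
#' @export
in_linkage_regions <- function(variants, regions) {
  if (!nrow(regions)) return(rep(FALSE, nrow(variants)))
  vapply(seq_len(nrow(variants)), function(i) {
    any(regions$CHROM == variants$CHROM[i] &
          regions$START <= variants$POS[i] &
          variants$POS[i] <= regions$END)
  }, logical(1))
}

#' @rdname in_linkage_regions
#' @export
intersect_linkage_regions <- function(variants, regions) {
  variants[in_linkage_regions(variants, regions), , drop = FALSE]
}

#' Run the full prioritization cascade
#'
#' Applies segregation, frequency, functional-impact, (optionally)
#' linkage-region and association-evidence filters, recording per-stage
#' outcomes. The stages are independent predicates, so the surviving set is
#' their conjunction regardless of order; the named failing stage reported
#' per variant is the first failing one in pipeline order.
#'
#' @param variants annotated variant data frame.
#' @param affected affected carrier ids (segregation stage).
#' @param stats optional [summary_stats()]; omitting it treats every key as
#'   absent (stage passes).
#' @param context `"wes"` or `"wgs"`.
#' @param regions optional `linkage_regions` adding the intersection stage.
#' @param maf frequency threshold.
#' @param alpha association threshold.
#' @param freq_mode rarity rule, see [frequency_pass()].
#' @param flag_unaffected optional ids of healthy members; adds a
#'   `NOT_IN_UNAFFECTED` annotation column to the report (a prioritization
#'   note, never a filter).
#' @return list of class `filter_report`: `stages` (variant x stage logical
#'   matrix), `fail_stage`, `survivors` (surviving rows), `genes` (unique
#'   surviving gene symbols).
#' @export
run_cascade <- function(variants, affected, stats = NULL,
                        context = c("wes", "wgs"), regions = NULL,
                        maf = 0.05, alpha = 0.05,
                        freq_mode = c("all", "any"),
                        flag_unaffected = NULL) {
  context <- match.arg(context)
  freq_mode <- match.arg(freq_mode)
  stages <- cbind(
    segregation = shared_by_affected(variants, affected),
    frequency = frequency_pass(variants, maf, freq_mode),
    functional = functional_pass(variants, context))
  if (!is.null(regions))
    stages <- cbind(stages, region = in_linkage_regions(variants, regions))
  stages <- cbind(stages,
                  association = if (is.null(stats)) rep(TRUE, nrow(variants))
                  else association_evidence_pass(variants, stats, alpha))
  pass <- rowSums(!stages) == 0
  first_fail <- apply(stages, 1, function(r)
    if (all(r)) NA_character_ else colnames(stages)[which(!r)[1]])
  survivors <- variants[pass, , drop = FALSE]
  report <- list(stages = stages, fail_stage = first_fail,
                 survivors = survivors,
                 genes = unique(survivors$GENE))
  if (!is.null(flag_unaffected)) {
    cl <- carriers_list(variants$CARRIERS)
    report$not_in_unaffected <- vapply(cl, function(cc)
      !any(flag_unaffected %in% cc), logical(1))
  }
  class(report) <- "filter_report"
  report
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d variants -> %d survivors in %d genes\n",
              nrow(x$stages), nrow(x$survivors), length(x$genes)))
  tab <- table(factor(x$fail_stage, levels = colnames(x$stages)))
  cat("failures by stage:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Write a per-stage filter report
#'
#' One row per (variant, stage) with the pass flag, mirroring the cascade's
#' audit trail.
#'
#' @param report a `filter_report`.
#' @param variants the variant table the report was computed from.
#' @param path output TSV path.
#' @export
write_filter_report <- function(report, variants, path) {
  long <- do.call(rbind, lapply(colnames(report$stages), function(s)
    data.frame(CHROM = variants$CHROM, POS = variants$POS,
               REF = variants$REF, ALT = variants$ALT,
               GENE = variants$GENE, STAGE = s,
               PASS = report$stages[, s], stringsAsFactors = FALSE)))
  utils::write.table(long, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
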