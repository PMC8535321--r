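#' Risk-locus weight
#'
#' Weights are natural-log odds ratios. For a protective allele the
#' reciprocal rule applies: any allele different from the protective one is
#' treated as the risk allele, with weight `ln(1 / OR)` applied to the count
#' of non-protective alleles.
#'
#' @param odds_ratio reported odds ratio (> 0).
#' @param protective logical; is the reported allele protective?
#' @return the log-odds weight.
#' @export
locus_weight <- function(odds_ratio, protective = FALSE) {
  if (any(odds_ratio <= 0)) stop("odds ratios must be positive")
  ifelse(rep_len(protective, length(odds_ratio)),
         log(1 / odds_ratio), log(odds_ratio))
}

#' Read a risk-score panel
#'
#' Tab-separated panel file with columns `LOCUS`, `OR`, `PROTECTIVE`
#' (0/1 or TRUE/FALSE) and optionally `FREQ` (risk-allele frequency, used
#' only for the impute-missing dosage policy).
#'
#' @param path file path.
#' @return data frame with the panel columns.
#' @export
read_score_panel <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("LOCUS", "OR", "PROTECTIVE") %in% names(tab)))
    stop("panel must have columns LOCUS, OR, PROTECTIVE")
  if (anyDuplicated(tab$LOCUS)) stop("duplicated panel loci")
  tab$PROTECTIVE <- as.logical(tab$PROTECTIVE)
  if (is.null(tab$FREQ)) tab$FREQ <- NA_real_
  tab
}

#' Weighted genetic risk score
#'
#' `wGRS = sum over panel loci of weight x risk-allele dosage`, with
#' [locus_weight()] weights. Dosages are risk-allele counts in
#' `{0, 1, 2}`; for a protective locus the risk allele is any allele other
#' than the protective one, so the supplied dosage must count non-protective
#' alleles. Missing dosages are either skipped (default, never fabricates
#' risk) or imputed as `2 x FREQ` when the panel carries frequencies.
#'
#' @param panel panel data frame (see [read_score_panel()]).
#' @param dosages named numeric vector (one subject) or a loci-by-subject
#'   matrix with rownames matching `panel$LOCUS`.
#' @param missing `"skip"` or `"impute"`.
#' @return numeric score(s), one per subject.
#' @export
compute_wgrs <- function(panel, dosages, missing = c("skip", "impute")) {
  missing <- match.arg(missing)
  if (is.null(dim(dosages))) dosages <- matrix(dosages, ncol = 1,
                                               dimnames = list(names(dosages), NULL))
  idx <- match(panel$LOCUS, rownames(dosages))
  if (anyNA(idx)) stop("dosages missing panel loci: ",
                       paste(panel$LOCUS[is.na(idx)], collapse = ", "))
  D <- dosages[idx, , drop = FALSE]
  if (!all(is.na(D) | (D %in% 0:2)))
    stop("dosages must be in {0, 1, 2} or NA")
  w <- locus_weight(panel$OR, panel$PROTECTIVE)
  if (missing == "impute") {
    if (any(is.na(D) & is.na(panel$FREQ)))
      stop("impute policy needs panel FREQ for loci with missing dosages")
    imp <- 2 * panel$FREQ
    D[] <- ifelse(is.na(D), imp[row(D)], D)
  }
  colSums(w * D, na.rm = TRUE)
}

#' Compare risk-score distributions between two groups
#'
#' Classical two-sample t test (equal-variance by default; Welch behind the
#' `welch` flag) with a two-sided p-value. Degenerate zero-variance input is
#' handled by convention: equal means give `t = 0, p = 1`.
#'
#' @param scores_a,scores_b numeric vectors (each of length >= 2).
#' @param welch use the Welch unequal-variance form.
#' @return list with `t`, `df` and `p`.
#' @export
compare_groups <- function(scores_a, scores_b, welch = FALSE) {
  if (length(scores_a) < 2 || length(scores_b) < 2)
    stop("each group needs at least two values")
  if (stats::var(scores_a) == 0 && stats::var(scores_b) == 0) {
    if (mean(scores_a) == mean(scores_b))
      return(list(t = 0, df = length(scores_a) + length(scores_b) - 2, p = 1))
    return(list(t = sign(mean(scores_a) - mean(scores_b)) * Inf,
                df = length(scores_a) + length(scores_b) - 2, p = 0))
  }
  tt <- stats::t.test(scores_a, scores_b, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
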