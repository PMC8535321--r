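#' Normalize variant keys
#'
#' Reduces `(chrom, pos, ref, alt)` records to a minimal, joinable
#' representation on 1-based GRCh37 coordinates: shared trailing bases are
#' trimmed first, then shared leading bases are trimmed with the position
#' advanced, leaving at least one base in each allele. Keys are what every
#' table in the package joins on, so the same normalization must be applied
#' to genotype tables, annotation tables and summary statistics.
#'
#' @param chrom chromosome labels.
#' @param pos 1-based physical positions.
#' @param ref,alt allele strings (`ref != alt` after normalization).
#' @return data frame with columns `chrom`, `pos`, `ref`, `alt`, `key`
#'   (the `chrom:pos:ref:alt` string).
#' @export
normalize_variant_keys <- function(chrom, pos, ref, alt) {
  chrom <- as.character(chrom)
  pos <- round(as.numeric(pos))
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (any(pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
  for (i in seq_along(ref)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    # trim shared suffix
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1, nchar(r) - 1)
      a <- substr(a, 1, nchar(a) - 1)
    }
    # trim shared prefix, advancing the position
    while (nchar(r) > 1 && nchar(a) > 1 && substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r))
      a <- substr(a, 2, nchar(a))
      p <- p + 1
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  if (any(ref == alt)) stop("ref == alt after normalization")
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             key = paste(chrom, pos, ref, alt, sep = ":"),
             stringsAsFactors = FALSE)
}

#' Read / write a genotype table
#'
#' The genotype-table dialect is tab-separated with a header row:
#' `CHROM POS REF ALT AF CM` followed by one column per individual id,
#' holding alternate-allele dosages in `{0, 1, 2}` with `NA` for missing.
#' Missing is a distinct state, never coded as dosage 0.
#'
#' @param path file path.
#' @return data frame of class `genotype_table`; individual columns are
#'   listed in `attr(x, "individuals")`.
#' @export
read_genotype_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("CHROM", "POS", "REF", "ALT", "AF", "CM")
  if (!all(need %in% names(tab)))
    stop("genotype table must have columns ", paste(need, collapse = ", "))
  inds <- setdiff(names(tab), need)
  as_genotype_table(tab, inds)
}

as_genotype_table <- function(tab, individuals) {
  nk <- normalize_variant_keys(tab$CHROM, tab$POS, tab$REF, tab$ALT)
  tab$CHROM <- nk$chrom; tab$POS <- nk$pos
  tab$REF <- nk$ref; tab$ALT <- nk$alt
  rownames(tab) <- NULL
  for (i in individuals) {
    d <- tab[[i]]
    if (!all(is.na(d) | d %in% 0:2))
      stop("dosages for ", i, " outside {0,1,2,NA}")
    tab[[i]] <- as.integer(d)
  }
  attr(tab, "individuals") <- individuals
  class(tab) <- c("genotype_table", "data.frame")
  tab
}

#' @rdname read_genotype_table
#' @param x a `genotype_table`.
#' @export
write_genotype_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

genotype_key <- function(x) paste(x$CHROM, x$POS, x$REF, x$ALT, sep = ":")

#' Merge two genotype tables
#'
#' Union of variants across two sources sharing an individual namespace.
#' For keys present in both, the record from the priority source (`a`) is
#' kept and the duplicate dropped; individuals missing from one source get
#' missing calls for that source's variants. A large discrepancy in allele
#' frequency between the two records for the same key (default > 0.2
#' absolute) usually indicates a strand or allele mismatch and raises a
#' warning (the priority record still wins).
#'
#' @param a,b `genotype_table`s; `a` is the priority source.
#' @param af_conflict_tol absolute allele-frequency difference above which a
#'   shared key triggers a warning.
#' @return merged `genotype_table`.
#' @export
merge_genotype_sets <- function(a, b, af_conflict_tol = 0.2) {
  ka <- genotype_key(a); kb <- genotype_key(b)
  shared <- intersect(ka, kb)
  if (length(shared)) {
    dif <- abs(a$AF[match(shared, ka)] - b$AF[match(shared, kb)])
    bad <- shared[!is.na(dif) & dif > af_conflict_tol]
    if (length(bad))
      warning(length(bad), " shared key(s) with allele-frequency conflict ",
              "(> ", af_conflict_tol, "); priority source kept: ",
              paste(utils::head(bad, 5), collapse = ", "))
  }
  ia <- attr(a, "individuals"); ib <- attr(b, "individuals")
  inds <- union(ia, ib)
  pad <- function(x, have) {
    for (i in setdiff(inds, have)) x[[i]] <- NA_integer_
    x[, c("CHROM", "POS", "REF", "ALT", "AF", "CM", inds), drop = FALSE]
  }
  out <- rbind(pad(as.data.frame(a), ia),
               pad(as.data.frame(b)[!(kb %in% shared), , drop = FALSE], ib))
  out <- out[order(out$CHROM, out$POS), , drop = FALSE]
  as_genotype_table(out, inds)
}

#' Assign an allele frequency from ordered sources
#'
#' Returns the first non-missing value in source order (the package default
#' mirrors the reference-database priority GnomAD NFE, then ExAC NFE, then
#' 1000 Genomes EUR); when every source is missing, a configured floor is
#' used so the variant stays usable in likelihood computations.
#'
#' @param ... frequency vectors in priority order (recycled to equal length).
#' @param floor value used when all sources are missing.
#' @return numeric vector of frequencies in `[0, 1]`.
#' @export
assign_allele_frequency <- function(..., floor = 0.001) {
  src <- list(...)
  n <- max(lengths(src))
  out <- rep(NA_real_, n)
  for (s in src) {
    s <- rep_len(as.numeric(s), n)
    out[is.na(out)] <- s[is.na(out)]
  }
  out[is.na(out)] <- floor
  if (any(out < 0 | out > 1))
    stop("allele frequency outside [0, 1]")
  out
}

#' Read a genetic map
#'
#' Three-column tab-separated file (`CHROM`, `POS`, `CM`) of anchor points;
#' within each chromosome anchors must be strictly increasing in both
#' physical position and cumulative cM.
#'
#' @param path file path.
#' @return data frame of class `genetic_map`.
#' @export
read_genetic_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("CHROM", "POS", "CM") %in% names(tab)))
    stop("genetic map must have columns CHROM, POS, CM")
  genetic_map(tab$CHROM, tab$POS, tab$CM)
}

#' @rdname read_genetic_map
#' @param chrom,pos,cm anchor vectors.
#' @export
genetic_map <- function(chrom, pos, cm) {
  tab <- data.frame(CHROM = as.character(chrom), POS = as.numeric(pos),
                    CM = as.numeric(cm), stringsAsFactors = FALSE)
  tab <- tab[order(tab$CHROM, tab$POS), , drop = FALSE]
  for (ch in unique(tab$CHROM)) {
    sub <- tab[tab$CHROM == ch, ]
    if (any(diff(sub$POS) <= 0) || any(diff(sub$CM) <= 0))
      stop("map anchors not strictly increasing on chromosome ", ch)
  }
  class(tab) <- c("genetic_map", "data.frame")
  tab
}

#' Interpolate a genetic-map position
#'
#' Linear interpolation of cumulative cM in physical position between
#' flanking anchors; beyond the terminal anchors the terminal cM value is
#' extrapolated as a constant.
#'
#' @param map a [genetic_map()].
#' @param chrom chromosome label.
#' @param pos physical position(s).
#' @return cM position(s).
#' @export
interpolate_cM <- function(map, chrom, pos) {
  sub <- map[map$CHROM == as.character(chrom), , drop = FALSE]
  if (!nrow(sub)) stop("chromosome ", chrom, " not in map")
  stats::approx(sub$POS, sub$CM, xout = pos, rule = 2, ties = "ordered")$y
}

#' Haldane map function
#'
#' Converts a genetic distance in cM to a recombination fraction:
#' theta = (1 - exp(-2 d / 100)) / 2, in `[0, 0.5)`.
#'
#' @param d genetic distance(s) in cM, non-negative.
#' @return recombination fraction(s).
#' @export
haldane_theta <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("genetic distance must be >= 0")
  (1 - exp(-2 * d / 100)) / 2
}

#' Read external-cohort summary statistics
#'
#' Tab-separated table with columns `CHROM POS REF ALT P COHORT`, mapping
#' normalized variant keys to per-cohort association p-values. Keys absent
#' from the table are distinguishable from present ones, which the
#' association-evidence filter relies on.
#'
#' @param path file path.
#' @return data frame of class `summary_stats` with a normalized `key`.
#' @export
read_summary_stats <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("CHROM", "POS", "REF", "ALT", "P", "COHORT")
  if (!all(need %in% names(tab)))
    stop("summary stats must have columns ", paste(need, collapse = ", "))
  summary_stats(tab)
}

#' @rdname read_summary_stats
#' @param tab data frame with the summary-stats columns.
#' @export
summary_stats <- function(tab) {
  if (any(tab$P <= 0 | tab$P > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  nk <- normalize_variant_keys(tab$CHROM, tab$POS, tab$REF, tab$ALT)
  tab$key <- nk$key
  class(tab) <- c("summary_stats", "data.frame")
  tab
}

#' Convert a VCF to a genotype table
#'
#' Reads a VCF 4.x file with GT fields (via the `vcfR` package), splits
#' multi-allelic records into biallelic rows, normalizes keys, and counts
#' alternate-allele dosages. Allele frequency and cM columns are left `NA`
#' for downstream assignment via [assign_allele_frequency()] and
#' [interpolate_cM()].
#'
#' @param path VCF path (plain or gzipped).
#' @return a `genotype_table`.
#' @export
vcf_to_genotype_table <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("vcf_to_genotype_table requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  inds <- colnames(gt)
  rows <- list()
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    for (ai in seq_along(alts)) {
      g <- gt[r, ]
      alleles <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
      dos <- vapply(alleles, function(x) {
        if (length(x) == 0 || any(x == ".") || any(is.na(x))) return(NA_integer_)
        sum(x == as.character(ai))
      }, integer(1))
      rows[[length(rows) + 1L]] <- data.frame(
        CHROM = fix[r, "CHROM"], POS = as.integer(fix[r, "POS"]),
        REF = fix[r, "REF"], ALT = alts[ai], AF = NA_real_, CM = NA_real_,
        t(dos), check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[-(1:6)] <- inds
  as_genotype_table(out, inds)
}
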