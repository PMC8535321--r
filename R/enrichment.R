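#' Read gene sets in GMT format
#'
#' One term per line: `id <TAB> description <TAB> member genes...`.
#' Genome-wide annotation counts (`genome_hits`) are not part of GMT; they
#' default to the member count and can be overridden per term.
#'
#' @param path GMT file path.
#' @param category category label applied to every term in the file.
#' @param genome_hits optional named integer vector (term id ->
#'   genome-wide annotation count).
#' @return list of `gene_set` objects (`id`, `label`, `category`,
#'   `members`, `genome_hits`).
#' @export
read_gmt <- function(path, category = "pathway", genome_hits = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(ln, 1, 40))
    id <- parts[1]
    members <- toupper(parts[-(1:2)])
    gh <- if (!is.null(genome_hits) && id %in% names(genome_hits))
      genome_hits[[id]] else length(members)
    gene_set(id, parts[2], category, members, gh)
  })
}

#' @rdname read_gmt
#' @param id term identifier.
#' @param label term description.
#' @param members member gene symbols.
#' @export
gene_set <- function(id, label, category, members, genome_hits = length(members)) {
  members <- unique(toupper(members))
  if (genome_hits < length(members))
    stop("genome_hits must be >= the number of term members")
  structure(list(id = id, label = label, category = category,
                 members = members, genome_hits = as.integer(genome_hits)),
            class = "gene_set")
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability that a query of `n` genes overlaps a term with
#' `K` genome-wide annotated genes in `k` or more genes, out of a universe
#' of `N` genes: `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#' Matching is case-insensitive on gene symbols.
#'
#' @param query character vector of query gene symbols.
#' @param term a [gene_set()].
#' @param N universe size (default 20000 protein-coding genes; the choice
#'   of background is the analyst's and shifts p-values materially).
#' @return list of class `enrichment_result`: `term`, `category`, `genes`
#'   (overlap symbols), `k`, `n`, `K`, `N`, `p`.
#' @export
hypergeometric_enrichment <- function(query, term, N = 20000L) {
  query <- unique(toupper(query))
  n <- length(query)
  K <- term$genome_hits
  if (K > N || n > N) stop("K and n must not exceed the universe size N")
  hits <- intersect(query, term$members)
  k <- length(hits)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(term = term$id, label = term$label,
                 category = term$category, genes = hits,
                 k = k, n = n, K = K, N = as.integer(N), p = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s [%s]: k=%d of n=%d (K=%d, N=%d), p = %.3g\n",
              x$term, x$category, x$k, x$n, x$K, x$N, x$p))
  invisible(x)
}

#' Bonferroni adjustment by category annotation count
#'
#' `min(1, p * m)` where `m` is the number of annotations in the term's
#' category (user-supplied; it is a property of the annotation source, not
#' of the query).
#'
#' @param p unadjusted probability(ies).
#' @param m annotation count, `>= 1`.
#' @return adjusted probability(ies).
#' @export
bonferroni_adjust <- function(p, m) {
  if (any(m < 1)) stop("annotation count m must be >= 1")
  pmin(1, p * m)
}

#' Enrichment over a gene-set collection
#'
#' Convenience wrapper: runs [hypergeometric_enrichment()] for every term
#' and applies [bonferroni_adjust()] with per-category annotation counts.
#'
#' @param query query gene symbols.
#' @param terms list of [gene_set()]s.
#' @param N universe size.
#' @param annotation_counts named vector (category -> annotation count `m`);
#'   categories not listed get `m = length(terms in that category)`.
#' @return data frame with one row per term
#'   (`CATEGORY TERM GENES K_SELECTED K_GENOME P P_ADJUSTED`).
#' @export
enrichment_table <- function(query, terms, N = 20000L,
                             annotation_counts = NULL) {
  cats <- vapply(terms, function(t) t$category, character(1))
  m_of <- function(cat) {
    if (!is.null(annotation_counts) && cat %in% names(annotation_counts))
      annotation_counts[[cat]] else sum(cats == cat)
  }
  rows <- lapply(terms, function(t) {
    r <- hypergeometric_enrichment(query, t, N)
    data.frame(CATEGORY = r$category, TERM = r$term,
               GENES = paste(r$genes, collapse = ","),
               K_SELECTED = r$k, K_GENOME = r$K, P = r$p,
               P_ADJUSTED = bonferroni_adjust(r$p, m_of(r$category)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Linkage-colocation sensitivity rerun
#'
#' When two or more of a term's overlapping query genes lie in the same
#' linkage region, their contributions to the overlap are not independent
#' signals. For each region contributing >= 2 overlap genes, all but one
#' (the lowest genomic position, a deterministic choice) are dropped from
#' the query and the enrichment is recomputed. Genes whose position cannot
#' be resolved are retained with a warning.
#'
#' @param query query gene symbols.
#' @param term a [gene_set()].
#' @param regions a `linkage_regions` data frame.
#' @param gene_positions data frame with columns `GENE`, `CHROM`, `POS`.
#' @param N universe size.
#' @return list with `original` and `rerun` [hypergeometric_enrichment()]
#'   results and `dropped` (the excluded symbols).
#' @export
colocated_sensitivity <- function(query, term, regions, gene_positions,
                                  N = 20000L) {
  original <- hypergeometric_enrichment(query, term, N)
  overlap <- original$genes
  gp <- gene_positions
  gp$GENE <- toupper(gp$GENE)
  pos <- gp[match(overlap, gp$GENE), , drop = FALSE]
  unresolved <- overlap[is.na(pos$GENE)]
  if (length(unresolved))
    warning("positions unresolved, genes retained: ",
            paste(unresolved, collapse = ", "))
  dropped <- character()
  if (nrow(regions)) {
    for (r in seq_len(nrow(regions))) {
      inside <- !is.na(pos$GENE) & pos$CHROM == regions$CHROM[r] &
        pos$POS >= regions$START[r] & pos$POS <= regions$END[r]
      if (sum(inside) >= 2) {
        g <- overlap[inside]
        keep <- g[which.min(pos$POS[inside])]
        dropped <- c(dropped, setdiff(g, keep))
      }
    }
  }
  rerun <- hypergeometric_enrichment(setdiff(toupper(query), dropped), term, N)
  list(original = original, rerun = rerun, dropped = unique(dropped))
}
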