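#' Assemble a family cohort for burden testing
#'
#' Combines a list of pedigrees and optional unrelated singletons into one
#' cohort with a block-diagonal kinship structure (one block per family,
#' identity/2 for the unrelated subjects). Individual ids must be unique
#' across the whole cohort.
#'
#' @param peds list of [pedigree()] objects.
#' @param unrelated character vector of unrelated singleton ids.
#' @param unrelated_affected affection for the singletons
#'   (`"yes"`/`"no"`, recycled).
#' @return list of class `family_cohort`: `ids`, `family` (per subject),
#'   `affected` (0/1), `kin2` (the 2*phi matrix).
#' @export
family_cohort <- function(peds, unrelated = character(),
                          unrelated_affected = "no") {
  ids <- c(unlist(lapply(peds, function(p) p$id)), unrelated)
  if (anyDuplicated(ids))
    stop("individual ids must be unique across families")
  fam <- c(unlist(lapply(peds, function(p) rep(attr(p, "family"), nrow(p)))),
           rep("unrelated", length(unrelated)))
  aff <- c(unlist(lapply(peds, function(p) p$affected)),
           rep_len(unrelated_affected, length(unrelated)))
  n <- length(ids)
  kin2 <- matrix(0, n, n, dimnames = list(ids, ids))
  off <- 0L
  for (p in peds) {
    k <- nrow(p)
    kin2[off + seq_len(k), off + seq_len(k)] <- 2 * kinship_matrix(p)
    off <- off + k
  }
  if (length(unrelated))
    diag(kin2)[off + seq_along(unrelated)] <- 1
  structure(list(ids = ids, family = fam,
                 affected = as.integer(aff == "yes"), kin2 = kin2),
            class = "family_cohort")
}

#' One-subject-per-family carrier collapsing
#'
#' Collapses a carrier list to family-level counts: each family contributes
#' at most one counted subject — counted on the affected side if the family
#' contains any affected carrier, otherwise on the control side; healthy
#' relatives of an already-counted family are not double-counted. Unrelated
#' subjects (family label `"unrelated"` or `NA`) each count once.
#'
#' @param carriers data frame with columns `individual`, `family`,
#'   `status` (`"yes"`/`"no"` affected).
#' @return list with `n_ms_families` and `n_control_subjects`.
#' @export
collapse_per_family <- function(carriers) {
  if (is.null(carriers$family) || any(is.na(carriers$family) & is.na(carriers$individual)))
    stop("every carrier needs a family label (use 'unrelated' for singletons)")
  fam <- as.character(carriers$family)
  fam[is.na(fam)] <- "unrelated"
  unrel <- fam == "unrelated"
  n_ms <- 0L; n_ct <- 0L
  for (f in unique(fam[!unrel])) {
    st <- carriers$status[fam == f]
    if (any(st == "yes")) n_ms <- n_ms + 1L else n_ct <- n_ct + 1L
  }
  n_ms <- n_ms + sum(unrel & carriers$status == "yes")
  n_ct <- n_ct + sum(unrel & carriers$status != "yes")
  list(n_ms_families = n_ms, n_control_subjects = n_ct)
}

#' Kinship-adjusted gene-based burden score test
#'
#' Collapses the qualifying variants of a gene into a per-subject burden
#' `b_i = sum_v w_v g_iv` and tests association with affection through a
#' score statistic whose null variance accounts for relatedness:
#' `U = sum_i (y_i - ybar) b_i`,
#' `V = (sum_v w_v^2 2 p_v (1 - p_v)) * c' (2 Phi) c`, `stat = U / sqrt(V)`
#' with a two-sided normal p. Variant frequencies `p_v` are estimated from
#' one member per family (chosen with the given seed) plus the unrelated
#' subjects, so relatedness does not inflate the estimates. A positive stat
#' means the qualifying alleles are enriched in affected subjects. Genes
#' with a single qualifying variant are reported, not tested
#' (see [singleton_report()]).
#'
#' @param cohort a [family_cohort()].
#' @param dosages variants x subjects matrix (columns named by cohort ids)
#'   for one gene.
#' @param gene gene symbol for the result record.
#' @param weights per-variant weights; default 1 (unweighted counts).
#'   `weights = "madsen_browning"` uses `1 / sqrt(p_v (1 - p_v))`.
#' @param freq_seed seed for the one-member-per-family frequency sample.
#' @return list of class `burden_result`: `gene`, `n_variants`, `stat`,
#'   `p`, `tested`.
#' @export
gene_burden_test <- function(cohort, dosages, gene = "gene",
                             weights = NULL, freq_seed = 1L) {
  if (is.null(dim(dosages))) dosages <- matrix(dosages, nrow = 1)
  idx <- match(cohort$ids, colnames(dosages))
  if (anyNA(idx)) stop("dosages missing cohort subjects")
  G <- dosages[, idx, drop = FALSE]
  nv <- nrow(G)
  if (nv < 2)
    stop("gene has fewer than 2 qualifying variants; use singleton_report()")

  # deterministic representative choice without disturbing the caller's
  # random stream (this function may be called inside permutation loops)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(freq_seed)
  rep_cols <- unlist(lapply(unique(cohort$family), function(f) {
    members <- which(cohort$family == f)
    if (f == "unrelated") members else members[sample.int(length(members), 1L)]
  }))
  p_hat <- rowMeans(G[, rep_cols, drop = FALSE], na.rm = TRUE) / 2
  w <- if (is.null(weights)) rep(1, nv)
  else if (identical(weights, "madsen_browning")) {
    pmb <- pmin(pmax(p_hat, 1e-6), 1 - 1e-6)
    1 / sqrt(pmb * (1 - pmb))
  } else rep_len(weights, nv)

  y <- cohort$affected
  cvec <- y - mean(y)
  b <- as.numeric(crossprod(G, w))
  U <- sum(cvec * b)
  V <- sum(w^2 * 2 * p_hat * (1 - p_hat)) *
    as.numeric(t(cvec) %*% cohort$kin2 %*% cvec)
  if (V <= 0)
    return(structure(list(gene = gene, n_variants = nv, stat = 0, p = 1,
                          tested = FALSE), class = "burden_result"))
  stat <- U / sqrt(V)
  structure(list(gene = gene, n_variants = nv, stat = stat,
                 p = 2 * stats::pnorm(abs(stat), lower.tail = FALSE),
                 tested = TRUE), class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("%s: %d variants, stat = %.4f, p = %.4g%s\n", x$gene,
              x$n_variants, x$stat, x$p,
              if (!x$tested) " (untested: no variation)" else ""))
  invisible(x)
}

#' Within-family permutation p-value for the burden statistic
#'
#' Cross-check of the normal approximation: affection labels are permuted
#' within each family (and within the unrelated block), preserving the
#' family affection counts, and the score statistic is recomputed.
#'
#' @inheritParams gene_burden_test
#' @param n_perm number of permutations.
#' @param seed permutation seed.
#' @return two-sided permutation p-value.
#' @export
gene_burden_permutation <- function(cohort, dosages, n_perm = 1000L,
                                    seed = 1L, weights = NULL) {
  obs <- gene_burden_test(cohort, dosages, weights = weights)
  set.seed(seed)
  fam_idx <- split(seq_along(cohort$ids), cohort$family)
  perm_stats <- replicate(n_perm, {
    y <- cohort$affected
    for (ii in fam_idx) y[ii] <- y[sample(ii)]
    shuffled <- cohort
    shuffled$affected <- y
    gene_burden_test(shuffled, dosages, weights = weights)$stat
  })
  mean(abs(perm_stats) >= abs(obs$stat) - 1e-12)
}

#' Descriptive record for single-variant genes
#'
#' Genes with exactly one qualifying variant are not burden-tested; the
#' record mirrors the descriptive table layout (variant key, effect and
#' one-subject-per-family carrier counts).
#'
#' @param cohort a [family_cohort()].
#' @param dosages 1 x subjects matrix (or vector named by subject id).
#' @param gene gene symbol.
#' @param variant_key key string for the record.
#' @param effect free-text effect annotation.
#' @return list with the record fields (no p-value), or `NULL` when no
#'   subject carries the variant.
#' @export
singleton_report <- function(cohort, dosages, gene, variant_key = NA,
                             effect = NA) {
  d <- if (is.null(dim(dosages))) dosages else dosages[1, ]
  d <- d[match(cohort$ids, names(d))]
  carrier <- which(!is.na(d) & d > 0)
  if (!length(carrier)) return(NULL)
  cc <- collapse_per_family(data.frame(
    individual = cohort$ids[carrier],
    family = cohort$family[carrier],
    status = ifelse(cohort$affected[carrier] == 1, "yes", "no"),
    stringsAsFactors = FALSE))
  list(gene = gene, variant_key = variant_key, effect = effect,
       n_ms_families = cc$n_ms_families,
       n_control_subjects = cc$n_control_subjects)
}
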