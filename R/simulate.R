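#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator in one validated
#' object. A fixed `seed` makes all outputs byte-identical across runs: the
#' generator draws from a single pseudo-random stream in a documented order
#' (founder alleles by marker, then meiosis indicators by non-founder and
#' marker, then any conditioning redraws).
#'
#' @param ped a [pedigree()].
#' @param n_markers number of simulated markers.
#' @param freq founder alternate-allele frequency: a single value, a vector
#'   of length `n_markers`, or a function `function(n)` drawing frequencies.
#' @param spacing_cM inter-marker spacing in cM (recombination between
#'   adjacent markers follows [haldane_theta()] of the gap).
#' @param chrom chromosome label for the simulated markers.
#' @param start_pos physical position of the first marker; markers are
#'   placed every `pos_step` bp.
#' @param pos_step physical spacing in bp.
#' @param disease_locus optional marker index (1-based) at which all
#'   affected members are conditioned, by rejection sampling of inheritance
#'   vectors, to share a founder haplotype identical-by-descent.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(ped, n_markers = 5L, freq = 0.5, spacing_cM = 10,
                       chrom = "1", start_pos = 1e6L, pos_step = 1e6L,
                       disease_locus = NULL, seed = 1L) {
  stopifnot(inherits(ped, "pedigree"), n_markers >= 1)
  if (!is.null(disease_locus) &&
      (disease_locus < 1 || disease_locus > n_markers))
    stop("disease_locus outside the simulated map")
  structure(list(ped = ped, n_markers = as.integer(n_markers), freq = freq,
                 spacing_cM = spacing_cM, chrom = as.character(chrom),
                 start_pos = as.numeric(start_pos),
                 pos_step = as.numeric(pos_step),
                 disease_locus = disease_locus, seed = as.integer(seed)),
            class = "sim_config")
}

resolve_freq <- function(freq, M) {
  q <- if (is.function(freq)) freq(M) else rep_len(freq, M)
  if (any(q < 0 | q > 1)) stop("allele frequencies must be in [0, 1]")
  q
}

#' Gene dropping through a pedigree
#'
#' Simulates marker genotypes by Mendelian segregation: founder alleles are
#' drawn i.i.d. from the configured frequency, and each non-founder inherits
#' one allele per parent, with the transmitted grand-parental origin
#' switching between adjacent markers with the Haldane recombination
#' fraction of their cM gap. With a `disease_locus` set, whole inheritance
#' realizations are rejection-sampled until every affected member carries a
#' common founder allele identical-by-descent at that locus.
#'
#' @param config a [sim_config()]; `set.seed(config$seed)` is applied unless
#'   `use_seed = FALSE` (so replicate loops can manage their own stream).
#' @param use_seed whether to seed the random stream from the config.
#' @return a `genotype_table` with one column per pedigree member and an
#'   `ibd_sharing` attribute (logical per marker: do all affected members
#'   share a founder allele IBD there?).
#' @export
gene_drop <- function(config, use_seed = TRUE) {
  if (use_seed) set.seed(config$seed)
  ped <- config$ped
  M <- config$n_markers
  q <- resolve_freq(config$freq, M)
  theta <- haldane_theta(rep(config$spacing_cM, max(M - 1L, 0L)))

  ord <- attr(ped, "topo")
  fo <- is_founder(ped)
  n <- nrow(ped)
  f_idx <- which(fo)
  nf_idx <- ord[!fo[ord]]
  aff <- which(ped$affected == "yes")

  drop_once <- function() {
    X <- matrix(stats::rbinom(2L * length(f_idx) * M, 1L, rep(q, each = 2L * length(f_idx))),
                nrow = 2L * length(f_idx), ncol = M)
    Spat <- matrix(0L, n, M)   # founder-allele slot on the paternal chromosome
    Smat <- matrix(0L, n, M)
    for (k in seq_along(f_idx)) {
      Spat[f_idx[k], ] <- 2L * k - 1L
      Smat[f_idx[k], ] <- 2L * k
    }
    for (i in nf_idx) {
      fa <- match(ped$father[i], ped$id)
      mo <- match(ped$mother[i], ped$id)
      for (src in c("p", "m")) {
        bits <- integer(M)
        bits[1] <- stats::rbinom(1L, 1L, 0.5)
        if (M > 1L) {
          rec <- stats::rbinom(M - 1L, 1L, theta)
          bits <- cumsum(c(bits[1], rec)) %% 2L
        }
        from <- if (src == "p") list(Spat[fa, ], Smat[fa, ]) else list(Spat[mo, ], Smat[mo, ])
        picked <- ifelse(bits == 0L, from[[1]], from[[2]])
        if (src == "p") Spat[i, ] <- picked else Smat[i, ] <- picked
      }
    }
    list(Spat = Spat, Smat = Smat, X = X)
  }

  shares_at <- function(d, m) {
    slots <- rbind(d$Spat[aff, m], d$Smat[aff, m])
    common <- Reduce(intersect, lapply(seq_along(aff), function(t) slots[, t]))
    length(common) > 0
  }

  d <- drop_once()
  if (!is.null(config$disease_locus) && length(aff) >= 2) {
    tries <- 0L
    while (!shares_at(d, config$disease_locus)) {
      d <- drop_once()
      tries <- tries + 1L
      if (tries > 1e5) stop("disease-locus conditioning: rejection limit hit")
    }
  }

  dos <- matrix(0L, n, M)
  for (m in seq_len(M))
    dos[, m] <- d$X[d$Spat[, m], m] + d$X[d$Smat[, m], m]

  ibd <- if (length(aff) >= 2)
    vapply(seq_len(M), function(m) shares_at(d, m), logical(1))
  else rep(NA, M)

  tab <- data.frame(
    CHROM = config$chrom,
    POS = config$start_pos + (seq_len(M) - 1L) * config$pos_step,
    REF = "A", ALT = "G", AF = q,
    CM = (seq_len(M) - 1L) * config$spacing_cM,
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) tab[[ped$id[i]]] <- dos[i, ]
  # degenerate REF/ALT duplicates are fine here: keys get unique positions
  out <- as_genotype_table(tab, ped$id)
  attr(out, "ibd_sharing") <- ibd
  out
}

missense_tools <- c("sift", "polyphen", "mutation_taster",
                    "mutation_assessor", "fathmm")

#' Simulate an annotated variant table with known filter truth
#'
#' Builds fixtures for the prioritization cascade: each variant is
#' constructed to pass the full cascade or to fail exactly one designated
#' stage, with every other stage passing by design. Score columns are drawn
#' from well-separated ranges so random jitter cannot cross a threshold.
#' The accompanying external-cohort summary statistics are generated
#' alongside (rare "absent" keys and significant / non-significant
#' p-values as each design requires).
#'
#' @param ped a [pedigree()] (carrier lists are drawn over its members).
#' @param n_pass number of designed full-cascade survivors.
#' @param n_fail number of designed failures; failing stages are cycled
#'   through segregation, frequency, functional and association.
#' @param regions optional `linkage_regions`; when supplied, a region stage
#'   is added to the design cycle and passing variants are placed inside
#'   the first region.
#' @param context `"wes"` or `"wgs"` (dispatches the non-coding rule).
#' @param maf,alpha cascade thresholds the design is built against.
#' @param seed integer seed.
#' @return list with `variants` (annotated variant data frame), `stats`
#'   (a `summary_stats` table) and `truth` (per-variant `designed_pass`
#'   and `fail_stage`).
#' @export
simulate_annotated_variants <- function(ped, n_pass = 5L, n_fail = 15L,
                                        regions = NULL, context = "wes",
                                        maf = 0.05, alpha = 0.05, seed = 1L) {
  set.seed(seed)
  affected <- ped$id[ped$affected == "yes"]
  if (!length(affected)) stop("pedigree has no affected members")
  n <- n_pass + n_fail
  stages <- c("segregation", "frequency", "functional",
              if (!is.null(regions)) "region", "association")
  fail_stage <- c(rep(NA_character_, n_pass),
                  rep_len(stages, n_fail))

  in_region_pos <- function(k) {
    if (is.null(regions) || !nrow(regions)) return(1e6L + k * 1000L)
    as.integer(regions$START[1] + (k %% max(regions$END[1] - regions$START[1], 1)))
  }
  out_region_pos <- function(k) {
    if (is.null(regions) || !nrow(regions)) return(9e8L + k * 1000L)
    as.integer(max(regions$END) + 1e6L + k * 1000L)
  }

  cats_pass <- c("missense", "synonymous", "stopgain", "splicing", "intronic")
  rows <- vector("list", n)
  stats_rows <- list()
  for (k in seq_len(n)) {
    fs <- fail_stage[k]
    cat_k <- sample(cats_pass, 1)
    if (identical(fs, "functional")) cat_k <- sample(c("missense", "synonymous", "intronic"), 1)
    v <- list(
      CHROM = if (identical(fs, "region")) regions$CHROM[1] else
        if (!is.null(regions)) regions$CHROM[1] else "1",
      POS = if (identical(fs, "region")) out_region_pos(k) else in_region_pos(k),
      REF = "A", ALT = "G",
      GENE = sprintf("GENE%03d", k),
      CATEGORY = cat_k,
      KG_EUR = NA_real_, GNOMAD_NFE = NA_real_, EXAC_NFE = NA_real_,
      CADD_PHRED = NA_real_, GWAVA = NA_real_, GERP = NA_real_,
      SPIDEX = NA_real_, SPLICE_AI = NA_real_,
      SIFT = NA_character_, POLYPHEN = NA_character_,
      MUTATION_TASTER = NA_character_, MUTATION_ASSESSOR = NA_character_,
      FATHMM = NA_character_,
      CARRIERS = paste(affected, collapse = ",")
    )
    # frequency: rare everywhere unless this is the frequency failure
    v$GNOMAD_NFE <- stats::runif(1, 0.001, maf * 0.8)
    if (stats::runif(1) < 0.5) v$KG_EUR <- stats::runif(1, 0.001, maf * 0.8)
    if (identical(fs, "frequency")) v$GNOMAD_NFE <- stats::runif(1, 0.15, 0.4)
    # functional scores by category
    if (cat_k == "missense") {
      if (identical(fs, "functional")) {
        v$CADD_PHRED <- stats::runif(1, 0, 8)
        v$SIFT <- "damaging"                      # only 1 of 5 tools
      } else {
        v$CADD_PHRED <- stats::runif(1, 15, 40)
      }
    } else if (cat_k %in% c("synonymous", "intronic")) {
      if (identical(fs, "functional")) {
        v$CADD_PHRED <- stats::runif(1, 0, 8)
        v$GWAVA <- stats::runif(1, 0, 0.4)
        v$GERP <- stats::runif(1, -2, 2)
        v$SPIDEX <- stats::runif(1, -2, 2)
        v$SPLICE_AI <- stats::runif(1, 0, 0.3)
      } else if (context == "wgs" && cat_k == "intronic") {
        v$SPLICE_AI <- stats::runif(1, 0.5, 1)
      } else {
        v$CADD_PHRED <- stats::runif(1, 15, 40)
        v$SPLICE_AI <- stats::runif(1, 0.5, 1)
      }
    }
    # segregation: failure drops one affected member from the carriers
    if (identical(fs, "segregation"))
      v$CARRIERS <- paste(affected[-1], collapse = ",")
    # association evidence: survivors are nominally significant in one
    # cohort or absent; failures sit in all cohorts at p >= alpha
    if (identical(fs, "association")) {
      for (co in c("immunochip", "exomechip", "mschip"))
        stats_rows[[length(stats_rows) + 1L]] <- data.frame(
          CHROM = v$CHROM, POS = v$POS, REF = v$REF, ALT = v$ALT,
          P = stats::runif(1, 0.2, 0.9), COHORT = co,
          stringsAsFactors = FALSE)
    } else if (stats::runif(1) < 0.5) {
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        CHROM = v$CHROM, POS = v$POS, REF = v$REF, ALT = v$ALT,
        P = stats::runif(1, 1e-6, alpha * 0.8), COHORT = "immunochip",
        stringsAsFactors = FALSE)
    }
    rows[[k]] <- as.data.frame(v, stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, rows)
  stats <- if (length(stats_rows)) summary_stats(do.call(rbind, stats_rows))
  else summary_stats(data.frame(CHROM = character(), POS = integer(),
                                REF = character(), ALT = character(),
                                P = numeric(), COHORT = character()))
  list(variants = variants, stats = stats,
       truth = data.frame(GENE = variants$GENE,
                          designed_pass = is.na(fail_stage),
                          fail_stage = fail_stage,
                          stringsAsFactors = FALSE))
}

#' Simulate a case/control cohort for risk-score analysis
#'
#' Draws genotypes at the panel loci under Hardy-Weinberg proportions and
#' assigns affection through a logistic liability model whose per-locus
#' log odds ratios are the panel weights; sampling continues until the
#' requested case and control quotas are filled.
#'
#' @param panel data frame with columns `LOCUS`, `OR`, `PROTECTIVE`
#'   (logical) and `FREQ` (risk-allele frequency).
#' @param n_cases,n_controls cohort sizes (both > 0).
#' @param base_rate baseline disease probability for a subject carrying the
#'   frequency-expected dosage at every locus.
#' @param seed integer seed.
#' @return list with `dosages` (loci x subjects matrix of risk-allele
#'   counts) and `status` (`"case"` / `"control"`).
#' @export
simulate_wgrs_cohort <- function(panel, n_cases = 500L, n_controls = 500L,
                                 base_rate = 0.15, seed = 1L) {
  if (n_cases < 1 || n_controls < 1)
    stop("n_cases and n_controls must both be positive")
  set.seed(seed)
  L <- nrow(panel)
  w <- vapply(seq_len(L), function(i)
    locus_weight(panel$OR[i], panel$PROTECTIVE[i]), numeric(1))
  q <- panel$FREQ
  alpha <- stats::qlogis(base_rate) - sum(w * 2 * q)
  need <- c(case = n_cases, control = n_controls)
  got <- list(case = NULL, control = NULL)
  while (any(vapply(got, function(x) if (is.null(x)) 0L else ncol(x),
                    integer(1)) < need)) {
    nb <- 2L * sum(need)
    G <- matrix(stats::rbinom(L * nb, 2L, rep(q, nb)), nrow = L)
    pr <- stats::plogis(alpha + as.numeric(crossprod(G, w)))
    is_case <- stats::runif(nb) < pr
    got$case <- cbind(got$case, G[, is_case, drop = FALSE])
    got$control <- cbind(got$control, G[, !is_case, drop = FALSE])
  }
  dos <- cbind(got$case[, seq_len(n_cases), drop = FALSE],
               got$control[, seq_len(n_controls), drop = FALSE])
  rownames(dos) <- panel$LOCUS
  colnames(dos) <- c(sprintf("case_%d", seq_len(n_cases)),
                     sprintf("ctrl_%d", seq_len(n_controls)))
  list(dosages = dos,
       status = rep(c("case", "control"), c(n_cases, n_controls)))
}

#' Simulate a multi-family burden-testing cohort
#'
#' Builds a cohort of nuclear families plus unrelated controls with the
#' structure used for family-based burden testing, and gene-drops unlinked
#' variants through each family so that genotype covariance between
#' relatives follows twice the kinship matrix exactly. Affection labels are
#' structural (a fixed number of affected members per family) and, under
#' the null, independent of the genotypes.
#'
#' @param n_families number of multiplex families (2 founders + 2 children
#'   each; 3 of the 4 members affected).
#' @param n_unrelated number of unrelated unaffected controls.
#' @param n_variants number of unlinked variants to drop.
#' @param freq variant frequency specification as in [sim_config()].
#' @param seed integer seed.
#' @return a `family_cohort` (see [family_cohort()]) with a `dosages`
#'   element (variants x subjects) and `freq_true` attribute.
#' @export
simulate_burden_cohort <- function(n_families = 28L, n_unrelated = 30L,
                                   n_variants = 60L,
                                   freq = function(n) stats::runif(n, 0.02, 0.10),
                                   seed = 1L) {
  set.seed(seed)
  q <- resolve_freq(freq, n_variants)
  peds <- list()
  dosage_blocks <- list()
  for (f in seq_len(n_families)) {
    ids <- sprintf("F%02d_%s", f, c("pa", "ma", "c1", "c2"))
    ped <- pedigree(id = ids,
                    father = c(NA, NA, ids[1], ids[1]),
                    mother = c(NA, NA, ids[2], ids[2]),
                    sex = c("male", "female", "unknown", "unknown"),
                    affected = c("yes", "no", "yes", "yes"),
                    family = sprintf("F%02d", f))
    cfg <- sim_config(ped, n_markers = n_variants, freq = q,
                      spacing_cM = 1e4, pos_step = 1000)  # unlinked markers
    gt <- gene_drop(cfg, use_seed = FALSE)
    dosage_blocks[[f]] <- t(as.matrix(as.data.frame(gt)[, ids, drop = FALSE]))
    rownames(dosage_blocks[[f]]) <- ids
    peds[[f]] <- ped
  }
  unrel <- matrix(stats::rbinom(n_unrelated * n_variants, 2L,
                                rep(q, n_unrelated)),
                  nrow = n_variants)
  unrel_ids <- sprintf("HC%02d", seq_len(n_unrelated))
  dos <- cbind(do.call(cbind, lapply(dosage_blocks, t)), unrel)
  colnames(dos) <- c(unlist(lapply(peds, function(p) p$id)), unrel_ids)
  cohort <- family_cohort(peds, unrelated = unrel_ids,
                          unrelated_affected = rep("no", n_unrelated))
  cohort$dosages <- dos
  attr(cohort, "freq_true") <- q
  cohort
}
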