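#' Enumerate the inheritance-vector space of a pedigree
#'
#' The engine behind all linkage computations. Each non-founder contributes
#' two meiosis bits (0 = grand-paternal, 1 = grand-maternal transmission);
#' the space of inheritance vectors therefore has `2^(2 * n_nonfounders)`
#' states. For every state the founder-allele slot carried on each
#' individual's paternal and maternal chromosome is tabulated, the
#' Whittemore-Halpern NPL-all statistic `S_all` over the affected members is
#' computed, and the exact null mean and standard deviation of `S_all` under
#' the uniform distribution over states give the normalized score
#' `Z = (S_all - mu0) / sigma0`.
#'
#' @param ped a [pedigree()] with at least two affected members.
#' @param cap maximum number of meiosis bits that will be enumerated
#'   (memory grows as `2^bits`); larger pedigrees are rejected.
#' @return object of class `inheritance_space`: a list with elements
#'   `n_vectors`, `bits`, `S`, `Z`, `mu0`, `sigma0`, per-state slot matrices
#'   and the sharing-class tabulation used by [kong_cox_exlod()].
#' @export
inheritance_space <- function(ped, cap = 16L) {
  ord <- attr(ped, "topo")
  fo <- is_founder(ped)
  nf_idx <- ord[!fo[ord]]                      # non-founders, topo order
  B <- 2L * length(nf_idx)
  if (B < 2L) stop("pedigree has no non-founders")
  if (B > cap)
    stop("pedigree has ", B, " meiosis bits; enumeration cap is ", cap)
  if (sum(ped$affected == "yes") < 2)
    stop("NPL scoring needs at least two affected members")

  nv <- 2L^B
  n <- nrow(ped)
  vidx <- 0:(nv - 1L)
  f_idx <- which(fo)
  Apat <- matrix(0L, nv, n)
  Amat <- matrix(0L, nv, n)
  for (k in seq_along(f_idx)) {
    Apat[, f_idx[k]] <- 2L * k - 1L
    Amat[, f_idx[k]] <- 2L * k
  }
  bit_of <- integer(n)                         # first meiosis bit per nonfounder
  for (j in seq_along(nf_idx)) {
    i <- nf_idx[j]
    bit_of[i] <- 2L * j - 1L
    fa <- match(ped$father[i], ped$id)
    mo <- match(ped$mother[i], ped$id)
    bp <- bitwAnd(vidx, bitwShiftL(1L, 2L * j - 2L)) > 0L
    bm <- bitwAnd(vidx, bitwShiftL(1L, 2L * j - 1L)) > 0L
    Apat[, i] <- ifelse(bp, Amat[, fa], Apat[, fa])
    Amat[, i] <- ifelse(bm, Amat[, mo], Apat[, mo])
  }

  aff <- which(ped$affected == "yes")
  S <- s_all_states(Apat, Amat, aff, n_slots = 2L * length(f_idx))
  mu0 <- mean(S)
  sigma0 <- sqrt(mean(S^2) - mu0^2)
  if (sigma0 > 1e-12) {
    Z <- (S - mu0) / sigma0
  } else {
    warning("uninformative family: sigma0 = 0, all Z set to 0")
    sigma0 <- 0
    Z <- rep(0, nv)
  }

  cls <- factor(round(S, 9))
  class_id <- as.integer(cls)
  class_S <- as.numeric(levels(cls))
  class_p0 <- as.numeric(table(cls)) / nv
  class_z <- if (sigma0 > 0) (class_S - mu0) / sigma0 else rep(0, length(class_S))

  structure(list(
    ped = ped, bits = B, n_vectors = nv,
    Apat = Apat, Amat = Amat, n_founders = length(f_idx),
    S = S, Z = Z, mu0 = mu0, sigma0 = sigma0,
    class_id = class_id, class_z = class_z, class_p0 = class_p0
  ), class = "inheritance_space")
}

#' @export
print.inheritance_space <- function(x, ...) {
  cat(sprintf(
    "<inheritance_space> %d bits (%d states), %d founders; mu0 = %.4f, sigma0 = %.4f\n",
    x$bits, x$n_vectors, x$n_founders, x$mu0, x$sigma0))
  invisible(x)
}

# S_all for every enumerated state. For a = n affected, sums over the 2^a
# ways of picking one allele per affected the product over founder alleles
# of factorial(multiplicity), scaled by 2^-a.
s_all_states <- function(Apat, Amat, aff, n_slots) {
  nv <- nrow(Apat)
  a <- length(aff)
  tot <- numeric(nv)
  for (h in 0:(2L^a - 1L)) {
    pick_mat <- bitwAnd(h, bitwShiftL(1L, seq_len(a) - 1L)) > 0L
    M <- matrix(0L, nv, a)
    for (t in seq_len(a))
      M[, t] <- if (pick_mat[t]) Amat[, aff[t]] else Apat[, aff[t]]
    pf <- rep(1, nv)
    for (f in seq_len(n_slots)) {
      b <- rowSums(M == f)
      pf <- pf * factorial(b)
    }
    tot <- tot + pf
  }
  tot / 2^a
}

#' Whittemore-Halpern NPL-all score for one inheritance vector
#'
#' @param ped a [pedigree()] with >= 2 affected members.
#' @param v integer/logical vector of meiosis bits, length
#'   `2 * n_nonfounders`, ordered as two bits (paternal, maternal) per
#'   non-founder in parent-before-child order; 0 = grand-paternal.
#' @return the raw `S_all` value.
#' @seealso [inheritance_space()] for all states at once.
#' @export
s_all <- function(ped, v) {
  space <- inheritance_space(ped)
  space$S[vector_index(v)]
}

vector_index <- function(v) {
  v <- as.integer(v)
  if (!all(v %in% 0:1)) stop("inheritance vector bits must be 0/1")
  sum(v * 2L^(seq_along(v) - 1L)) + 1L
}

#' Exact NPL-all null calibration
#'
#' Enumerates the inheritance space and returns the null mean, null standard
#' deviation and the per-state normalized scores of the NPL-all statistic.
#'
#' @inheritParams inheritance_space
#' @return list with `mu0`, `sigma0`, and `Z` (per-state).
#' @export
npl_normalize <- function(ped, cap = 16L) {
  space <- inheritance_space(ped, cap)
  list(mu0 = space$mu0, sigma0 = space$sigma0, Z = space$Z)
}

founder_patterns <- function(space) {
  ns <- 2L * space$n_founders
  if (ns > 16L) stop("too many founder alleles to enumerate (", ns, ")")
  np <- 2L^ns
  P <- matrix(0L, np, ns)
  idx <- 0:(np - 1L)
  for (s in seq_len(ns)) P[, s] <- as.integer(bitwAnd(idx, bitwShiftL(1L, s - 1L)) > 0L)
  P
}

#' Marker likelihood per inheritance vector
#'
#' `P(observed genotypes | inheritance vector)` for a biallelic marker, with
#' founder alleles i.i.d. alternate with the given frequency. Missing calls
#' and untyped individuals impose no constraint. Summation is over the
#' founder-allele assignments consistent with the vector and the calls.
#'
#' @param space an [inheritance_space()] (or a [pedigree()], which is
#'   enumerated on the fly).
#' @param calls named vector of alternate-allele dosages `{0, 1, 2, NA}`;
#'   names are individual ids.
#' @param freq alternate-allele frequency in `(0, 1)`.
#' @param v optional single inheritance vector (bits); if omitted the
#'   likelihood for every state is returned.
#' @return numeric vector of likelihoods (length `n_vectors`, or 1 if `v`
#'   is given).
#' @export
genotype_vector_likelihood <- function(space, calls, freq, v = NULL) {
  if (inherits(space, "pedigree")) space <- inheritance_space(space)
  if (freq <= 0 || freq >= 1) stop("allele frequency must be in (0, 1)")
  ped <- space$ped
  obs <- rep(NA_integer_, nrow(ped))
  hit <- match(names(calls), ped$id)
  if (anyNA(hit)) stop("calls for unknown individuals: ",
                       paste(names(calls)[is.na(hit)], collapse = ", "))
  obs[hit] <- as.integer(calls)
  obs[!ped$genotyped] <- NA_integer_
  typed <- which(!is.na(obs))
  P <- founder_patterns(space)
  rs <- rowSums(P)
  wp <- freq^rs * (1 - freq)^(ncol(P) - rs)
  e <- emission_probs_cpp(space$Apat, space$Amat, typed, obs[typed], P, wp)
  if (is.null(v)) e else e[vector_index(v)]
}

#' Kong-Cox exponential-model LOD score
#'
#' One-parameter exponential tilting of the null inheritance distribution:
#' `L(delta) = sum_v w(v) exp(delta Z(v)) / E0[exp(delta Z)]`, maximized
#' over `delta >= 0` by golden-section search; the LOD is `log10 L(delta^)`
#' and the one-sided tail probability is
#' `p = 1 - Phi(sqrt(2 ln10 * exLOD))`. With complete data the likelihood
#' increases without bound and the supremum
#' `-log10 P0(maximal sharing class)` is reported; negative sharing evidence
#' yields exLOD 0 and p 0.5 (the model is one-sided).
#'
#' @param z normalized NPL scores, one per state (or per sharing class).
#' @param weights posterior state weights (need not be normalized).
#' @param null_prob null probabilities of the states; defaults to uniform.
#' @param delta_max upper bound of the tilting-parameter search.
#' @param tol golden-section convergence tolerance.
#' @return list of class `kong_cox` with `delta_hat`, `exlod`, `p`
#'   (`delta_hat = Inf` flags a supremum attained in the complete-data
#'   limit).
#' @export
kong_cox_exlod <- function(z, weights, null_prob = NULL,
                           delta_max = 10, tol = 1e-6) {
  if (is.null(null_prob)) null_prob <- rep(1 / length(z), length(z))
  stopifnot(length(z) == length(weights), length(z) == length(null_prob))
  if (any(!is.finite(weights)) || sum(weights) <= 0)
    stop("non-finite or all-zero posterior weights")
  w <- weights / sum(weights)
  p0 <- null_prob / sum(null_prob)
  m <- max(z)
  loglr <- function(d) {
    ez <- exp(d * (z - m))
    log10(sum(w * ez)) - log10(sum(p0 * ez))
  }
  gr <- (sqrt(5) - 1) / 2
  lo <- 0; hi <- delta_max
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- loglr(x1); f2 <- loglr(x2)
  while (hi - lo > tol) {
    if (f1 < f2) {
      lo <- x1; x1 <- x2; f1 <- f2; x2 <- lo + gr * (hi - lo); f2 <- loglr(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1; x1 <- hi - gr * (hi - lo); f1 <- loglr(x1)
    }
  }
  dhat <- (lo + hi) / 2
  val <- loglr(dhat)
  if (delta_max - dhat < 1e-3) {
    # maximizer at the search boundary: report the delta -> Inf supremum,
    # the likelihood ratio restricted to the maximal sharing class
    top <- abs(z - m) < 1e-9
    lim <- log10(sum(w[top])) - log10(sum(p0[top]))
    if (is.finite(lim) && lim > val) { val <- lim; dhat <- Inf }
  }
  exlod <- max(0, val)
  if (exlod < 1e-12) { exlod <- 0; dhat <- 0 }
  p <- stats::pnorm(sqrt(2 * log(10) * exlod), lower.tail = FALSE)
  structure(list(delta_hat = dhat, exlod = exlod, p = p), class = "kong_cox")
}

#' @export
print.kong_cox <- function(x, ...) {
  cat(sprintf("Kong-Cox exponential model: exLOD = %.4f, p = %.5g (delta = %s)\n",
              x$exlod, x$p,
              if (is.infinite(x$delta_hat)) "sup" else sprintf("%.4f", x$delta_hat)))
  invisible(x)
}

#' Maximum attainable exponential LOD for a pedigree
#'
#' The complete-data ceiling of the Kong-Cox exponential LOD: the posterior
#' concentrated on the maximal allele-sharing class (what a fully
#' informative marker yields when every affected shares maximally) gives
#' `exLOD = -log10 P0(maximal class)`. For the reference multiplex pedigree
#' this is `log10 64 = 1.806` with tail probability 0.00196.
#'
#' @inheritParams inheritance_space
#' @param delta_max,tol passed to [kong_cox_exlod()].
#' @return a `kong_cox` result.
#' @export
max_attainable_exlod <- function(ped, cap = 16L, delta_max = 10, tol = 1e-6) {
  space <- if (inherits(ped, "inheritance_space")) ped else inheritance_space(ped, cap)
  top <- which.max(space$class_z)
  w <- as.numeric(seq_along(space$class_z) == top)
  kong_cox_exlod(space$class_z, w, space$class_p0,
                 delta_max = delta_max, tol = tol)
}

# precomputed per-bit state-flip index, for the meiosis-wise HMM transition
flip_index <- function(space) {
  vidx <- 0:(space$n_vectors - 1L)
  vapply(seq_len(space$bits),
         function(b) bitwXor(vidx, bitwShiftL(1L, b - 1L)) + 1L,
         integer(space$n_vectors))
}

# one HMM transition: each meiosis bit flips independently with prob theta
mix_bits <- function(f, theta, flip) {
  for (b in seq_len(ncol(flip)))
    f <- (1 - theta) * f + theta * f[flip[, b]]
  f
}

#' Multipoint non-parametric linkage scan
#'
#' Lander-Green hidden Markov chain over inheritance vectors: marker
#' emissions from [genotype_vector_likelihood()], transitions with per-bit
#' recombination fraction from [haldane_theta()] of the inter-marker cM gap,
#' forward-backward posterior state weights per marker, and
#' [kong_cox_exlod()] applied at each marker.
#'
#' @param ped a [pedigree()].
#' @param gtab a `genotype_table` with `AF` and `CM` populated; markers must
#'   be position-ordered within each chromosome.
#' @param map optional [genetic_map()] used to fill missing `CM` values.
#' @param cap enumeration cap (bits), see [inheritance_space()].
#' @param delta_max Kong-Cox search bound.
#' @param include_sex_chroms keep X/Y markers (excluded by default: the
#'   autosomal inheritance model does not handle X transmission).
#' @return data frame of class `linkage_track` with one row per marker:
#'   `CHROM, POS, CM, ZBAR, EXLOD, P, DELTA` (`ZBAR` is the posterior mean
#'   of the normalized NPL score).
#' @export
multipoint_npl <- function(ped, gtab, map = NULL, cap = 16L, delta_max = 10,
                           include_sex_chroms = FALSE) {
  space <- inheritance_space(ped, cap)
  tab <- as.data.frame(gtab)
  inds <- attr(gtab, "individuals")
  if (!include_sex_chroms) {
    sexch <- tab$CHROM %in% c("X", "Y", "chrX", "chrY", "23", "24")
    tab <- tab[!sexch, , drop = FALSE]
  }
  if (!nrow(tab)) stop("no markers to analyse")
  if (!is.null(map)) {
    miss <- is.na(tab$CM)
    for (ch in unique(tab$CHROM[miss])) {
      sel <- miss & tab$CHROM == ch
      tab$CM[sel] <- interpolate_cM(map, ch, tab$POS[sel])
    }
  }
  if (anyNA(tab$CM)) stop("markers with missing cM positions")
  if (anyNA(tab$AF) || any(tab$AF <= 0 | tab$AF >= 1))
    stop("marker allele frequencies must be in (0, 1)")

  P <- founder_patterns(space)
  rs <- rowSums(P)
  flip <- flip_index(space)
  ped_obs <- matrix(NA_integer_, nrow(space$ped), nrow(tab))
  hit <- match(inds, space$ped$id)
  keep <- !is.na(hit)
  ped_obs[hit[keep], ] <- t(as.matrix(tab[, inds[keep], drop = FALSE]))
  ped_obs[!space$ped$genotyped, ] <- NA_integer_

  out <- list()
  for (ch in unique(tab$CHROM)) {
    sel <- which(tab$CHROM == ch)
    if (is.unsorted(tab$POS[sel]))
      stop("markers not position-ordered on chromosome ", ch)
    if (is.unsorted(tab$CM[sel]))
      stop("marker cM not non-decreasing on chromosome ", ch)
    M <- length(sel)
    nv <- space$n_vectors
    E <- matrix(0, nv, M)
    for (m in seq_len(M)) {
      j <- sel[m]
      typed <- which(!is.na(ped_obs[, j]))
      q <- tab$AF[j]
      wp <- q^rs * (1 - q)^(ncol(P) - rs)
      E[, m] <- emission_probs_cpp(space$Apat, space$Amat, typed,
                                   ped_obs[typed, j], P, wp)
      if (sum(E[, m]) <= 0)
        stop("marker ", ch, ":", tab$POS[j],
             " is Mendelian-inconsistent with the pedigree")
    }
    theta <- haldane_theta(diff(tab$CM[sel]))
    # forward (includes emission), backward (excludes own emission)
    Fm <- matrix(0, nv, M)
    f <- E[, 1] / nv
    Fm[, 1] <- f / sum(f)
    if (M > 1) for (m in 2:M) {
      f <- mix_bits(Fm[, m - 1], theta[m - 1], flip) * E[, m]
      s <- sum(f)
      if (s <= 0) stop("zero forward probability at marker ", m, " on ", ch)
      Fm[, m] <- f / s
    }
    Bm <- matrix(1 / nv, nv, M)
    if (M > 1) for (m in (M - 1):1) {
      b <- mix_bits(Bm[, m + 1] * E[, m + 1], theta[m], flip)
      Bm[, m] <- b / sum(b)
    }
    for (m in seq_len(M)) {
      w <- Fm[, m] * Bm[, m]
      w <- w / sum(w)
      wc <- as.numeric(rowsum(w, space$class_id))
      kc <- kong_cox_exlod(space$class_z, wc, space$class_p0,
                           delta_max = delta_max)
      out[[length(out) + 1L]] <- data.frame(
        CHROM = ch, POS = tab$POS[sel[m]], CM = tab$CM[sel[m]],
        ZBAR = sum(w * space$Z), EXLOD = kc$exlod, P = kc$p,
        DELTA = kc$delta_hat, stringsAsFactors = FALSE)
    }
  }
  track <- do.call(rbind, out)
  class(track) <- c("linkage_track", "data.frame")
  track
}

#' Call linkage regions from an exLOD track
#'
#' Peaks are the markers whose exLOD lies within `epsilon` of the track's
#' global maximum. Each peak is extended left and right to the nearest
#' marker where the exLOD drops to zero (exLOD <= 0); that boundary marker's
#' position is the region endpoint, and chromosome ends terminate regions.
#' Regions that overlap or share a shore boundary are merged.
#'
#' @param track a `linkage_track` (needs `CHROM`, `POS`, `EXLOD`).
#' @param epsilon peak tolerance on exLOD.
#' @return data frame of class `linkage_regions` with columns
#'   `CHROM, START, END, MAX_EXLOD, N_PEAKS` (1-based inclusive
#'   coordinates); total spanned length in `attr(x, "total_length")`.
#' @export
call_linkage_regions <- function(track, epsilon = 1e-6) {
  empty <- data.frame(CHROM = character(), START = numeric(),
                      END = numeric(), MAX_EXLOD = numeric(),
                      N_PEAKS = integer(), stringsAsFactors = FALSE)
  if (!nrow(track)) stop("empty linkage track")
  gmax <- max(track$EXLOD)
  if (gmax <= 0) {
    attr(empty, "total_length") <- 0
    class(empty) <- c("linkage_regions", "data.frame")
    return(empty)
  }
  out <- list()
  for (ch in unique(track$CHROM)) {
    sub <- track[track$CHROM == ch, , drop = FALSE]
    sub <- sub[order(sub$POS), , drop = FALSE]
    peaks <- which(sub$EXLOD >= gmax - epsilon)
    if (!length(peaks)) next
    ivs <- lapply(peaks, function(pk) {
      zero <- which(sub$EXLOD <= 0)
      left <- zero[zero < pk]
      right <- zero[zero > pk]
      c(start = sub$POS[if (length(left)) max(left) else 1L],
        end = sub$POS[if (length(right)) min(right) else nrow(sub)])
    })
    ivs <- do.call(rbind, ivs)
    o <- order(ivs[, "start"])
    ivs <- ivs[o, , drop = FALSE]
    pk_pos <- sub$POS[peaks][o]
    merged <- list()
    cur <- ivs[1, ]
    cur_pk <- pk_pos[1]
    for (r in seq_len(nrow(ivs))[-1]) {
      if (ivs[r, "start"] <= cur["end"]) {
        cur["end"] <- max(cur["end"], ivs[r, "end"])
        cur_pk <- c(cur_pk, pk_pos[r])
      } else {
        merged[[length(merged) + 1L]] <- list(iv = cur, pk = cur_pk)
        cur <- ivs[r, ]; cur_pk <- pk_pos[r]
      }
    }
    merged[[length(merged) + 1L]] <- list(iv = cur, pk = cur_pk)
    for (mg in merged) {
      inside <- sub$POS >= mg$iv["start"] & sub$POS <= mg$iv["end"]
      out[[length(out) + 1L]] <- data.frame(
        CHROM = ch, START = unname(mg$iv["start"]), END = unname(mg$iv["end"]),
        MAX_EXLOD = max(sub$EXLOD[inside]),
        N_PEAKS = length(unique(mg$pk)), stringsAsFactors = FALSE)
    }
  }
  regions <- if (length(out)) do.call(rbind, out) else empty
  attr(regions, "total_length") <- sum(regions$END - regions$START + 1)
  class(regions) <- c("linkage_regions", "data.frame")
  regions
}

#' @rdname call_linkage_regions
#' @param regions a `linkage_regions` object.
#' @param path output path for a BED-like TSV
#'   (`CHROM START END MAX_EXLOD N_PEAKS`, 1-based inclusive).
#' @export
write_linkage_regions <- function(regions, path) {
  utils::write.table(as.data.frame(regions), path, quote = FALSE,
                     sep = "\t", row.names = FALSE)
  invisible(path)
}
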