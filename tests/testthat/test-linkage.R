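test_that("NPL-all scores for an affected sib pair match enumeration by hand", {
  sib <- sibpair_pedigree()
  # bits: (s1 pat, s1 mat, s2 pat, s2 mat); equal bits = shared grandparental origin
  expect_equal(s_all(sib, c(0, 0, 0, 0)), 1.5)   # IBD-2: (2!+1+1+2!)/4
  expect_equal(s_all(sib, c(0, 0, 1, 1)), 1.0)   # IBD-0: all products 1
  expect_equal(s_all(sib, c(0, 0, 1, 0)), 1.25)  # IBD-1

  nn <- npl_normalize(sib)
  expect_equal(nn$mu0, 1.25)
  expect_equal(nn$sigma0, sqrt(0.03125))
  expect_equal(nn$Z[1], sqrt(2))  # IBD-2 state

  # guard: a single affected member cannot be scored
  single <- pedigree(id = c("f", "m", "k"), father = c(NA, NA, "f"),
                     mother = c(NA, NA, "m"),
                     sex = c("male", "female", "unknown"),
                     affected = c("no", "no", "yes"))
  expect_error(inheritance_space(single), "at least two affected")
})

test_that("Z normalization is exact for every enumerated pedigree", {
  for (ped in list(sibpair_pedigree(), cousins_pedigree(),
                   multiplex_pedigree())) {
    sp <- inheritance_space(ped)
    expect_lt(abs(mean(sp$Z)), 1e-9)           # sum P0 Z = 0
    expect_lt(abs(mean(sp$Z^2) - 1), 1e-9)     # sum P0 Z^2 = 1
    expect_equal(sum(sp$class_p0), 1)
  }
})

test_that("marker likelihoods respect information content and Mendelian rules", {
  sib <- sibpair_pedigree()
  sp <- inheritance_space(sib)

  # all calls missing: every vector equally likely
  e0 <- genotype_vector_likelihood(sp, marker_calls(sib), 0.5)
  expect_true(all(abs(e0 - e0[1]) < 1e-12))

  # informative paternal configuration: sibs carrying different paternal
  # alleles exclude exactly the paternal-sharing vectors
  e1 <- genotype_vector_likelihood(
    sp, marker_calls(sib, f = 1L, m = 0L, s1 = 1L, s2 = 0L), 0.5)
  pat_shared <- vapply(0:15, function(v) {
    bits <- as.integer(intToBits(v))[1:4]
    bits[1] == bits[3]  # same grandparental origin of the paternal allele
  }, logical(1))
  expect_true(all(e1[pat_shared] == 0))
  expect_true(all(e1[!pat_shared] > 0))

  # Mendelian impossibility: zero for every vector
  trio_sib <- sibpair_pedigree()
  e2 <- genotype_vector_likelihood(
    trio_sib, marker_calls(trio_sib, f = 0L, m = 0L, s1 = 2L), 0.5)
  expect_true(all(e2 == 0))

  expect_error(genotype_vector_likelihood(sp, marker_calls(sib), 1.5),
               "\\(0, 1\\)")
})

test_that("Kong-Cox scoring: null, perfect sib-pair sharing, and the tail transform", {
  sib <- sibpair_pedigree()
  sp <- inheritance_space(sib)

  # uniform posterior: no linkage evidence
  kc0 <- kong_cox_exlod(sp$class_z, sp$class_p0, sp$class_p0)
  expect_equal(kc0$exlod, 0)
  expect_equal(kc0$p, 0.5)
  expect_equal(kc0$delta_hat, 0)

  # perfect IBD-2 evidence: exLOD -> log10(4), the -log10 P0(max class) limit
  kc2 <- max_attainable_exlod(sib)
  expect_equal(kc2$exlod, log10(4), tolerance = 1e-9)
  expect_equal(kc2$p,
               pnorm(sqrt(2 * log(10) * log10(4)), lower.tail = FALSE))

  # supremum identity across enumerated pedigrees
  for (ped in list(sibpair_pedigree(), cousins_pedigree(),
                   multiplex_pedigree())) {
    spx <- inheritance_space(ped)
    top <- which.max(spx$class_z)
    expect_equal(max_attainable_exlod(spx)$exlod, -log10(spx$class_p0[top]),
                 tolerance = 1e-9)
  }

  expect_error(kong_cox_exlod(c(0, 1), c(0, 0), c(0.5, 0.5)), "weights")
})

test_that("multipoint chaining: length-1 chains, no-information flanks, and HMM collapse", {
  ped <- multiplex_pedigree()
  sp <- inheritance_space(ped)
  set.seed(31)
  g1 <- gene_drop(sim_config(ped, n_markers = 1, freq = 0.5, seed = 31))
  calls <- unlist(as.data.frame(g1)[1, ped$id])
  names(calls) <- ped$id

  tr1 <- multipoint_npl(ped, g1)
  e <- genotype_vector_likelihood(sp, calls, 0.5)
  w <- as.numeric(rowsum(e / sum(e), sp$class_id))
  kc <- kong_cox_exlod(sp$class_z, w, sp$class_p0)
  expect_equal(tr1$EXLOD, kc$exlod, tolerance = 1e-9)
  expect_equal(tr1$P, kc$p, tolerance = 1e-9)

  # flanking fully-missing markers leave the focal marker unchanged
  tab <- as.data.frame(g1)
  flank <- tab[c(1, 1, 1), ]
  flank$POS <- c(1e6, 2e6, 3e6); flank$CM <- c(0, 10, 20)
  flank[c(1, 3), ped$id] <- NA
  g3 <- pedscan:::as_genotype_table(flank, ped$id)
  tr3 <- multipoint_npl(ped, g3)
  expect_equal(tr3$EXLOD[2], tr1$EXLOD[1], tolerance = 1e-9)

  # two identical fully informative markers at zero distance = either alone
  # (fully informative: the emission is constant on its support, so the
  # duplicate adds no information; a partially informative marker would)
  sib <- sibpair_pedigree()
  sib_tab <- data.frame(CHROM = "1", POS = c(1e6, 1000001), REF = "A",
                        ALT = "G", AF = 0.5, CM = c(0, 0),
                        f = 1L, m = 0L, s1 = 1L, s2 = 1L,
                        stringsAsFactors = FALSE)
  gd <- pedscan:::as_genotype_table(sib_tab, sib$id)
  trd <- multipoint_npl(sib, gd)
  tr_single <- multipoint_npl(sib, pedscan:::as_genotype_table(sib_tab[1, ], sib$id))
  expect_gt(tr_single$EXLOD[1], 0)   # paternal sharing forced
  expect_equal(trd$EXLOD, rep(tr_single$EXLOD[1], 2), tolerance = 1e-9)

  # p-exLOD consistency holds for every emitted record
  g5 <- gene_drop(sim_config(ped, n_markers = 5, freq = 0.5, spacing_cM = 10,
                             seed = 77))
  tr5 <- multipoint_npl(ped, g5)
  expect_equal(tr5$P,
               pnorm(sqrt(2 * log(10) * tr5$EXLOD), lower.tail = FALSE),
               tolerance = 1e-12)

  # unordered markers are rejected
  bad <- tab[c(1, 1), ]
  bad$POS <- c(2e6, 1e6); bad$CM <- c(0, 10)
  gb <- pedscan:::as_genotype_table(bad[order(bad$CM), ], ped$id)
  gb$POS <- c(2e6, 1e6)
  expect_error(multipoint_npl(ped, gb), "position-ordered")
})

test_that("region calling follows the peak-and-shore rule with merging", {
  mk_track <- function(exlod, pos = seq_along(exlod) * 1e6, chrom = "1") {
    structure(data.frame(CHROM = chrom, POS = pos, EXLOD = exlod,
                         stringsAsFactors = FALSE),
              class = c("linkage_track", "data.frame"))
  }
  # all zero: no regions
  r0 <- call_linkage_regions(mk_track(rep(0, 6)))
  expect_equal(nrow(r0), 0)
  expect_equal(attr(r0, "total_length"), 0)

  # single peak with shores at the flanking zero markers
  tr <- mk_track(c(0, 0.3, 1.8, 1.2, 0, 0.4))
  r1 <- call_linkage_regions(tr)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$START, 1e6)
  expect_equal(r1$END, 5e6)
  expect_equal(r1$MAX_EXLOD, 1.8)
  expect_equal(r1$N_PEAKS, 1L)

  # two peaks sharing a zero boundary merge into one region
  tr2 <- mk_track(c(0, 1.8, 0, 1.8, 0))
  r2 <- call_linkage_regions(tr2)
  expect_equal(nrow(r2), 1)
  expect_equal(r2$START, 1e6)
  expect_equal(r2$END, 5e6)
  expect_equal(r2$N_PEAKS, 2L)

  # chromosome ends terminate regions; separate chromosomes never merge
  tr3 <- rbind(mk_track(c(1.8, 0.5, 0)),
               mk_track(c(0.2, 1.8, 0.3), chrom = "2"))
  class(tr3) <- c("linkage_track", "data.frame")
  r3 <- call_linkage_regions(tr3)
  expect_equal(nrow(r3), 2)
  expect_equal(r3$START, c(1e6, 1e6))
  expect_equal(r3$END, c(3e6, 3e6))
  expect_equal(attr(r3, "total_length"), sum(r3$END - r3$START + 1))
})
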