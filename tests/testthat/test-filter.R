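test_that("segregation requires every affected member among the carriers", {
  v <- rbind(annot_variant(carriers = "a1,a2"),
             annot_variant(pos = 2000L, carriers = "a1"),
             annot_variant(pos = 3000L, carriers = "a1,a2,h1"))
  flags <- shared_by_affected(v, c("a1", "a2"))
  expect_equal(flags, c(TRUE, FALSE, TRUE))  # healthy carriage never excludes
  expect_error(shared_by_affected(v, character()), "non-empty")
})

test_that("frequency filter applies the strict-rarity rule across databases", {
  v <- rbind(annot_variant(gnomad_nfe = 0.0487),          # just under 5%
             annot_variant(pos = 2000L, kg_eur = 0.06, gnomad_nfe = NA),
             annot_variant(pos = 3000L, gnomad_nfe = NA), # absent everywhere
             annot_variant(pos = 4000L, kg_eur = 0.01, gnomad_nfe = 0.06))
  expect_equal(frequency_pass(v, 0.05), c(TRUE, FALSE, TRUE, FALSE))
  # "any" mode: one rare populated source suffices
  expect_equal(frequency_pass(v, 0.05, mode = "any"), c(TRUE, FALSE, TRUE, TRUE))
  # monotone: lowering the threshold never adds survivors
  for (thr in c(0.04, 0.02, 0.005))
    expect_true(all(frequency_pass(v, thr) <= frequency_pass(v, 0.05)))
})

test_that("functional filter dispatches on category and context", {
  # high-impact categories always pass, even scoreless
  hi <- annot_variant(category = "stopgain", cadd = NA)
  expect_true(functional_pass(hi))

  # missense: CADD > 10 or >= 2 damaging tool calls
  m1 <- annot_variant(cadd = 24.5)
  m2 <- annot_variant(cadd = 9, sift = "damaging")
  m3 <- annot_variant(cadd = 9, sift = "damaging", fathmm = "damaging")
  m4 <- annot_variant(cadd = NA)
  expect_equal(functional_pass(rbind(m1, m2, m3, m4)),
               c(TRUE, FALSE, TRUE, FALSE))

  # tool-native damaging labels are recognized
  m5 <- annot_variant(cadd = 9, polyphen = "probably_damaging",
                      mutation_taster = "disease_causing")
  expect_true(functional_pass(m5))

  # synonymous / non-coding: any of the five scores in the WES context
  s1 <- annot_variant(category = "synonymous", cadd = NA, gwava = 0.6)
  s2 <- annot_variant(category = "synonymous", cadd = NA)
  i1 <- annot_variant(category = "intronic", cadd = NA, spidex = -4.5)
  expect_equal(functional_pass(rbind(s1, s2, i1), context = "wes"),
               c(TRUE, FALSE, TRUE))
  # WGS context: non-coding needs SpliceAI; synonymous keeps the full battery
  expect_equal(functional_pass(rbind(s1, i1), context = "wgs"),
               c(TRUE, FALSE))
  i2 <- annot_variant(category = "intronic", cadd = NA, splice_ai = 0.55)
  expect_true(functional_pass(i2, context = "wgs"))

  bad <- annot_variant(category = "weird")
  expect_error(functional_pass(bad), "unknown variant categories")
})

test_that("association-evidence filter keeps significant-or-absent keys", {
  v <- rbind(annot_variant(pos = 100L), annot_variant(pos = 200L),
             annot_variant(pos = 300L))
  st <- summary_stats(data.frame(
    CHROM = "1", POS = c(100L, 100L, 200L, 200L, 200L),
    REF = "A", ALT = "G",
    P = c(0.01, 0.5, 0.3, 0.6, 0.9),
    COHORT = c("a", "b", "a", "b", "c")))
  expect_equal(association_evidence_pass(v, st, 0.05),
               c(TRUE, FALSE, TRUE))  # significant / never / absent
})

test_that("linkage-region intersection uses 1-based inclusive endpoints", {
  regions <- data.frame(CHROM = "1", START = 1000, END = 2000,
                        MAX_EXLOD = 1.8, N_PEAKS = 1L)
  v <- rbind(annot_variant(pos = 1000L), annot_variant(pos = 2000L),
             annot_variant(pos = 2001L), annot_variant(pos = 999L))
  expect_equal(in_linkage_regions(v, regions), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(nrow(intersect_linkage_regions(v, regions[0, ])), 0)
})

test_that("the cascade equals the conjunction of its predicates on designed fixtures", {
  ped <- multiplex_pedigree()
  affected <- ped$id[ped$affected == "yes"]
  sim <- simulate_annotated_variants(ped, n_pass = 5, n_fail = 15, seed = 42)
  rep <- run_cascade(sim$variants, affected, sim$stats, context = "wes")
  expect_setequal(rep$survivors$GENE, sim$truth$GENE[sim$truth$designed_pass])
  expect_equal(unname(rep$fail_stage), sim$truth$fail_stage)

  # brute-force one-pass conjunction oracle
  brute <- shared_by_affected(sim$variants, affected) &
    frequency_pass(sim$variants, 0.05) &
    functional_pass(sim$variants, "wes") &
    association_evidence_pass(sim$variants, sim$stats, 0.05)
  expect_equal(rowSums(!rep$stages) == 0, brute)

  # degenerate threshold: only frequency-absent variants can survive
  rep0 <- run_cascade(sim$variants, affected, sim$stats, maf = 1e-12)
  absent <- is.na(sim$variants$KG_EUR) & is.na(sim$variants$GNOMAD_NFE) &
    is.na(sim$variants$EXAC_NFE)
  expect_true(all(absent[rowSums(!rep0$stages) == 0]))

  # healthy-carriage prioritization flag annotates, never filters
  repf <- run_cascade(sim$variants, affected, sim$stats,
                      flag_unaffected = "III.3")
  expect_equal(nrow(repf$survivors), nrow(rep$survivors))
  expect_length(repf$not_in_unaffected, nrow(sim$variants))

  # per-stage report writes one row per variant x stage
  path <- withr::local_tempfile(fileext = ".tsv")
  write_filter_report(rep, sim$variants, path)
  long <- read.delim(path)
  expect_equal(nrow(long), nrow(sim$variants) * ncol(rep$stages))
})

test_that("cascade truth recovery holds across 100 seeds with a region stage", {
  ped <- multiplex_pedigree()
  affected <- ped$id[ped$affected == "yes"]
  regions <- data.frame(CHROM = "1", START = 5e5, END = 5e6,
                        MAX_EXLOD = 1.8, N_PEAKS = 1L)
  ok <- vapply(1:100, function(s) {
    sim <- simulate_annotated_variants(ped, n_pass = 5, n_fail = 15,
                                       regions = regions, seed = s)
    rep <- run_cascade(sim$variants, affected, sim$stats,
                       context = "wes", regions = regions)
    setequal(rep$survivors$GENE, sim$truth$GENE[sim$truth$designed_pass]) &&
      identical(unname(rep$fail_stage), sim$truth$fail_stage)
  }, logical(1))
  expect_true(all(ok))
})
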