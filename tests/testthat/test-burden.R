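test_that("one-subject-per-family collapsing reproduces the carrier arithmetic", {
  # 12 affected carriers in 6 families + 5 healthy relatives of those
  # families + 5 unrelated healthy subjects -> 6 affected families, 5 controls
  fams <- rep(sprintf("fam%d", 1:6), each = 2)
  carriers <- data.frame(
    individual = sprintf("p%02d", 1:22),
    family = c(fams, rep(sprintf("fam%d", 1:5), 1), rep("unrelated", 5)),
    status = c(rep("yes", 12), rep("no", 10)),
    stringsAsFactors = FALSE)
  cc <- collapse_per_family(carriers)
  expect_equal(cc$n_ms_families, 6)
  expect_equal(cc$n_control_subjects, 5)

  expect_equal(collapse_per_family(data.frame(
    individual = "x", family = "unrelated", status = "no")),
    list(n_ms_families = 0L, n_control_subjects = 1L))
  expect_equal(collapse_per_family(data.frame(
    individual = c("a", "b"), family = "famA", status = "yes"))$n_ms_families, 1L)
  # a family whose only carriers are healthy counts once as control
  expect_equal(collapse_per_family(data.frame(
    individual = c("a", "b"), family = "famA", status = "no"))$n_control_subjects, 1L)
})

test_that("the kinship-adjusted score matches the closed form for unrelated subjects", {
  set.seed(8)
  n <- 40
  ids <- sprintf("u%02d", 1:n)
  cohort <- family_cohort(list(), unrelated = ids,
                          unrelated_affected = rep(c("yes", "no"), n / 2))
  G <- matrix(rbinom(3 * n, 2, 0.15), nrow = 3,
              dimnames = list(NULL, ids))
  res <- gene_burden_test(cohort, G, gene = "TESTG")

  # independent closed form: unrelated subjects, 2*Phi = I
  y <- cohort$affected
  cvec <- y - mean(y)
  p_hat <- rowMeans(G) / 2
  U <- sum(cvec * colSums(G))
  V <- sum(2 * p_hat * (1 - p_hat)) * sum(cvec^2)
  expect_equal(res$stat, U / sqrt(V), tolerance = 1e-9)
  expect_equal(res$p, 2 * pnorm(abs(U / sqrt(V)), lower.tail = FALSE),
               tolerance = 1e-9)

  # sign convention: carriers concentrated in affected subjects => stat > 0
  G2 <- matrix(0L, 2, n, dimnames = list(NULL, ids))
  G2[, y == 1] <- 1L
  expect_gt(gene_burden_test(cohort, G2)$stat, 0)

  # constant dosage: stat centers to 0, p = 1 (still formally tested since
  # the binomial variance term is positive at p_hat = 1/2)
  G3 <- matrix(1L, 2, n, dimnames = list(NULL, ids))
  res3 <- gene_burden_test(cohort, G3)
  expect_equal(res3$stat, 0)
  expect_equal(res3$p, 1)

  # monomorphic-reference gene: V = 0, flagged untested
  G4 <- matrix(0L, 2, n, dimnames = list(NULL, ids))
  res4 <- gene_burden_test(cohort, G4)
  expect_false(res4$tested)
  expect_equal(res4$p, 1)

  expect_error(gene_burden_test(cohort, G[1, , drop = FALSE]),
               "singleton_report")
})

test_that("identical burden in every subject centers to zero", {
  cohort <- simulate_burden_cohort(n_families = 4, n_unrelated = 4,
                                   n_variants = 2, seed = 3)
  G <- matrix(1L, 2, length(cohort$ids), dimnames = list(NULL, cohort$ids))
  # constant dosage: U = 0 by centering (variance also collapses)
  res <- gene_burden_test(cohort, G)
  expect_equal(res$stat, 0)
})

test_that("the normal approximation agrees with within-family permutation", {
  # the permutation null is conditional on the family affection counts, so
  # only loose agreement with the unconditional normal approximation is
  # expected; check closeness and significance concordance over seeds
  for (s in c(3, 17, 23)) {
    cohort <- simulate_burden_cohort(n_families = 20, n_unrelated = 20,
                                     n_variants = 3,
                                     freq = function(n) runif(n, 0.1, 0.3),
                                     seed = s)
    res <- gene_burden_test(cohort, cohort$dosages)
    p_perm <- gene_burden_permutation(cohort, cohort$dosages,
                                      n_perm = 400, seed = 5)
    expect_lt(abs(res$p - p_perm), 0.2)
    expect_equal(res$p < 0.01, p_perm < 0.01)
  }
})

test_that("power rises with the case-control carrier gap", {
  set.seed(41)
  n <- 60
  ids <- sprintf("u%02d", 1:n)
  cohort <- family_cohort(list(), unrelated = ids,
                          unrelated_affected = rep(c("yes", "no"), n / 2))
  y <- cohort$affected
  mean_abs <- vapply(c(0, 0.15, 0.35), function(gap) {
    stats <- replicate(60, {
      pr <- ifelse(y == 1, 0.15 + gap, 0.15)
      G <- rbind(rbinom(n, 2, pr), rbinom(n, 2, pr))
      colnames(G) <- ids
      gene_burden_test(cohort, G)$stat
    })
    mean(abs(stats))
  }, numeric(1))
  expect_true(all(diff(mean_abs) > -0.15))  # non-decreasing up to MC noise
  expect_gt(mean_abs[3], mean_abs[1])
})

test_that("single-variant genes get a descriptive record, never a test", {
  cohort <- simulate_burden_cohort(n_families = 3, n_unrelated = 2, seed = 2,
                                   n_variants = 2)
  d <- rep(0L, length(cohort$ids)); names(d) <- cohort$ids
  d[cohort$ids[cohort$family == "F01"][1:2]] <- 1L   # two carriers, one family
  d[cohort$ids[cohort$family == "unrelated"][1]] <- 1L
  rec <- singleton_report(cohort, d, gene = "CCNL2-like",
                          variant_key = "1:1334052:CTAGAG:C",
                          effect = "splice acceptor")
  expect_null(rec$p)
  expect_equal(rec$n_ms_families, 1)       # the family's affected carrier
  expect_equal(rec$n_control_subjects, 1)  # the unrelated healthy carrier

  # zero-carrier gene is omitted
  expect_null(singleton_report(cohort, stats::setNames(rep(0L, length(cohort$ids)),
                                                       cohort$ids), "none"))
})
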