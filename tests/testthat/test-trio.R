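test_that("de novo verdicts follow the evidence thresholds", {
  dn <- function(tab) detect_de_novo(tab, "PROBAND", "SIRE", "DAM")

  # textbook case: proband 0/1 (AD 14/29), both parents clean 0/0
  res <- dn(trio_site(1, 0, 0, pro_dp = 29, pro_ad = 14))
  expect_equal(res$verdict, "de_novo")

  # a carrier parent always means inherited
  expect_equal(dn(trio_site(1, 1, 0))$verdict, "inherited")
  expect_match(dn(trio_site(1, 1, 0))$reasons, "sire")
  expect_equal(dn(trio_site(1, 0, 2))$verdict, "inherited")

  # stray parental alt reads -> unresolved, named parent
  res <- dn(trio_site(1, 0, 0, dam_ad = 3))
  expect_equal(res$verdict, "unresolved")
  expect_match(res$reasons, "alt reads in dam")

  # thin parental coverage -> unresolved
  res <- dn(trio_site(1, 0, 0, sire_dp = 6))
  expect_equal(res$verdict, "unresolved")
  expect_match(res$reasons, "sire depth")

  # weak or unbalanced proband evidence -> unresolved
  expect_equal(dn(trio_site(1, 0, 0, pro_ad = 3))$verdict, "unresolved")
  expect_equal(dn(trio_site(1, 0, 0, pro_dp = 40, pro_ad = 36))$verdict,
               "unresolved")
  # missing genotypes never produce a de novo call
  expect_equal(dn(trio_site(NA, 0, 0))$verdict, "unresolved")
  expect_equal(dn(trio_site(1, NA, 0))$verdict, "unresolved")
})

test_that("Mendel verdicts match brute-force transmission enumeration", {
  # Oracle: a trio is compatible iff some allele of the sire and some
  # allele of the dam sum to the child dosage.
  alleles <- function(d) switch(as.character(d), "0" = 0L,
                                "1" = c(0L, 1L), "2" = 1L)
  oracle <- function(c, s, d) {
    any(outer(alleles(s), alleles(d), "+") == c)
  }
  for (child in 0:2) for (sire in 0:2) for (dam in 0:2) {
    tab <- trio_site(child, sire, dam)
    res <- count_mendel_errors(tab, "PROBAND", "SIRE", "DAM", strict = TRUE)
    expect_equal(res$errors == 1, !oracle(child, sire, dam),
                 label = sprintf("strict child=%d sire=%d dam=%d",
                                 child, sire, dam))
    # default mode: identical except the de novo signature is exempt
    res2 <- count_mendel_errors(tab, "PROBAND", "SIRE", "DAM")
    if (child == 1 && sire == 0 && dam == 0) {
      expect_equal(res2$errors, 0)
      expect_equal(res2$verdicts$verdict, "de_novo_signature")
    } else {
      expect_equal(res2$errors, res$errors)
    }
  }
  # missing genotypes are excluded from the tested count
  res <- count_mendel_errors(trio_site(2, NA, 0), "PROBAND", "SIRE", "DAM")
  expect_equal(res$n_tested, 0)
  expect_equal(res$errors, 0)
})

test_that("IBD estimation recovers self, parent-offspring and unrelated", {
  cfg <- sim_config(n_cohort_sites = 5000, seed = 11)
  sim <- simulate_all(cfg)
  tab <- sim$cohort$table
  ctrl <- sim$cohort$samples$controls

  # The generator draws sites independently (no linkage), so no distance
  # thinning is applied here; the default thinning serves real genomes.
  # identity case: a sample against itself
  self <- estimate_ibd(tab, "PROBAND", "PROBAND", freq_samples = ctrl,
                       thin_bp = 1)
  expect_equal(self$z2, 1, tolerance = 1e-12)
  expect_equal(self$pi_hat, 1, tolerance = 1e-12)

  # parent-offspring: Z0 near zero, pi_hat near 1/2
  po <- estimate_ibd(tab, "PROBAND", "SIRE", freq_samples = ctrl,
                     thin_bp = 1)
  expect_lte(po$z0, 0.02)
  expect_gte(po$pi_hat, 0.45)
  expect_lte(po$pi_hat, 0.55)

  # unrelated pair
  un <- estimate_ibd(tab, "SIRE", "DAM", freq_samples = ctrl, thin_bp = 1)
  expect_lte(un$pi_hat, 0.05)

  # symmetry and the Z simplex
  rev <- estimate_ibd(tab, "SIRE", "PROBAND", freq_samples = ctrl,
                      thin_bp = 1)
  expect_equal(po$pi_hat, rev$pi_hat)
  for (e in list(self, po, un)) {
    expect_equal(e$z0 + e$z1 + e$z2, 1, tolerance = 1e-12)
  }

  # refuses to estimate from too few sites
  few <- subset_variants(tab, seq_len(30))
  expect_error(estimate_ibd(few, "PROBAND", "SIRE", freq_samples = ctrl,
                            thin_bp = 1), "refused")
})

test_that("microsatellite transmission matches exhaustive assignment", {
  ms_row <- function(locus, sample, a) {
    data.frame(locus = locus, sample = sample, allele1 = a[1], allele2 = a[2])
  }
  trio_ms <- function(child, sire, dam) {
    rbind(ms_row("L1", "PROBAND", child), ms_row("L1", "SIRE", sire),
          ms_row("L1", "DAM", dam))
  }
  check1 <- function(child, sire, dam) {
    check_microsat_transmission(trio_ms(child, sire, dam),
                                "PROBAND", "SIRE", "DAM")$consistent_loci
  }
  # worked examples
  expect_equal(check1(c(150, 154), c(150, 158), c(154, 160)), 1)
  expect_equal(check1(c(150, 154), c(158, 162), c(154, 160)), 0)

  # exhaustive oracle over random allele draws: both assignments of the
  # child pair to the parents
  set.seed(77)
  for (i in 1:200) {
    pool <- sample(100:120, 4)
    sire <- sample(pool, 2, replace = TRUE)
    dam <- sample(pool, 2, replace = TRUE)
    child <- sample(pool, 2, replace = TRUE)
    oracle <- (child[1] %in% sire && child[2] %in% dam) ||
      (child[2] %in% sire && child[1] %in% dam)
    expect_equal(check1(child, sire, dam), as.integer(oracle))
  }

  # missing calls exclude the locus from the total, with a warning
  ms <- rbind(trio_ms(c(150, 154), c(150, 158), c(154, 160)),
              ms_row("L2", "PROBAND", c(NA, NA)),
              ms_row("L2", "SIRE", c(101, 103)),
              ms_row("L2", "DAM", c(105, 107)))
  expect_warning(res <- check_microsat_transmission(ms, "PROBAND", "SIRE",
                                                    "DAM"), "L2")
  expect_equal(res$total_loci, 1)
})

test_that("expected protein-changing de novo count is about one per trio", {
  res <- expected_protein_changing_dn(73, 0.013, n_trios = 10000, seed = 3)
  expect_equal(res$analytic, 0.949)
  expect_lt(abs(res$mc_mean - res$analytic), 3 * res$mc_se)
  expect_equal(expected_protein_changing_dn(50, 0, n_trios = 100,
                                            seed = 1)$mc_mean, 0)
})
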