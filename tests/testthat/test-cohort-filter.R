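make_branch_table <- function() {
  # 6 variants x (proband + 4 controls); dosages chosen per test comments
  v <- data.frame(contig = "chr1", pos = c(10, 20, 30, 40, 50, 60) * 10L,
                  ref = "A", alt = "G")
  samples <- c("PROBAND", paste0("C", 1:4))
  # rows: 1 hom proband private; 2 het proband private; 3 het proband with
  # one control carrier; 4 missing proband; 5 hom proband, one control het;
  # 6 het proband private with one missing control genotype
  gt <- rbind(
    c(2, 0, 0, 0, 0),
    c(1, 0, 0, 0, 0),
    c(1, 0, 1, 0, 0),
    c(NA, 0, 0, 0, 0),
    c(2, 0, 0, 2, 0),
    c(1, 0, 0, 0, NA))
  gt_a <- ifelse(is.na(gt), NA_integer_, as.integer(gt == 2))
  gt_b <- ifelse(is.na(gt), NA_integer_, as.integer(gt >= 1))
  variant_table(v, samples, gt_a, gt_b,
                dp = matrix(30L, 6, 5), ad = ifelse(is.na(gt), 0L, gt * 10L),
                gq = matrix(99L, 6, 5))
}

test_that("zygosity selection splits proband genotypes into branches", {
  tab <- make_branch_table()
  hom <- select_zygosity(tab, "PROBAND", "homozygous")
  het <- select_zygosity(tab, "PROBAND", "heterozygous")
  expect_setequal(hom$variants$pos, c(100, 500))
  expect_setequal(het$variants$pos, c(200, 300, 600))
  # the missing proband call is in neither branch
  expect_false(400 %in% c(hom$variants$pos, het$variants$pos))
  expect_error(select_zygosity(tab, "NOBODY", "homozygous"), "NOBODY")
})

test_that("private filtering removes any panel-carried variant", {
  tab <- make_branch_table()
  panel <- control_panel(tab, paste0("C", 1:4))
  het <- select_zygosity(tab, "PROBAND", "heterozygous")
  priv <- filter_private(het, panel)
  # carried het by one control -> removed; absent from all -> retained
  expect_setequal(priv$variants$pos, c(200, 600))
  # strict mode also drops the variant with a missing panel genotype
  strict <- filter_private(het, panel, missing_policy = "strict")
  expect_setequal(strict$variants$pos, 200)
})

test_that("protein-changing filter applies the any-transcript rule", {
  tab <- make_branch_table()
  keys <- variant_keys(tab)
  ann <- data.frame(
    key = keys, protein_changing = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  kept <- filter_protein_changing(tab, ann)
  expect_setequal(kept$variants$pos, c(100, 200))
  expect_equal(n_variants(filter_protein_changing(
    tab, transform(ann, protein_changing = FALSE))), 0)
  expect_error(filter_protein_changing(tab, ann[-2, ]), "unannotated")
})

test_that("artifact flags detect gaps, repeats and coverage dropouts", {
  set.seed(61)
  left <- rand_bases(600)
  gap <- paste(rep("N", 50), collapse = "")
  mid <- rand_bases(100)   # variant sits here, 100 bp from the gap
  tract <- paste(rep("AT", 200), collapse = "")
  right <- rand_bases(600)
  seq <- paste0(left, gap, mid, tract, right)
  ref <- Biostrings::DNAStringSet(c(chr1 = seq))

  near <- list(contig = "chr1", pos = 650 + 100)
  fl <- flag_artifacts(near, ref)
  expect_true(fl$near_gap)
  expect_true(is.na(fl$low_coverage))  # no coverage supplied -> unknown

  far <- list(contig = "chr1", pos = nchar(seq) - 50)
  expect_false(flag_artifacts(far, ref)$near_gap)

  # centred in the (AT)x200 tract; brute-force oracle for the window scan
  centre <- 750 + 200
  fl <- flag_artifacts(list(contig = "chr1", pos = centre), ref)
  win <- substr(seq, centre - 100, centre + 99)
  m <- gregexpr("(AT){3,}|(TA){3,}", win)[[1]]
  oracle_frac <- sum(attr(m, "match.length")) / nchar(win)
  expect_true(oracle_frac > 0.8)
  expect_true(fl$repetitive)
  expect_false(flag_artifacts(far, ref)$repetitive)

  # soft-masked (lowercase) windows also count as repetitive
  soft <- seq
  substr(soft, 1201, 1600) <- tolower(substr(soft, 1201, 1600))
  refsoft <- c(chr1 = soft)  # character form preserves the masking case
  expect_true(flag_artifacts(list(contig = "chr1", pos = 1400),
                             refsoft)$repetitive)

  # simulated coverage dropout to depth 2 -> low_coverage
  cov <- list(chr1 = rep(30L, nchar(seq)))
  cov$chr1[(centre - 60):(centre + 60)] <- 2L
  expect_true(flag_artifacts(list(contig = "chr1", pos = centre), ref,
                             cov)$low_coverage)
  expect_false(flag_artifacts(far, ref, cov)$low_coverage)
})

test_that("the cascade is monotone and its two filters commute", {
  for (seed in c(3, 8)) {
    cfg <- small_sim_config(seed)
    sim <- simulate_all(cfg)
    tab <- sim$cohort$table
    panel <- control_panel(tab, sim$cohort$samples$controls)
    het <- select_zygosity(tab, "PROBAND", "heterozygous")
    priv <- filter_private(het, panel)
    ann <- annotate_all(het, sim$reference$models, sim$reference$reference)
    pc_first <- filter_private(filter_protein_changing(het, ann), panel)
    priv_first <- filter_protein_changing(priv, ann)
    expect_setequal(variant_keys(pc_first), variant_keys(priv_first))
    # monotone: each stage a subset of its input
    expect_true(all(variant_keys(priv) %in% variant_keys(het)))
    expect_true(all(variant_keys(priv_first) %in% variant_keys(priv)))
    # determinism: rerunning the cascade reproduces the report
    r1 <- run_cascade(tab, "PROBAND", panel, ann, "heterozygous")
    r2 <- run_cascade(tab, "PROBAND", panel, ann, "heterozygous")
    expect_identical(r1$report, r2$report)
    # empty input -> all-zero report
    r0 <- run_cascade(subset_variants(tab, FALSE), "PROBAND", panel, ann,
                      "homozygous")
    expect_equal(r0$report$count, c(0, 0, 0))
  }
})

test_that("an error-free panel removes every inherited variant", {
  cfg <- small_sim_config(14)
  sim <- simulate_all(cfg)
  tab <- sim$cohort$table
  man <- sim$cohort$manifest
  panel <- control_panel(tab, sim$cohort$samples$controls)
  het <- select_zygosity(tab, "PROBAND", "heterozygous")
  priv <- filter_private(het, panel)
  # survivors are planted de novo events or cohort variants the panel
  # happens to lack -- never variants with a panel carrier
  expect_true(all(man$n_panel_carriers[match(variant_keys(priv),
                                             man$key)] == 0))
  dn_keys <- man$key[man$origin == "de_novo" & man$proband_dosage == 1]
  expect_true(all(dn_keys %in% variant_keys(priv)))
})

test_that("site-list panels drive the same privacy decision", {
  tab <- make_branch_table()
  f <- withr::local_tempfile(fileext = ".tsv")
  v <- tab$variants[c(3, 5), ]
  v$n_carriers <- c(1L, 2L)
  write.table(v, f, sep = "\t", quote = FALSE, row.names = FALSE)
  panel <- panel_from_sites(f, n_controls = 288)
  expect_equal(panel$n_controls, 288)
  het <- select_zygosity(tab, "PROBAND", "heterozygous")
  expect_setequal(filter_private(het, panel)$variants$pos, c(200, 600))
})
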