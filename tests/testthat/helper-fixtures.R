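# Fixtures are built in code; nothing is read from disk.

BASES <- c("A", "C", "G", "T")
sense_codon_pool <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

rand_bases <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# A single-exon transcript on its own contig. `codons` is the full codon
# vector (ATG ... stop). Returns reference, model and the genomic position
# of each CDS base.
single_exon_fixture <- function(codons, strand = "+", utr5 = 10, utr3 = 10,
                                contig = "chrT") {
  cds <- paste(codons, collapse = "")
  seq <- paste0(rand_bases(utr5), cds, rand_bases(utr3))
  L <- nchar(seq)
  if (strand == "+") {
    model <- transcript_model("TXF", "GENEF", contig, "+",
                              data.frame(start = 1, end = L),
                              utr5 + 1, utr5 + nchar(cds))
    cds_gpos <- seq(utr5 + 1, utr5 + nchar(cds))
  } else {
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    model <- transcript_model("TXF", "GENEF", contig, "-",
                              data.frame(start = 1, end = L),
                              L - (utr5 + nchar(cds)) + 1, L - utr5)
    cds_gpos <- seq(L - utr5, L - (utr5 + nchar(cds)) + 1)
  }
  list(reference = Biostrings::DNAStringSet(setNames(seq, contig)),
       model = model, cds = cds, cds_gpos = cds_gpos, length = L)
}

# Two-exon plus-strand transcript with a known intron, for splice tests.
two_exon_fixture <- function(codons, split_after = 30, intron_len = 60,
                             utr5 = 8, utr3 = 8, contig = "chrT") {
  cds <- paste(codons, collapse = "")
  stopifnot(split_after < nchar(cds))
  intron <- paste0("GT", rand_bases(intron_len - 4), "AG")
  exon1 <- paste0(rand_bases(utr5), substr(cds, 1, split_after))
  exon2 <- paste0(substr(cds, split_after + 1, nchar(cds)), rand_bases(utr3))
  seq <- paste0(exon1, intron, exon2)
  e1_end <- nchar(exon1)
  e2_start <- e1_end + intron_len + 1
  model <- transcript_model(
    "TX2", "GENE2", contig, "+",
    data.frame(start = c(1, e2_start), end = c(e1_end, nchar(seq))),
    utr5 + 1, e2_start + (nchar(cds) - split_after) - 1)
  list(reference = Biostrings::DNAStringSet(setNames(seq, contig)),
       model = model, cds = cds, e1_end = e1_end, e2_start = e2_start)
}

# Random small genotype table.
random_table <- function(n = 25, m = 3, seed = 1) {
  set.seed(seed)
  v <- data.frame(contig = sample(c("chr1", "chr2"), n, TRUE),
                  pos = sample.int(1e5, n),
                  ref = sample(BASES, n, TRUE))
  v$alt <- vapply(v$ref, function(r) sample(setdiff(BASES, r), 1), "")
  gt_a <- matrix(sample(c(0L, 0L, 1L, NA), n * m, TRUE), n, m)
  gt_b <- matrix(sample(c(0L, 1L, 1L, NA), n * m, TRUE), n, m)
  dp <- matrix(rpois(n * m, 20), n, m)
  ad <- pmin(matrix(rpois(n * m, 8), n, m), dp)
  gq <- matrix(sample(0:99, n * m, TRUE), n, m)
  variant_table(v, paste0("S", seq_len(m)), gt_a, gt_b, dp, ad, gq)
}

# One-variant trio table from dosages and depth evidence.
trio_site <- function(pro, sire, dam,
                      pro_dp = 29, pro_ad = NULL,
                      sire_dp = 25, sire_ad = 0,
                      dam_dp = 30, dam_ad = 0) {
  gt <- function(d) {
    if (is.na(d)) c(NA_integer_, NA_integer_)
    else switch(as.character(d), "0" = c(0L, 0L), "1" = c(0L, 1L),
                "2" = c(1L, 1L))
  }
  ad_of <- function(d, dp, ad) {
    if (!is.null(ad)) return(ad)
    if (is.na(d)) 0L else switch(as.character(d), "0" = 0L,
                                 "1" = as.integer(dp / 2), "2" = dp)
  }
  g <- cbind(gt(pro), gt(sire), gt(dam))
  variant_table(
    data.frame(contig = "chr1", pos = 1000L, ref = "T", alt = "C"),
    c("PROBAND", "SIRE", "DAM"),
    matrix(g[1, ], 1), matrix(g[2, ], 1),
    matrix(c(pro_dp, sire_dp, dam_dp), 1),
    matrix(c(ad_of(pro, pro_dp, pro_ad), ad_of(sire, sire_dp, sire_ad),
             ad_of(dam, dam_dp, dam_ad)), 1),
    matrix(99L, 1, 3))
}

# Small, fast simulation settings used where full study-scale conditions
# are not the point of the test.
small_sim_config <- function(seed, ...) {
  sim_config(genome_length = 3e5, n_contigs = 2, n_genes = 6,
             n_controls = 24, n_cohort_sites = 600, lambda_dn = 15,
             seed = seed, ...)
}
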