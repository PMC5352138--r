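test_that("codon addressing follows the CDS arithmetic", {
  expect_equal(cds_to_codon(1052), list(codon_index = 351L, offset = 1L))
  expect_equal(cds_to_codon(1), list(codon_index = 1L, offset = 0L))
  expect_equal(cds_to_codon(3), list(codon_index = 1L, offset = 2L))
  # round-trip identity over a long range
  pos <- 1:10000
  addr <- cds_to_codon(pos)
  expect_identical(3L * (addr$codon_index - 1L) + addr$offset + 1L, pos)
})

test_that("genomic-to-CDS mapping is strand-aware and symmetric", {
  set.seed(7)
  codons <- c("ATG", sample(sense_codon_pool(), 360, TRUE), "TAA")
  plus <- single_exon_fixture(codons, strand = "+")
  minus <- single_exon_fixture(codons, strand = "-")
  # identity and offset arithmetic on the plus strand
  expect_equal(map_genomic_to_cds(plus$cds_gpos[1], plus$model)$cds_pos, 1L)
  expect_equal(map_genomic_to_cds(plus$cds_gpos[1] + 1051, plus$model)$cds_pos,
               1052L)
  # minus-strand mirror of the same construction: identical CDS positions
  for (cp in c(1L, 2L, 500L, 1052L)) {
    expect_equal(map_genomic_to_cds(minus$cds_gpos[cp], minus$model)$cds_pos,
                 cp)
  }
  expect_equal(map_genomic_to_cds(1e6, plus$model)$type, "intergenic")
})

test_that("a T>C change at CDS 1052 of a Leu codon is called p.(Leu351Pro)", {
  set.seed(11)
  codons <- c("ATG", sample(sense_codon_pool(), 350, TRUE), "TGA")
  codons[351] <- "CTG"  # leucine codon; CDS position 1052 is its middle T
  for (strand in c("+", "-")) {
    fix <- single_exon_fixture(codons, strand = strand)
    gpos <- fix$cds_gpos[1052]
    refb <- if (strand == "+") "T" else "A"
    altb <- if (strand == "+") "C" else "G"
    csq <- annotate_variant(
      list(contig = "chrT", pos = gpos, ref = refb, alt = altb),
      fix$model, fix$reference)
    expect_equal(csq$csq_class, "missense")
    expect_equal(csq$hgvs_c, "c.1052T>C")
    expect_equal(csq$hgvs_p, "p.(Leu351Pro)")
    expect_true(csq$protein_changing)
    expect_equal(csq$codon_index, 351L)
  }
})

test_that("middle-base T>C in leucine codons follows the genetic code", {
  # The four CTN codons give proline; TTA/TTG give serine. All six changes
  # are missense.
  leu <- c("CTA", "CTC", "CTG", "CTT", "TTA", "TTG")
  expected_aa <- c(CTA = "Pro", CTC = "Pro", CTG = "Pro", CTT = "Pro",
                   TTA = "Ser", TTG = "Ser")
  for (codon in leu) {
    codons <- c("ATG", "AAA", codon, "GGG", "TAA")
    fix <- single_exon_fixture(codons)
    gpos <- fix$cds_gpos[3 * 2 + 2]  # middle base of codon 3
    csq <- annotate_variant(
      list(contig = "chrT", pos = gpos, ref = "T", alt = "C"),
      fix$model, fix$reference)
    expect_equal(csq$csq_class, "missense")
    expect_equal(csq$hgvs_p, sprintf("p.(Leu3%s)", expected_aa[[codon]]))
  }
})

test_that("re-translating the mutated CDS agrees with every annotation", {
  # Independent oracle: apply the SNV to the full CDS, translate both
  # sequences with Biostrings, and derive the expected class/protein change.
  set.seed(101)
  n_checked <- 0
  for (rep in 1:5) {
    codons <- c("ATG", sample(sense_codon_pool(), sample(80:200, 1), TRUE),
                sample(c("TAA", "TAG", "TGA"), 1))
    strand <- sample(c("+", "-"), 1)
    fix <- single_exon_fixture(codons, strand = strand)
    cds <- fix$cds
    L <- nchar(cds)
    for (k in 1:220) {
      cp <- sample.int(L, 1)
      tx_ref <- substr(cds, cp, cp)
      tx_alt <- sample(setdiff(BASES, tx_ref), 1)
      mut <- cds
      substr(mut, cp, cp) <- tx_alt
      prot_ref <- as.character(Biostrings::translate(
        Biostrings::DNAString(cds), no.init.codon = TRUE))
      prot_alt <- as.character(Biostrings::translate(
        Biostrings::DNAString(mut), no.init.codon = TRUE))

      gpos <- fix$cds_gpos[cp]
      refb <- if (strand == "+") tx_ref else chartr("ACGT", "TGCA", tx_ref)
      altb <- if (strand == "+") tx_alt else chartr("ACGT", "TGCA", tx_alt)
      csq <- annotate_variant(
        list(contig = "chrT", pos = gpos, ref = refb, alt = altb),
        fix$model, fix$reference)

      if (prot_ref == prot_alt) {
        expect_equal(csq$csq_class, "synonymous")
        expect_false(csq$protein_changing)
        expect_equal(csq$hgvs_p, "")
      } else {
        diffs <- which(strsplit(prot_ref, "")[[1]] !=
                         strsplit(prot_alt, "")[[1]])
        expect_length(diffs, 1)
        expect_equal(csq$codon_index, diffs)
        expect_true(csq$protein_changing)
        aa1 <- substr(prot_ref, diffs, diffs)
        aa2 <- substr(prot_alt, diffs, diffs)
        want <- if (cp <= 3 && aa2 != "M") "start_loss"
          else if (aa1 != "*" && aa2 == "*") "stop_gain"
          else if (aa1 == "*" && aa2 != "*") "stop_loss"
          else "missense"
        expect_equal(csq$csq_class, want)
      }
      expect_equal(csq$hgvs_c, sprintf("c.%d%s>%s", cp, tx_ref, tx_alt))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 1000)
})

test_that("splice-site and non-coding regions classify by distance", {
  set.seed(23)
  codons <- c("ATG", sample(sense_codon_pool(), 40, TRUE), "TAA")
  fix <- two_exon_fixture(codons, split_after = 30, intron_len = 60)
  ref <- fix$reference
  at <- function(pos) {
    refb <- substr(as.character(ref[[1]]), pos, pos)
    altb <- setdiff(c("A", "G"), refb)[1]
    annotate_variant(list(contig = "chrT", pos = pos, ref = refb, alt = altb),
                     fix$model, ref)
  }
  # first/second intronic base at the donor: splice_site, protein-changing
  expect_equal(at(fix$e1_end + 1)$csq_class, "splice_site")
  expect_true(at(fix$e1_end + 2)$protein_changing)
  # third intronic base: plain non-coding
  expect_equal(at(fix$e1_end + 3)$csq_class, "non_coding")
  # acceptor side
  expect_equal(at(fix$e2_start - 1)$csq_class, "splice_site")
  # 5' UTR base: non-coding
  expect_equal(at(1)$csq_class, "non_coding")
})

test_that("stop gain/loss, start loss, indels and N codons classify", {
  fix <- single_exon_fixture(c("ATG", "TAC", "CCC", "TAA"))
  g <- fix$cds_gpos
  csq <- annotate_variant(list(contig = "chrT", pos = g[6], ref = "C",
                               alt = "A"), fix$model, fix$reference)
  expect_equal(csq$csq_class, "stop_gain")   # TAC -> TAA
  expect_equal(csq$hgvs_p, "p.(Tyr2Ter)")
  csq <- annotate_variant(list(contig = "chrT", pos = g[11], ref = "A",
                               alt = "C"), fix$model, fix$reference)
  expect_equal(csq$csq_class, "stop_loss")   # TAA -> TCA
  csq <- annotate_variant(list(contig = "chrT", pos = g[1], ref = "A",
                               alt = "C"), fix$model, fix$reference)
  expect_equal(csq$csq_class, "start_loss")
  # indels: length change not divisible by 3 -> frameshift, else inframe
  refb <- substr(as.character(fix$reference[[1]]), g[4], g[5])
  csq <- annotate_variant(list(contig = "chrT", pos = g[4], ref = refb,
                               alt = substr(refb, 1, 1)),
                          fix$model, fix$reference)
  expect_equal(csq$csq_class, "frameshift")
  refb3 <- substr(as.character(fix$reference[[1]]), g[4], g[7])
  csq <- annotate_variant(list(contig = "chrT", pos = g[4], ref = refb3,
                               alt = substr(refb3, 1, 1)),
                          fix$model, fix$reference)
  expect_equal(csq$csq_class, "inframe_indel")
  # ambiguity base in the codon -> unresolvable, not protein-changing
  fixn <- single_exon_fixture(c("ATG", "TAC", "CCC", "TAA"))
  s <- as.character(fixn$reference[[1]])
  substr(s, fixn$cds_gpos[5], fixn$cds_gpos[5]) <- "N"
  refn <- Biostrings::DNAStringSet(setNames(s, "chrT"))
  csq <- annotate_variant(list(contig = "chrT", pos = fixn$cds_gpos[6],
                               ref = substr(s, fixn$cds_gpos[6],
                                            fixn$cds_gpos[6]), alt = "G"),
                          fixn$model, refn)
  expect_equal(csq$csq_class, "unresolvable")
  expect_false(csq$protein_changing)
  # REF mismatch is a data-integrity error naming the position
  expect_error(
    annotate_variant(list(contig = "chrT", pos = g[2], ref = "N", alt = "C"),
                     fix$model, fix$reference),
    "REF mismatch")
})

test_that("any-transcript rule governs protein-changing status", {
  # Two overlapping models on one contig: the variant is missense in one
  # frame and lands in the UTR of the other.
  set.seed(31)
  codons <- c("ATG", "AAA", "CTG", "GGG", "TAA")
  fix <- single_exon_fixture(codons, utr5 = 30, utr3 = 30)
  L <- fix$length
  m2 <- transcript_model("TXU", "GENEU", "chrT", "+",
                         data.frame(start = 1, end = L), 2, 7)
  g <- fix$cds_gpos[8]  # middle of codon 3 (CTG)
  tab <- variant_table(
    data.frame(contig = "chrT", pos = g, ref = "T", alt = "C"),
    "S1", matrix(0L, 1, 1), matrix(1L, 1, 1))
  ann <- annotate_all(tab, list(fix$model, m2), fix$reference)
  expect_equal(nrow(ann), 2)
  expect_setequal(ann$csq_class, c("missense", "non_coding"))
  expect_true(protein_changing_any(ann)[[variant_keys(tab)]])

  # variant on a contig with no models -> intergenic; empty table -> empty
  tab2 <- variant_table(
    data.frame(contig = "chrZ", pos = 5L, ref = "A", alt = "T"),
    "S1", matrix(0L, 1, 1), matrix(1L, 1, 1))
  ann2 <- annotate_all(tab2, list(fix$model), fix$reference)
  expect_equal(ann2$csq_class, "intergenic")
  expect_equal(nrow(annotate_all(subset_variants(tab2, FALSE),
                                 list(fix$model), fix$reference)), 0)
})

test_that("gene-set screening selects by span overlap", {
  set.seed(13)
  codons <- c("ATG", sample(sense_codon_pool(), 20, TRUE), "TAA")
  fix <- single_exon_fixture(codons)
  span_end <- fix$length
  mk <- function(pos) {
    refb <- substr(as.character(fix$reference[[1]]), pos, pos)
    data.frame(contig = "chrT", pos = pos,
               ref = ifelse(nzchar(refb), refb, "A"), alt = NA)
  }
  v <- rbind(mk(15), mk(span_end))           # inside
  v <- rbind(v, data.frame(contig = "chrT", pos = span_end + 1L,
                           ref = "A", alt = NA))  # 1 bp outside
  v$alt <- vapply(v$ref, function(r) setdiff(BASES, r)[1], "")
  tab <- variant_table(v, "S1", matrix(0L, 3, 1), matrix(1L, 3, 1))
  hit <- screen_gene_set(tab, list(fix$model), "GENEF")
  expect_equal(n_variants(hit), 2)
  expect_false((span_end + 1L) %in% hit$variants$pos)
  expect_warning(screen_gene_set(tab, list(fix$model), c("GENEF", "NOPE")),
                 "NOPE")
  # a clean panel yields an empty sub-table
  far <- variant_table(data.frame(contig = "chrQ", pos = 1L, ref = "A",
                                  alt = "T"),
                       "S1", matrix(0L, 1, 1), matrix(1L, 1, 1))
  expect_equal(n_variants(screen_gene_set(far, list(fix$model), "GENEF")), 0)
})
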