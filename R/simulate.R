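# Seeded synthetic data: miniature diploid reference with gene models,
# control cohort, trio with planted inherited/de novo/artifact variants,
# and a full planted-truth manifest.

TRIO_SAMPLES <- c(proband = "PROBAND", sire = "SIRE", dam = "DAM")

#' Simulation configuration
#'
#' Defaults mirror the study conditions the pipeline was built to emulate:
#' a 288-genome control panel, a Poisson mean of 73 de novo events per trio
#' of which 1.3% are protein-changing, and a handful of artifact-prone
#' sites, all on a miniature 2 Mb / 2-contig genome carrying 20 genes.
#'
#' @param genome_length total genome size in bp, split over `n_contigs`.
#' @param n_contigs number of contigs.
#' @param n_genes number of genes (single- and multi-exon, both strands).
#' @param n_controls control-panel size.
#' @param n_cohort_sites segregating sites drawn for the cohort.
#' @param lambda_dn mean de novo events per trio.
#' @param p_protein_changing probability a de novo event is protein-changing.
#' @param geno_error_rate per-genotype error rate applied to the trio.
#' @param artifact_site_count planted artifact-prone homozygous candidates.
#' @param n_gaps assembly N-gap runs (one is placed inside an intron).
#' @param gap_length length of each N-gap run.
#' @param n_repeat_tracts low-complexity dinucleotide tracts (one is placed
#'   inside a coding exon).
#' @param repeat_tract_length length of each tract in bp.
#' @param depth_mean mean simulated read depth.
#' @param seed RNG seed; every simulation function derives its stream from
#'   it, so equal configs give byte-identical outputs.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 2e6, n_contigs = 2, n_genes = 20,
                       n_controls = 288, n_cohort_sites = 20000,
                       lambda_dn = 73, p_protein_changing = 0.013,
                       geno_error_rate = 0, artifact_site_count = 4,
                       n_gaps = 4, gap_length = 50, n_repeat_tracts = 2,
                       repeat_tract_length = 400, depth_mean = 30, seed = 1) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_contigs = as.integer(n_contigs),
              n_genes = as.integer(n_genes),
              n_controls = as.integer(n_controls),
              n_cohort_sites = as.integer(n_cohort_sites),
              lambda_dn = lambda_dn,
              p_protein_changing = p_protein_changing,
              geno_error_rate = geno_error_rate,
              artifact_site_count = as.integer(artifact_site_count),
              n_gaps = as.integer(n_gaps),
              gap_length = as.integer(gap_length),
              n_repeat_tracts = as.integer(n_repeat_tracts),
              repeat_tract_length = as.integer(repeat_tract_length),
              depth_mean = depth_mean,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(genome_length > 0, n_contigs >= 1, n_genes >= 3,
              n_controls >= 1, n_cohort_sites >= 1, lambda_dn > 0,
              p_protein_changing >= 0, p_protein_changing <= 1,
              geno_error_rate >= 0, geno_error_rate <= 1,
              artifact_site_count >= 0, n_gaps >= 1, n_repeat_tracts >= 1)
  })
  structure(cfg, class = "sim_config")
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

SENSE_CODONS <- NULL  # filled lazily; names(GENETIC_CODE) minus stops

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# Build one gene region on the plus strand, then optionally mirror it to
# the minus strand. Relative coordinates are 1-based within the region.
build_gene <- function(gene_id, tx_id, n_codons, n_exons, strand,
                       utr5 = 12L, utr3 = 12L, at_tract_codons = 0L,
                       intron_gap_len = 0L) {
  stopifnot(n_codons >= at_tract_codons + 20L)
  codons <- c("ATG",
              sample(sense_codons(), n_codons - 2L, replace = TRUE),
              sample(STOP_CODONS, 1))
  tract_rel <- NULL
  if (at_tract_codons > 0) {
    # Alternating ATA/TAT codons form an AT tract that is still coding
    # (Ile/Tyr, no stops in frame). Replaces a mid-CDS codon run.
    at <- rep(c("ATA", "TAT"), length.out = at_tract_codons)
    ins <- max(2L, floor((n_codons - at_tract_codons) / 2))
    codons[seq(ins, ins + at_tract_codons - 1L)] <- at
    tract_cds <- c((ins - 1L) * 3L + 1L, (ins - 1L + at_tract_codons) * 3L)
  }
  cds <- paste(codons, collapse = "")
  cds_len <- nchar(cds)

  # Split CDS into exon chunks of >= 30 bp.
  if (n_exons > 1) {
    repeat {
      cuts <- sort(sample(seq(31L, cds_len - 30L), n_exons - 1L))
      if (all(diff(c(0L, cuts, cds_len)) >= 30L)) break
    }
  } else cuts <- integer(0)
  bounds <- c(0L, cuts, cds_len)
  chunks <- vapply(seq_len(n_exons), function(i) {
    substr(cds, bounds[i] + 1L, bounds[i + 1L])
  }, character(1))

  introns <- character(max(0L, n_exons - 1L))
  for (i in seq_along(introns)) {
    ilen <- sample(120:260, 1)
    if (i == 1 && intron_gap_len > 0) ilen <- max(ilen, intron_gap_len + 80L)
    body <- random_seq(ilen - 4L)
    if (i == 1 && intron_gap_len > 0) {
      mid <- floor((ilen - 4L - intron_gap_len) / 2)
      substr(body, mid + 1L, mid + intron_gap_len) <-
        paste(rep("N", intron_gap_len), collapse = "")
    }
    introns[i] <- paste0("GT", body, "AG")
  }

  parts <- character(0)
  exon_rel <- data.frame(start = integer(0), end = integer(0))
  pos <- 0L
  push <- function(s) { parts <<- c(parts, s); pos <<- pos + nchar(s); }
  push(random_seq(utr5))
  cds_start_rel <- pos + 1L
  cds_cursor <- 0L
  gap_rel <- NULL
  for (i in seq_len(n_exons)) {
    ex_start <- if (i == 1) 1L else pos + 1L
    push(chunks[i])
    cds_cursor <- cds_cursor + nchar(chunks[i])
    if (i == n_exons) {
      cds_end_rel <- pos
      push(random_seq(utr3))
      ex_end <- pos
    } else {
      ex_end <- pos
    }
    exon_rel <- rbind(exon_rel, data.frame(start = ex_start, end = ex_end))
    if (i < n_exons) {
      if (i == 1 && intron_gap_len > 0) {
        off <- regexpr("N+", introns[i])
        gap_rel <- c(pos + off, pos + off + attr(off, "match.length") - 1L)
      }
      push(introns[i])
    }
  }
  # First exon starts at region start (includes 5' UTR).
  exon_rel$start[1] <- 1L
  region <- paste(parts, collapse = "")
  L <- nchar(region)
  if (at_tract_codons > 0) {
    # CDS-relative tract to region-relative (single-exon assumption is not
    # needed: map both ends through the exon chunks).
    tract_rel <- cds_rel_to_region(tract_cds, bounds, exon_rel, cds_start_rel)
  }

  flip <- function(iv) c(L - iv[2] + 1L, L - iv[1] + 1L)
  if (strand == "-") {
    region <- revcomp(region)
    ex <- t(apply(as.matrix(exon_rel), 1, function(r) flip(r)))
    exon_rel <- data.frame(start = ex[, 1], end = ex[, 2])
    exon_rel <- exon_rel[order(exon_rel$start), , drop = FALSE]
    cdsiv <- flip(c(cds_start_rel, cds_end_rel))
    cds_start_rel <- cdsiv[1]; cds_end_rel <- cdsiv[2]
    if (!is.null(tract_rel)) tract_rel <- flip(tract_rel)
    if (!is.null(gap_rel)) gap_rel <- flip(gap_rel)
  }
  list(gene_id = gene_id, tx_id = tx_id, strand = strand, seq = region,
       length = L, exons = exon_rel, cds_start = cds_start_rel,
       cds_end = cds_end_rel, tract = tract_rel, gap = gap_rel)
}

# Map a CDS-relative interval to region-relative coordinates on the
# plus-strand layout (before any minus-strand flip).
cds_rel_to_region <- function(iv, bounds, exon_rel, cds_start_rel) {
  one <- function(cpos) {
    chunk <- findInterval(cpos - 1L, bounds, rightmost.closed = FALSE)
    chunk <- min(max(chunk, 1L), nrow(exon_rel))
    within <- cpos - bounds[chunk]
    ex_cds_start <- if (chunk == 1) cds_start_rel else exon_rel$start[chunk]
    ex_cds_start + within - 1L
  }
  c(one(iv[1]), one(iv[2]))
}

#' Simulate a miniature reference genome with gene models
#'
#' Generates random contigs carrying genes with valid start/stop codons and
#' CDS lengths divisible by 3 (single- and multi-exon, both strands),
#' embedded N-gap runs (one inside an intron) and low-complexity AT tracts
#' (one inside a coding exon) to exercise artifact flagging. Deterministic
#' under `config$seed`.
#'
#' @param config a [sim_config()].
#' @return List of class `sim_reference`: `reference`
#'   ([Biostrings::DNAStringSet]), `models` (list of [transcript_model()]),
#'   `gaps` and `tracts` (data.frames of feature coordinates), `config`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  contig_len <- config$genome_length %/% config$n_contigs
  contigs <- paste0("chr", seq_len(config$n_contigs))
  genes_per <- diff(floor(seq(0, config$n_genes, length.out =
                                config$n_contigs + 1)))

  models <- list()
  gaps <- list()
  tracts <- list()
  seqs <- setNames(character(config$n_contigs), contigs)
  gene_no <- 0L

  for (ci in seq_len(config$n_contigs)) {
    ng <- genes_per[ci]
    built <- list()
    for (g in seq_len(ng)) {
      gene_no <- gene_no + 1L
      special_gap <- gene_no == 1L
      special_tract <- gene_no == 2L
      at_codons <- if (special_tract) {
        as.integer(ceiling(config$repeat_tract_length / 3))
      } else 0L
      built[[g]] <- build_gene(
        gene_id = sprintf("GENE%03d", gene_no),
        tx_id = sprintf("TX%03d", gene_no),
        n_codons = max(sample(150:350, 1), at_codons + 40L),
        n_exons = if (special_gap) sample(2:4, 1)
                  else if (special_tract) 1L else sample(1:4, 1),
        strand = if (gene_no <= 2) "+" else sample(c("+", "-"), 1),
        at_tract_codons = at_codons,
        intron_gap_len = if (special_gap) config$gap_length else 0L
      )
    }
    total_gene <- sum(vapply(built, `[[`, integer(1), "length"))
    free <- contig_len - total_gene
    if (free < (ng + 1L) * 800L) {
      stop("infeasible gene packing on ", contigs[ci],
           ": increase genome_length or reduce n_genes", call. = FALSE)
    }
    spacer_len <- free %/% (ng + 1L)
    parts <- character(0)
    cursor <- 0L
    spacer_starts <- integer(0)
    for (g in seq_len(ng)) {
      parts <- c(parts, random_seq(spacer_len))
      spacer_starts <- c(spacer_starts, cursor + 1L)
      cursor <- cursor + spacer_len
      b <- built[[g]]
      off <- cursor
      models[[length(models) + 1]] <- transcript_model(
        b$tx_id, b$gene_id, contigs[ci], b$strand,
        data.frame(start = b$exons$start + off, end = b$exons$end + off),
        b$cds_start + off, b$cds_end + off)
      if (!is.null(b$gap)) {
        gaps[[length(gaps) + 1]] <- data.frame(
          contig = contigs[ci], start = b$gap[1] + off, end = b$gap[2] + off,
          context = "intronic")
      }
      if (!is.null(b$tract)) {
        tracts[[length(tracts) + 1]] <- data.frame(
          contig = contigs[ci], start = b$tract[1] + off,
          end = b$tract[2] + off, context = "coding", unit = "AT")
      }
      parts <- c(parts, b$seq)
      cursor <- cursor + b$length
    }
    tail_len <- contig_len - cursor
    parts <- c(parts, random_seq(tail_len))
    spacer_starts <- c(spacer_starts, cursor + 1L)
    seqs[ci] <- paste(parts, collapse = "")
  }

  # Remaining intergenic gaps and repeat tracts, placed mid-spacer at the
  # contig tails (spacers are >= 800 bp by the packing check).
  n_extra_gaps <- config$n_gaps - 1L
  n_extra_tracts <- config$n_repeat_tracts - 1L
  place <- function(ci, frac, feature) {
    s <- seqs[ci]
    pos <- as.integer(nchar(s) * frac)
    # back off if we'd land inside a gene
    spans <- do.call(rbind, lapply(models, function(m) {
      if (m$contig != contigs[ci]) return(NULL)
      sp <- transcript_span(m)
      data.frame(start = sp["start"], end = sp["end"])
    }))
    repeat {
      end <- pos + nchar(feature) - 1L
      inside <- !is.null(spans) &&
        any(pos <= spans$end + 600L & end >= spans$start - 600L)
      if (!inside || pos + nchar(feature) >= nchar(s)) break
      pos <- pos + 400L
    }
    substr(s, pos, pos + nchar(feature) - 1L) <- feature
    seqs[ci] <<- s
    c(pos, pos + nchar(feature) - 1L)
  }
  if (n_extra_gaps > 0) {
    for (k in seq_len(n_extra_gaps)) {
      ci <- ((k - 1L) %% config$n_contigs) + 1L
      iv <- place(ci, 0.05 + 0.9 * k / (n_extra_gaps + 1),
                  paste(rep("N", config$gap_length), collapse = ""))
      gaps[[length(gaps) + 1]] <- data.frame(
        contig = contigs[ci], start = iv[1], end = iv[2],
        context = "intergenic")
    }
  }
  if (n_extra_tracts > 0) {
    for (k in seq_len(n_extra_tracts)) {
      ci <- ((k - 1L) %% config$n_contigs) + 1L
      tract <- paste(rep("AT", ceiling(config$repeat_tract_length / 2)),
                     collapse = "")
      iv <- place(ci, 0.12 + 0.8 * k / (n_extra_tracts + 1), tract)
      tracts[[length(tracts) + 1]] <- data.frame(
        contig = contigs[ci], start = iv[1], end = iv[2],
        context = "intergenic", unit = "AT")
    }
  }

  structure(list(
    reference = Biostrings::DNAStringSet(seqs),
    models = models,
    gaps = do.call(rbind, gaps),
    tracts = do.call(rbind, tracts),
    config = config
  ), class = "sim_reference")
}

#' Write a simulated reference to FASTA + GFF3
#'
#' @param simref a [simulate_reference()] result.
#' @param dir output directory (created if needed).
#' @return Named list of the `fasta` and `gff3` paths.
#' @export
write_sim_reference <- function(simref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "reference.fa")
  gff3 <- file.path(dir, "genes.gff3")
  Biostrings::writeXStringSet(simref$reference, fasta)
  write_gff3(simref$models, gff3)
  list(fasta = fasta, gff3 = gff3)
}

# Inverse of map_genomic_to_cds for positions known to be coding.
map_cds_to_genomic <- function(cds_pos, model) {
  seg <- cds_segments(model)
  lens <- seg$end - seg$start + 1L
  total <- sum(lens)
  p_plus <- if (model$strand == "+") cds_pos else total - cds_pos + 1L
  cum <- cumsum(lens)
  i <- which(p_plus <= cum)[1]
  before <- if (i > 1) cum[i - 1L] else 0L
  seg$start[i] + (p_plus - before) - 1L
}

# Best protein-changing annotation of an arbitrary variant across models.
classify_planted <- function(contig, pos, ref, alt, models, reference) {
  best <- list(csq_class = "intergenic", protein_changing = FALSE,
               gene_id = NA_character_)
  for (m in models) {
    if (m$contig != contig) next
    sp <- transcript_span(m)
    if (pos < sp["start"] || pos > sp["end"]) next
    csq <- annotate_variant(list(contig = contig, pos = pos, ref = ref,
                                 alt = alt), m, reference)
    if (csq$protein_changing || best$csq_class == "intergenic") {
      best <- list(csq_class = csq$csq_class,
                   protein_changing = csq$protein_changing ||
                     best$protein_changing,
                   gene_id = csq$gene_id)
    }
  }
  best
}

# Rejection-sample a missense SNV inside a model's CDS, optionally
# restricted to an allowed set of genomic positions.
engineer_missense <- function(model, reference, contig_chars,
                              allowed_gpos = NULL, tries = 1000) {
  seg <- cds_segments(model)
  total <- sum(seg$end - seg$start + 1L)
  bases <- c("A", "C", "G", "T")
  for (t in seq_len(tries)) {
    cds_pos <- sample(4:(total - 3L), 1)
    gpos <- map_cds_to_genomic(cds_pos, model)
    if (!is.null(allowed_gpos) && !gpos %in% allowed_gpos) next
    refb <- toupper(substr(contig_chars[[model$contig]], gpos, gpos))
    if (!refb %in% bases) next
    for (altb in sample(setdiff(bases, refb))) {
      csq <- annotate_variant(list(contig = model$contig, pos = gpos,
                                   ref = refb, alt = altb), model, reference)
      if (csq$csq_class == "missense") {
        return(list(contig = model$contig, pos = gpos, ref = refb,
                    alt = altb, gene_id = model$gene_id,
                    csq_class = "missense"))
      }
    }
  }
  stop("failed to engineer a missense variant after ", tries, " tries",
       call. = FALSE)
}

#' Simulate a control cohort and a trio with planted variants
#'
#' Cohort site frequencies follow a U-shaped Beta(0.3, 0.3) spectrum;
#' parents are drawn from those frequencies and the proband inherits one
#' allele from each parent. `Poisson(lambda_dn)` de novo events are added
#' to the proband (each protein-changing with probability
#' `p_protein_changing`, engineered into a CDS), plus
#' `artifact_site_count` proband-homozygous protein-changing sites placed
#' in artifact-prone context (near the intronic assembly gap, inside the
#' coding AT tract, or under a simulated coverage dropout). Optional
#' genotype errors perturb trio calls at `geno_error_rate`. Every emitted
#' variant carries a planted-truth manifest record including its expected
#' cascade fate.
#'
#' @param config a [sim_config()].
#' @param simref matching [simulate_reference()] result.
#' @return List of class `sim_cohort`: `table` (a [variant_table()] with
#'   control and trio samples), `manifest` (data.frame; attributes
#'   `n_dn_drawn`, `flips`, `expected_mendel_errors`), `coverage` (per-base
#'   depth track), `freqs` (named ALT frequencies of cohort sites),
#'   `samples` (list with `proband`, `sire`, `dam`, `controls`).
#' @export
simulate_cohort_and_trio <- function(config, simref) {
  stopifnot(inherits(config, "sim_config"), inherits(simref, "sim_reference"))
  set.seed(config$seed + 1L)
  reference <- simref$reference
  models <- simref$models
  contigs <- names(reference)
  contig_chars <- as.list(as.character(reference))
  clen <- setNames(Biostrings::width(reference), contigs)
  bases <- c("A", "C", "G", "T")

  controls <- sprintf("CTRL%03d", seq_len(config$n_controls))
  samples <- c(controls, TRIO_SAMPLES[["sire"]], TRIO_SAMPLES[["dam"]],
               TRIO_SAMPLES[["proband"]])
  nc <- config$n_controls

  ## --- cohort sites -------------------------------------------------------
  per_contig <- diff(floor(seq(0, config$n_cohort_sites,
                               length.out = length(contigs) + 1)))
  pos_list <- list()
  for (ci in seq_along(contigs)) {
    want <- per_contig[ci]
    draw <- sort(sample.int(clen[ci], min(clen[ci], want * 2L)))
    refb <- toupper(substring(contig_chars[[ci]], draw, draw))
    ok <- refb %in% bases
    keep <- head(which(ok), want)
    pos_list[[ci]] <- data.frame(contig = contigs[ci], pos = draw[keep],
                                 ref = refb[keep])
  }
  sites <- do.call(rbind, pos_list)
  n <- nrow(sites)
  sites$alt <- vapply(sites$ref, function(r) sample(setdiff(bases, r), 1),
                      character(1))
  p <- rbeta(n, 0.3, 0.3)

  draw_mat <- function(ncol) {
    matrix(rbinom(n * ncol, 1L, rep(p, times = ncol)), n, ncol)
  }
  ctrl_a <- draw_mat(nc); ctrl_b <- draw_mat(nc)
  sire_al <- cbind(rbinom(n, 1L, p), rbinom(n, 1L, p))
  dam_al <- cbind(rbinom(n, 1L, p), rbinom(n, 1L, p))
  pro_a <- sire_al[cbind(seq_len(n), sample(1:2, n, replace = TRUE))]
  pro_b <- dam_al[cbind(seq_len(n), sample(1:2, n, replace = TRUE))]

  origin <- rep("cohort", n)
  flavor <- rep(NA_character_, n)
  planted_class <- rep(NA_character_, n)
  planted_pc <- rep(NA, n)
  used <- paste(sites$contig, sites$pos)

  add_site <- function(contig, pos, ref, alt) {
    sites <<- rbind(sites, data.frame(contig = contig, pos = pos, ref = ref,
                                      alt = alt))
    ctrl_a <<- rbind(ctrl_a, rep(0L, nc)); ctrl_b <<- rbind(ctrl_b, rep(0L, nc))
    sire_al <<- rbind(sire_al, c(0L, 0L)); dam_al <<- rbind(dam_al, c(0L, 0L))
    used <<- c(used, paste(contig, pos))
  }

  ## --- de novo events -----------------------------------------------------
  n_dn <- rpois(1, config$lambda_dn)
  dn_pc <- rbinom(n_dn, 1L, config$p_protein_changing) == 1L
  for (k in seq_len(n_dn)) {
    if (dn_pc[k]) {
      repeat {
        m <- models[[sample(length(models), 1)]]
        v <- engineer_missense(m, reference, contig_chars)
        if (!paste(v$contig, v$pos) %in% used) break
      }
      cls <- classify_planted(v$contig, v$pos, v$ref, v$alt, models, reference)
      add_site(v$contig, v$pos, v$ref, v$alt)
      pro_a <- c(pro_a, 0L); pro_b <- c(pro_b, 1L)
      origin <- c(origin, "de_novo"); flavor <- c(flavor, NA)
      planted_class <- c(planted_class, cls$csq_class)
      planted_pc <- c(planted_pc, cls$protein_changing)
    } else {
      repeat {
        ctg <- sample(contigs, 1)
        gpos <- sample.int(clen[ctg], 1)
        refb <- toupper(substr(contig_chars[[ctg]], gpos, gpos))
        if (!refb %in% bases || paste(ctg, gpos) %in% used) next
        altb <- sample(setdiff(bases, refb), 1)
        cls <- classify_planted(ctg, gpos, refb, altb, models, reference)
        if (!cls$protein_changing) break
      }
      add_site(ctg, gpos, refb, altb)
      pro_a <- c(pro_a, 0L); pro_b <- c(pro_b, 1L)
      origin <- c(origin, "de_novo"); flavor <- c(flavor, NA)
      planted_class <- c(planted_class, cls$csq_class)
      planted_pc <- c(planted_pc, cls$protein_changing)
    }
  }

  ## --- artifact-prone homozygous candidates -------------------------------
  flavors <- rep(c("near_gap", "repetitive", "low_coverage"),
                 length.out = config$artifact_site_count)
  low_cov_sites <- list()
  gap_model <- models[[1]]   # carries the intronic gap
  tract_model <- models[[2]] # carries the coding AT tract
  gap_iv <- simref$gaps[simref$gaps$context == "intronic", , drop = FALSE][1, ]
  tract_iv <- simref$tracts[simref$tracts$context == "coding", , drop = FALSE][1, ]
  gap_near <- unlist(Map(seq, cds_segments(gap_model)$start,
                         cds_segments(gap_model)$end))
  gap_near <- gap_near[abs(gap_near - (gap_iv$start + gap_iv$end) / 2) <= 450]
  tract_inner <- seq(tract_iv$start + 110L, tract_iv$end - 110L)

  for (k in seq_along(flavors)) {
    fl <- flavors[k]
    repeat {
      v <- switch(fl,
        near_gap = engineer_missense(gap_model, reference, contig_chars,
                                     allowed_gpos = gap_near),
        repetitive = engineer_missense(tract_model, reference, contig_chars,
                                       allowed_gpos = tract_inner),
        low_coverage = engineer_missense(
          models[[sample(3:length(models), 1)]], reference, contig_chars)
      )
      if (!paste(v$contig, v$pos) %in% used) break
    }
    add_site(v$contig, v$pos, v$ref, v$alt)
    # Artifact context also degrades the parental calls: parents are
    # no-calls at these sites (so they do not inflate the Mendel count).
    sire_al[nrow(sire_al), ] <- NA_integer_
    dam_al[nrow(dam_al), ] <- NA_integer_
    pro_a <- c(pro_a, 1L); pro_b <- c(pro_b, 1L)
    origin <- c(origin, "artifact"); flavor <- c(flavor, fl)
    planted_class <- c(planted_class, "missense")
    planted_pc <- c(planted_pc, TRUE)
    if (fl == "low_coverage") {
      low_cov_sites[[length(low_cov_sites) + 1]] <-
        list(contig = v$contig, pos = v$pos)
    }
  }

  ## --- assemble genotype matrices -----------------------------------------
  ntot <- nrow(sites)
  gt_a <- cbind(ctrl_a, sire_al[, 1], dam_al[, 1], pro_a)
  gt_b <- cbind(ctrl_b, sire_al[, 2], dam_al[, 2], pro_b)
  m_samp <- ncol(gt_a)
  dose <- gt_a + gt_b

  dp <- matrix(rpois(ntot * m_samp, config$depth_mean), ntot, m_samp)
  trio_cols <- (m_samp - 2L):m_samp
  dp[, trio_cols] <- pmax(dp[, trio_cols], 15L)
  ad <- matrix(0L, ntot, m_samp)
  het <- !is.na(dose) & dose == 1L
  ad[het] <- rbinom(sum(het), dp[het], 0.5)
  # Trio het evidence clipped into the admissible band so verdicts depend
  # on genotypes, not depth noise (a well-covered genome).
  for (j in trio_cols) {
    h <- which(het[, j])
    lo <- pmax(5L, ceiling(0.2 * dp[h, j]))
    hi <- pmax(lo, floor(0.8 * dp[h, j]))
    ad[h, j] <- pmin(pmax(ad[h, j], lo), hi)
  }
  hom <- !is.na(dose) & dose == 2L
  ad[hom] <- dp[hom]
  gq <- matrix(99L, ntot, m_samp)

  ## --- genotype errors in the trio ---------------------------------------
  flips <- data.frame(row = integer(0), sample = character(0),
                      from = integer(0), to = integer(0))
  if (config$geno_error_rate > 0) {
    for (j in trio_cols) {
      hit <- which(runif(ntot) < config$geno_error_rate)
      for (i in hit) {
        d0 <- gt_a[i, j] + gt_b[i, j]
        if (is.na(d0)) next
        d1 <- sample(setdiff(0:2, d0), 1)
        gt_a[i, j] <- if (d1 == 2L) 1L else 0L
        gt_b[i, j] <- if (d1 >= 1L) 1L else 0L
        ad[i, j] <- switch(as.character(d1), "0" = 0L,
                           "1" = max(5L, as.integer(dp[i, j] / 2)),
                           "2" = dp[i, j])
        flips <- rbind(flips, data.frame(
          row = i, sample = samples[j], from = d0, to = d1))
      }
    }
    dose <- gt_a + gt_b
  }

  ## --- drop monomorphic cohort rows ---------------------------------------
  poly <- rowSums(dose, na.rm = TRUE) > 0L | origin != "cohort"
  sites <- sites[poly, , drop = FALSE]
  gt_a <- gt_a[poly, , drop = FALSE]; gt_b <- gt_b[poly, , drop = FALSE]
  dp <- dp[poly, , drop = FALSE]; ad <- ad[poly, , drop = FALSE]
  gq <- gq[poly, , drop = FALSE]
  origin <- origin[poly]; flavor <- flavor[poly]
  planted_class <- planted_class[poly]; planted_pc <- planted_pc[poly]
  p_kept <- c(p, rep(NA, ntot - n))[poly]
  dose <- dose[poly, , drop = FALSE]

  table <- variant_table(sites, samples, gt_a, gt_b, dp, ad, gq)
  # variant_table sorts rows; recover the permutation to align the manifest.
  ord <- variant_order(sites)
  origin <- origin[ord]; flavor <- flavor[ord]
  planted_class <- planted_class[ord]; planted_pc <- planted_pc[ord]
  p_kept <- p_kept[ord]
  keys <- variant_keys(table)

  ## --- expected fates ------------------------------------------------------
  d_pro <- genotype_dosage(table, TRIO_SAMPLES[["proband"]])
  d_sire <- genotype_dosage(table, TRIO_SAMPLES[["sire"]])
  d_dam <- genotype_dosage(table, TRIO_SAMPLES[["dam"]])
  panel_dose <- table$gt_a[, seq_len(nc), drop = FALSE] +
    table$gt_b[, seq_len(nc), drop = FALSE]
  n_carriers <- rowSums(!is.na(panel_dose) & panel_dose >= 1L)
  private <- n_carriers == 0L

  # Consequence class for private variants not planted with one.
  need_csq <- which(is.na(planted_pc) & private & !is.na(d_pro) & d_pro >= 1L)
  for (i in need_csq) {
    cls <- classify_planted(table$variants$contig[i], table$variants$pos[i],
                            table$variants$ref[i], table$variants$alt[i],
                            models, reference)
    planted_class[i] <- cls$csq_class
    planted_pc[i] <- cls$protein_changing
  }

  fate <- rep("not_in_branch", length(keys))
  in_hom <- !is.na(d_pro) & d_pro == 2L
  in_het <- !is.na(d_pro) & d_pro == 1L
  fate[(in_hom | in_het) & !private] <- "removed_private"
  sel <- (in_hom | in_het) & private
  fate[sel & !(planted_pc %in% TRUE)] <- "removed_protein_changing"
  fate[in_hom & private & planted_pc %in% TRUE] <- "survives_homozygous"
  fate[in_het & private & planted_pc %in% TRUE] <- "survives_heterozygous"

  verdict <- rep(NA_character_, length(keys))
  hs <- fate == "survives_heterozygous"
  verdict[hs & (d_sire >= 1L | d_dam >= 1L)] <- "inherited"
  verdict[hs & d_sire == 0L & d_dam == 0L] <- "de_novo"

  manifest <- data.frame(
    key = keys,
    contig = table$variants$contig, pos = table$variants$pos,
    ref = table$variants$ref, alt = table$variants$alt,
    origin = origin, artifact_flavor = flavor,
    csq_class = planted_class, protein_changing = planted_pc,
    cohort_freq = p_kept,
    proband_dosage = d_pro, sire_dosage = d_sire, dam_dosage = d_dam,
    n_panel_carriers = n_carriers, private = private,
    expected_fate = fate, expected_verdict = verdict,
    stringsAsFactors = FALSE
  )
  mend <- mapply(mendel_site_verdict, d_pro, d_sire, d_dam)
  attr(manifest, "n_dn_drawn") <- n_dn
  attr(manifest, "flips") <- flips
  attr(manifest, "expected_mendel_errors") <- sum(mend == "error")

  ## --- coverage track ------------------------------------------------------
  coverage <- lapply(setNames(contigs, contigs), function(ctg) {
    rep(as.integer(config$depth_mean), clen[ctg])
  })
  for (s in low_cov_sites) {
    i0 <- max(1L, s$pos - 40L); i1 <- min(clen[s$contig], s$pos + 40L)
    coverage[[s$contig]][i0:i1] <- 2L
  }

  freqs <- setNames(p_kept, keys)
  structure(list(
    table = table, manifest = manifest, coverage = coverage,
    freqs = freqs,
    samples = list(proband = TRIO_SAMPLES[["proband"]],
                   sire = TRIO_SAMPLES[["sire"]],
                   dam = TRIO_SAMPLES[["dam"]], controls = controls)
  ), class = "sim_cohort")
}

#' Simulate trio microsatellite genotypes
#'
#' Parental allele lengths are drawn from per-locus pools; the child
#' inherits one allele from each parent. `error_loci` loci are corrupted so
#' the child's alleles cannot have been transmitted (to exercise
#' [check_microsat_transmission()]).
#'
#' @param config a [sim_config()] (only the seed is used).
#' @param n_loci number of loci (the standard multiplex uses 7).
#' @param error_loci number of loci corrupted to break transmission.
#' @return A `microsat_table` for samples PROBAND/SIRE/DAM.
#' @export
simulate_microsats <- function(config, n_loci = 7, error_loci = 0) {
  stopifnot(n_loci >= 1, error_loci <= n_loci)
  set.seed(config$seed + 2L)
  rows <- list()
  bad <- if (error_loci > 0) sample(n_loci, error_loci) else integer(0)
  for (l in seq_len(n_loci)) {
    locus <- sprintf("MS%02d", l)
    pool <- 100L + 10L * l + 2L * (0:7)
    sire <- sample(pool, 2, replace = TRUE)
    dam <- sample(pool, 2, replace = TRUE)
    child <- c(sample(sire, 1), sample(dam, 1))
    if (l %in% bad) child <- max(pool) + c(3L, 5L)
    rows[[l]] <- data.frame(
      locus = locus,
      sample = c(TRIO_SAMPLES[["sire"]], TRIO_SAMPLES[["dam"]],
                 TRIO_SAMPLES[["proband"]]),
      allele1 = c(sire[1], dam[1], child[1]),
      allele2 = c(sire[2], dam[2], child[2])
    )
  }
  structure(do.call(rbind, rows), class = c("microsat_table", "data.frame"))
}

#' Run the full simulator
#'
#' Convenience wrapper: reference + cohort/trio + microsatellites.
#' @param config a [sim_config()].
#' @return List with `reference` (a `sim_reference`), `cohort` (a
#'   `sim_cohort`) and `microsats`.
#' @export
simulate_all <- function(config = sim_config()) {
  simref <- simulate_reference(config)
  cohort <- simulate_cohort_and_trio(config, simref)
  ms <- simulate_microsats(config)
  list(reference = simref, cohort = cohort, microsats = ms)
}
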