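#' Strand-aware transcript model
#'
#' Exon/CDS structure of one mRNA, stored in genomic coordinates (1-based
#' inclusive, exons sorted and non-overlapping regardless of strand);
#' orientation is applied at coordinate-mapping time. The CDS spans
#' `[cds_start, cds_end]` genomically and its exonic length must be a
#' positive multiple of 3.
#'
#' @param transcript_id,gene_id identifiers.
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (genomic, 1-based
#'   inclusive).
#' @param cds_start,cds_end genomic bounds of the translated region.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, contig, strand,
                             exons, cds_start, cds_end) {
  stopifnot(strand %in% c("+", "-"),
            is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  rownames(exons) <- NULL
  if (any(exons$end < exons$start)) stop("exon end before start")
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("exons overlap in transcript ", transcript_id)
  }
  model <- structure(list(
    transcript_id = transcript_id, gene_id = gene_id, contig = contig,
    strand = strand, exons = exons,
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end)
  ), class = "transcript_model")
  len <- sum(with(cds_segments(model), end - start + 1L))
  if (len <= 0 || len %% 3L != 0L) {
    stop("CDS length ", len, " of transcript ", transcript_id,
         " is not a positive multiple of 3", call. = FALSE)
  }
  model
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model> ", x$transcript_id, " (", x$gene_id, ") ",
      x$contig, ":", min(x$exons$start), "-", max(x$exons$end), " (", x$strand,
      "), ", nrow(x$exons), " exon(s), CDS ", x$cds_start, "-", x$cds_end,
      "\n", sep = "")
  invisible(x)
}

#' Genomic CDS segments of a transcript
#'
#' Intersection of the exons with `[cds_start, cds_end]`, in genomic order.
#' @param model a [transcript_model()].
#' @return data.frame with columns `start`, `end`.
#' @export
cds_segments <- function(model) {
  s <- pmax(model$exons$start, model$cds_start)
  e <- pmin(model$exons$end, model$cds_end)
  keep <- e >= s
  data.frame(start = s[keep], end = e[keep])
}

transcript_span <- function(model) {
  c(start = min(model$exons$start), end = max(model$exons$end))
}

#' Spliced coding sequence of a transcript
#'
#' Concatenates the CDS segments in genomic order and reverse-complements
#' the result for minus-strand models, yielding the mRNA-sense CDS.
#' @param model a [transcript_model()].
#' @param reference [Biostrings::DNAStringSet] named by contig.
#' @return Uppercase character string.
#' @export
cds_sequence <- function(model, reference) {
  seg <- cds_segments(model)
  s <- paste(vapply(seq_len(nrow(seg)), function(i) {
    ref_subseq(reference, model$contig, seg$start[i], seg$end[i])
  }, character(1)), collapse = "")
  s <- toupper(s)
  if (model$strand == "-") s <- revcomp(s)
  s
}

#' Read transcript models from a GFF3 file
#'
#' Imports gene/mRNA/exon/CDS features (via \pkg{rtracklayer}) and builds
#' one [transcript_model()] per mRNA. Models whose CDS length is not a
#' positive multiple of 3 are rejected with a message; CDS features whose
#' parent is not an imported mRNA are skipped with a warning. When a
#' reference is supplied, each model's translated CDS is checked for a
#' leading start codon and trailing stop codon (warn, not fail).
#'
#' @param path_gff path to a GFF3 file.
#' @param reference optional [Biostrings::DNAStringSet] for start/stop
#'   validation.
#' @return List of [transcript_model()] objects.
#' @export
read_transcripts <- function(path_gff, reference = NULL) {
  gr <- rtracklayer::import(path_gff)
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(as.list(gr$Parent), function(p) {
    if (length(p) == 0) NA_character_ else p[[1]]
  }, character(1))

  is_mrna <- type %in% c("mRNA", "transcript")
  mrna_ids <- ids[is_mrna]

  orphan <- type == "CDS" & !(parents %in% mrna_ids)
  if (any(orphan)) {
    warning(sum(orphan), " CDS feature(s) without an mRNA parent skipped",
            call. = FALSE)
  }

  models <- list()
  for (i in which(is_mrna)) {
    tx_id <- ids[i]
    gene_id <- parents[i] %||% NA_character_
    sel_ex <- type == "exon" & parents == tx_id
    sel_cds <- type == "CDS" & parents == tx_id
    if (!any(sel_cds)) next
    exons <- data.frame(start = GenomicRanges::start(gr[sel_ex]),
                        end = GenomicRanges::end(gr[sel_ex]))
    if (nrow(exons) == 0) {
      exons <- data.frame(start = GenomicRanges::start(gr[sel_cds]),
                          end = GenomicRanges::end(gr[sel_cds]))
    }
    m <- tryCatch(
      transcript_model(
        transcript_id = tx_id,
        gene_id = if (is.na(gene_id)) tx_id else gene_id,
        contig = as.character(GenomicRanges::seqnames(gr[i])),
        strand = as.character(GenomicRanges::strand(gr[i])),
        exons = exons,
        cds_start = min(GenomicRanges::start(gr[sel_cds])),
        cds_end = max(GenomicRanges::end(gr[sel_cds]))
      ),
      error = function(e) {
        message("transcript ", tx_id, " rejected: ", conditionMessage(e))
        NULL
      }
    )
    if (is.null(m)) next
    if (!is.null(reference)) {
      cds <- cds_sequence(m, reference)
      first <- substr(cds, 1, 3)
      last <- substr(cds, nchar(cds) - 2, nchar(cds))
      if (first != "ATG") {
        warning("transcript ", tx_id, " does not begin with a start codon",
                call. = FALSE)
      }
      if (!last %in% STOP_CODONS) {
        warning("transcript ", tx_id, " does not end with a stop codon",
                call. = FALSE)
      }
    }
    models[[length(models) + 1]] <- m
  }
  models
}

#' Write transcript models as GFF3
#'
#' Emits gene, mRNA, exon and CDS features (with phase) via
#' \pkg{rtracklayer}, in the parent/child layout [read_transcripts()]
#' consumes.
#'
#' @param models list of [transcript_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  rows <- list()
  add <- function(contig, start, end, strand, type, id, parent, phase = NA_integer_) {
    rows[[length(rows) + 1]] <<- data.frame(
      contig = contig, start = start, end = end, strand = strand,
      type = type, ID = id, Parent = if (is.null(parent)) NA_character_ else parent,
      phase = phase, stringsAsFactors = FALSE)
  }
  for (m in models) {
    span <- transcript_span(m)
    add(m$contig, span["start"], span["end"], m$strand, "gene", m$gene_id, NULL)
    add(m$contig, span["start"], span["end"], m$strand, "mRNA",
        m$transcript_id, m$gene_id)
    for (i in seq_len(nrow(m$exons))) {
      add(m$contig, m$exons$start[i], m$exons$end[i], m$strand, "exon",
          paste0(m$transcript_id, ":exon", i), m$transcript_id)
    }
    seg <- cds_segments(m)
    # Phase: bases to skip before the first complete codon of each segment,
    # accumulated in translation order.
    ord <- if (m$strand == "+") seq_len(nrow(seg)) else rev(seq_len(nrow(seg)))
    cum <- 0L
    phase <- integer(nrow(seg))
    for (i in ord) {
      phase[i] <- (3L - (cum %% 3L)) %% 3L
      cum <- cum + seg$end[i] - seg$start[i] + 1L
    }
    for (i in seq_len(nrow(seg))) {
      add(m$contig, seg$start[i], seg$end[i], m$strand, "CDS",
          paste0(m$transcript_id, ":cds", i), m$transcript_id, phase[i])
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand
  )
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(df$Parent, function(p) if (is.na(p)) character(0) else p))
  S4Vectors::mcols(gr)$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
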