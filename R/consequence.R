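# Bespoke coding-consequence annotation: genomic -> CDS -> codon mapping,
# HGVS c./p. rendering, and protein-changing classification.

# Consequence classes considered protein-changing. The splice-site class
# covers the +/-2 intronic bases at each exon-intron junction.
PROTEIN_CHANGING_CLASSES <- c(
  "missense", "stop_gain", "stop_loss", "start_loss",
  "frameshift", "inframe_indel", "splice_site"
)

#' Map a genomic position onto a transcript's coding sequence
#'
#' Strand-aware: on the minus strand coding position 1 is the genomically
#' rightmost CDS base. Positions inside the transcript span but outside the
#' CDS are classified as `"intron"` or `"utr"`; intronic positions carry the
#' distance to the nearest exon boundary. Positions outside the span (or on
#' another contig) are `"intergenic"`.
#'
#' @param pos genomic position, 1-based.
#' @param model a [transcript_model()].
#' @param contig optional contig of the query; defaults to the model's.
#' @return List with `type` (`"cds"`, `"utr"`, `"intron"`, `"intergenic"`),
#'   `cds_pos` (1-based, NA unless `type == "cds"`) and `splice_dist`
#'   (bases into the intron from the nearest exon edge, NA unless intronic).
#' @export
map_genomic_to_cds <- function(pos, model, contig = NULL) {
  res <- list(type = "intergenic", cds_pos = NA_integer_,
              splice_dist = NA_integer_)
  if (!is.null(contig) && contig != model$contig) return(res)
  span <- transcript_span(model)
  if (pos < span["start"] || pos > span["end"]) return(res)

  ex <- model$exons
  in_exon <- any(pos >= ex$start & pos <= ex$end)
  if (!in_exon) {
    # Intron: distance to nearest flanking exon edge (1 = first intronic base).
    d_left <- pos - ex$end[ex$end < pos]
    d_right <- ex$start[ex$start > pos] - pos
    res$type <- "intron"
    res$splice_dist <- min(c(d_left, d_right))
    return(res)
  }
  seg <- cds_segments(model)
  hit <- which(pos >= seg$start & pos <= seg$end)
  if (length(hit) == 0) {
    res$type <- "utr"
    return(res)
  }
  lens <- seg$end - seg$start + 1L
  before <- if (hit > 1) sum(lens[seq_len(hit - 1)]) else 0L
  p_plus <- before + (pos - seg$start[hit]) + 1L
  total <- sum(lens)
  res$type <- "cds"
  res$cds_pos <- if (model$strand == "+") p_plus else total - p_plus + 1L
  res
}

#' Codon address of a coding position
#'
#' @param cds_pos 1-based position within the coding sequence (vectorised).
#' @return List with `codon_index` (1-based) and `offset` (0-based position
#'   within the codon, 0..2), satisfying
#'   `cds_pos == 3 * (codon_index - 1) + offset + 1`.
#' @export
cds_to_codon <- function(cds_pos) {
  stopifnot(all(cds_pos >= 1))
  list(codon_index = as.integer(ceiling(cds_pos / 3)),
       offset = as.integer((cds_pos - 1) %% 3))
}

blank_csq <- function(model, class, pc = FALSE) {
  data.frame(
    transcript_id = if (is.null(model)) NA_character_ else model$transcript_id,
    gene_id = if (is.null(model)) NA_character_ else model$gene_id,
    csq_class = class, hgvs_c = "", hgvs_p = "",
    protein_changing = pc, cds_pos = NA_integer_, codon_index = NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Annotate one variant against one transcript model
#'
#' For coding SNVs the affected codon is extracted from the spliced CDS, the
#' strand-corrected alternate base substituted, and both codons translated
#' with the standard genetic code; HGVS is rendered as `c.{pos}{REF}>{ALT}`
#' (transcript-strand alleles) and `p.(Xaa{idx}Yaa)` with three-letter
#' codes. Intronic variants within 2 bases of an exon--intron junction are
#' `splice_site`. CDS indels are `frameshift` when the length change is not
#' a multiple of 3, else `inframe_indel` (no HGVS indel nomenclature is
#' attempted). Codons containing ambiguity bases yield class
#' `"unresolvable"`, never protein-changing.
#'
#' @param variant single-row data.frame (or list) with `contig`, `pos`,
#'   `ref`, `alt`.
#' @param model a [transcript_model()].
#' @param reference [Biostrings::DNAStringSet]; the variant's REF allele is
#'   verified against it (data-integrity error on mismatch).
#' @return One-row data.frame: `transcript_id`, `gene_id`, `csq_class`,
#'   `hgvs_c`, `hgvs_p`, `protein_changing`, `cds_pos`, `codon_index`.
#' @export
annotate_variant <- function(variant, model, reference) {
  pos <- as.integer(variant$pos)
  refa <- toupper(variant$ref); alta <- toupper(variant$alt)
  obs <- toupper(ref_subseq(reference, variant$contig, pos,
                            pos + nchar(refa) - 1L))
  if (obs != refa) {
    stop("REF mismatch at ", variant$contig, ":", pos,
         " (expected ", refa, ", reference has ", obs, ")", call. = FALSE)
  }

  loc <- map_genomic_to_cds(pos, model, contig = variant$contig)
  is_snv <- nchar(refa) == 1 && nchar(alta) == 1

  if (loc$type == "intergenic") return(blank_csq(model, "intergenic"))
  if (loc$type == "intron") {
    if (loc$splice_dist <= 2) {
      out <- blank_csq(model, "splice_site", pc = TRUE)
      return(out)
    }
    return(blank_csq(model, "non_coding"))
  }
  if (loc$type == "utr") return(blank_csq(model, "non_coding"))

  # Coding.
  if (!is_snv) {
    delta <- nchar(alta) - nchar(refa)
    cls <- if (delta %% 3L != 0L) "frameshift" else "inframe_indel"
    out <- blank_csq(model, cls, pc = TRUE)
    out$cds_pos <- loc$cds_pos
    out$codon_index <- cds_to_codon(loc$cds_pos)$codon_index
    return(out)
  }

  cds <- cds_sequence(model, reference)
  cds_pos <- loc$cds_pos
  addr <- cds_to_codon(cds_pos)
  ci <- addr$codon_index
  codon_ref <- substr(cds, 3L * (ci - 1L) + 1L, 3L * ci)
  tx_ref <- if (model$strand == "+") refa else complement_base(refa)
  tx_alt <- if (model$strand == "+") alta else complement_base(alta)
  stopifnot(substr(cds, cds_pos, cds_pos) == tx_ref)
  codon_alt <- codon_ref
  substr(codon_alt, addr$offset + 1L, addr$offset + 1L) <- tx_alt

  if (grepl("[^ACGT]", codon_ref) || grepl("[^ACGT]", codon_alt)) {
    return(blank_csq(model, "unresolvable"))
  }
  aa_ref <- translate_codon(codon_ref)
  aa_alt <- translate_codon(codon_alt)

  cls <- if (ci == 1L && codon_ref == "ATG" && codon_alt != "ATG") {
    "start_loss"
  } else if (aa_ref == "*" && aa_alt != "*") {
    "stop_loss"
  } else if (aa_ref != "*" && aa_alt == "*") {
    "stop_gain"
  } else if (aa_ref == aa_alt) {
    "synonymous"
  } else {
    "missense"
  }
  pc <- cls %in% PROTEIN_CHANGING_CLASSES
  hgvs_c <- paste0("c.", cds_pos, tx_ref, ">", tx_alt)
  hgvs_p <- if (cls %in% c("missense", "stop_gain", "stop_loss", "start_loss")) {
    paste0("p.(", aa_three(aa_ref), ci, aa_three(aa_alt), ")")
  } else ""
  data.frame(transcript_id = model$transcript_id, gene_id = model$gene_id,
             csq_class = cls, hgvs_c = hgvs_c, hgvs_p = hgvs_p,
             protein_changing = pc, cds_pos = cds_pos, codon_index = ci,
             stringsAsFactors = FALSE)
}

#' Annotate every variant in a table against overlapping transcripts
#'
#' Each variant is annotated against every model whose span it overlaps;
#' variants overlapping no model receive a single `intergenic` row. For
#' downstream filtering a variant counts as protein-changing iff *any*
#' overlapping transcript yields a protein-changing consequence
#' (any-transcript rule).
#'
#' @param table a [variant_table()].
#' @param models list of [transcript_model()] objects.
#' @param reference [Biostrings::DNAStringSet].
#' @return data.frame with one row per (variant, consequence): `key`,
#'   `contig`, `pos`, `ref`, `alt` plus the [annotate_variant()] columns.
#' @export
annotate_all <- function(table, models, reference) {
  v <- table$variants
  keys <- variant_keys(table)
  empty <- data.frame(
    key = character(0), contig = character(0), pos = integer(0),
    ref = character(0), alt = character(0), transcript_id = character(0),
    gene_id = character(0), csq_class = character(0), hgvs_c = character(0),
    hgvs_p = character(0), protein_changing = logical(0),
    cds_pos = integer(0), codon_index = integer(0), stringsAsFactors = FALSE)
  if (nrow(v) == 0) return(empty)

  hit_models <- vector("list", nrow(v))
  for (m in models) {
    span <- transcript_span(m)
    idx <- which(v$contig == m$contig & v$pos >= span["start"] &
                   v$pos <= span["end"])
    for (i in idx) hit_models[[i]] <- c(hit_models[[i]], list(m))
  }
  rows <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    ms <- hit_models[[i]]
    if (is.null(ms)) {
      csq <- blank_csq(NULL, "intergenic")
    } else {
      csq <- do.call(rbind, lapply(ms, function(m) {
        annotate_variant(v[i, ], m, reference)
      }))
    }
    rows[[i]] <- cbind(
      data.frame(key = keys[i], contig = v$contig[i], pos = v$pos[i],
                 ref = v$ref[i], alt = v$alt[i], stringsAsFactors = FALSE),
      csq)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Protein-changing status per variant under the any-transcript rule
#'
#' @param annotations output of [annotate_all()].
#' @return Named logical vector keyed by variant key.
#' @export
protein_changing_any <- function(annotations) {
  tapply(annotations$protein_changing, annotations$key, any)
}

#' Subset a table to variants overlapping a gene set
#'
#' Returns all variants (any consequence class, including non-coding) whose
#' position falls within the genomic span of any transcript of a listed
#' gene -- the candidate-gene exclusion screen. Unknown gene ids are skipped
#' with a warning.
#'
#' @param table a [variant_table()].
#' @param models list of [transcript_model()] objects.
#' @param gene_ids non-empty character vector of gene identifiers.
#' @return A [variant_table()] subset.
#' @export
screen_gene_set <- function(table, models, gene_ids) {
  stopifnot(length(gene_ids) > 0)
  known <- unique(vapply(models, `[[`, character(1), "gene_id"))
  unknown <- setdiff(gene_ids, known)
  if (length(unknown) > 0) {
    warning("unknown gene id(s) skipped: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  v <- table$variants
  keep <- rep(FALSE, nrow(v))
  for (m in models) {
    if (!m$gene_id %in% gene_ids) next
    span <- transcript_span(m)
    keep <- keep | (v$contig == m$contig & v$pos >= span["start"] &
                      v$pos <= span["end"])
  }
  subset_variants(table, keep)
}

#' Write an annotation table as TSV
#'
#' @param annotations output of [annotate_all()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  cols <- c("contig", "pos", "ref", "alt", "gene_id", "transcript_id",
            "csq_class", "hgvs_c", "hgvs_p", "protein_changing")
  write.table(annotations[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
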