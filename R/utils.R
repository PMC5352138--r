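# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert 1-based inclusive coordinates to 0-based half-open, and back
#'
#' All on-disk coordinates (VCF, GFF3) are 1-based inclusive; internal
#' interval arithmetic is 0-based half-open. These two functions are the
#' single point of conversion.
#'
#' @param start,end 1-based inclusive interval bounds.
#' @return `to_halfopen()`: list with `start0` (0-based) and `end0`
#'   (exclusive). `to_onebased()`: list with `start` and `end` (1-based
#'   inclusive).
#' @keywords internal
to_halfopen <- function(start, end) list(start0 = start - 1L, end0 = end)

#' @rdname to_halfopen
#' @param start0,end0 0-based half-open interval bounds.
#' @keywords internal
to_onebased <- function(start0, end0) list(start = start0 + 1L, end = end0)

# Three-letter amino-acid codes, HGVS style ("*" renders as Ter).
AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Ter"
)

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Translate a single codon with the standard genetic code. Codons containing
# ambiguity bases return NA.
translate_codon <- function(codon) {
  codon <- toupper(codon)
  aa <- Biostrings::GENETIC_CODE[codon]
  unname(aa)
}

aa_three <- function(aa) unname(AA_THREE[aa])

# Reverse complement of a plain character string (ACGTN, case preserved as
# upper).
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan", x)
}

# Extract a 1-based inclusive subsequence from a reference. The reference
# is a DNAStringSet or a named character vector; only the character form
# preserves soft-masking case (Biostrings stores bases uppercased).
ref_subseq <- function(reference, contig, start, end) {
  if (!contig %in% names(reference)) {
    stop("contig '", contig, "' not present in reference", call. = FALSE)
  }
  len <- contig_length(reference, contig)
  start <- max(1L, start)
  end <- min(len, end)
  if (end < start) return("")
  if (is.character(reference)) {
    substr(reference[[contig]], start, end)
  } else {
    as.character(Biostrings::subseq(reference[[contig]], start, end))
  }
}

contig_length <- function(reference, contig) {
  if (!contig %in% names(reference)) return(NA_integer_)
  if (is.character(reference)) nchar(reference[[contig]])
  else length(reference[[contig]])
}

# Deterministic sort order for variants: (contig, pos, ref, alt), C locale.
variant_order <- function(df) {
  order(df$contig, df$pos, df$ref, df$alt, method = "radix")
}
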