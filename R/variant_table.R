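#' In-memory multi-sample genotype table
#'
#' The canonical container the whole pipeline operates on: an ordered set of
#' biallelic variants plus per-sample genotype records. Allele calls are
#' stored as two integer matrices (`gt_a`, `gt_b`; 0 = REF, 1 = ALT, NA =
#' missing) alongside depth (`dp`), alt-supporting depth (`ad`) and genotype
#' quality (`gq`) matrices, all with one row per variant and one column per
#' sample. Rows are always sorted by (contig, pos, ref, alt); genotypes are
#' normalised so `gt_a <= gt_b` and missingness is diploid (both alleles NA
#' or neither).
#'
#' @param variants data.frame with columns `contig` (character), `pos`
#'   (1-based integer), `ref`, `alt` (non-empty uppercase allele strings,
#'   `alt != ref`).
#' @param samples character vector of sample identifiers.
#' @param gt_a,gt_b integer matrices of first/second allele calls.
#' @param dp,ad,gq integer matrices of total depth, alt depth and genotype
#'   quality; default all-zero.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(variants, samples, gt_a, gt_b,
                          dp = NULL, ad = NULL, gq = NULL) {
  stopifnot(is.data.frame(variants),
            all(c("contig", "pos", "ref", "alt") %in% names(variants)))
  n <- nrow(variants)
  m <- length(samples)
  zero <- function(x) {
    if (is.null(x)) x <- matrix(0L, n, m)
    x <- matrix(as.integer(x), n, m)
    x
  }
  as_gt <- function(x) matrix(as.integer(x), n, m)
  gt_a <- as_gt(gt_a); gt_b <- as_gt(gt_b)
  dp <- zero(dp); ad <- zero(ad); gq <- zero(gq)

  variants$contig <- as.character(variants$contig)
  variants$pos <- as.integer(variants$pos)
  variants$ref <- toupper(as.character(variants$ref))
  variants$alt <- toupper(as.character(variants$alt))
  rownames(variants) <- NULL

  if (n > 0) {
    if (any(variants$pos < 1L)) stop("variant positions must be >= 1")
    if (any(!nzchar(variants$ref)) || any(!nzchar(variants$alt))) {
      stop("ref and alt alleles must be non-empty")
    }
    if (any(variants$ref == variants$alt)) stop("alt must differ from ref")
  }

  # Diploid missingness: one NA allele implies both.
  half_missing <- xor(is.na(gt_a), is.na(gt_b))
  if (any(half_missing)) {
    gt_a[half_missing] <- NA_integer_
    gt_b[half_missing] <- NA_integer_
  }
  # Normalise allele order (phase is ignored throughout).
  swap <- !is.na(gt_a) & !is.na(gt_b) & gt_a > gt_b
  if (any(swap)) {
    tmp <- gt_a[swap]; gt_a[swap] <- gt_b[swap]; gt_b[swap] <- tmp
  }
  if (any(ad > dp, na.rm = TRUE)) stop("alt_depth exceeds total_depth")

  ord <- variant_order(variants)
  x <- structure(list(
    variants = variants[ord, , drop = FALSE],
    samples = as.character(samples),
    gt_a = gt_a[ord, , drop = FALSE],
    gt_b = gt_b[ord, , drop = FALSE],
    dp = dp[ord, , drop = FALSE],
    ad = ad[ord, , drop = FALSE],
    gq = gq[ord, , drop = FALSE]
  ), class = "variant_table")
  rownames(x$variants) <- NULL
  for (f in c("gt_a", "gt_b", "dp", "ad", "gq")) {
    dimnames(x[[f]]) <- list(NULL, x$samples)
  }
  x
}

#' @export
print.variant_table <- function(x, ...) {
  cat("<variant_table> ", n_variants(x), " variants x ",
      length(x$samples), " samples\n", sep = "")
  if (n_variants(x) > 0) {
    print(utils::head(x$variants, 5))
    if (n_variants(x) > 5) cat("...\n")
  }
  invisible(x)
}

#' Number of variants in a table
#' @param table a [variant_table()].
#' @export
n_variants <- function(table) nrow(table$variants)

#' Canonical variant keys
#'
#' `"contig:pos:ref:alt"` strings identifying each row; used to join tables,
#' annotations, panels and manifests.
#' @param table a [variant_table()].
#' @export
variant_keys <- function(table) {
  with(table$variants, paste(contig, pos, ref, alt, sep = ":"))
}

#' Row-subset a variant table
#' @param table a [variant_table()].
#' @param idx logical or integer row index.
#' @export
subset_variants <- function(table, idx) {
  variant_table(table$variants[idx, , drop = FALSE], table$samples,
                table$gt_a[idx, , drop = FALSE], table$gt_b[idx, , drop = FALSE],
                table$dp[idx, , drop = FALSE], table$ad[idx, , drop = FALSE],
                table$gq[idx, , drop = FALSE])
}

sample_col <- function(table, sample) {
  j <- match(sample, table$samples)
  if (is.na(j)) stop("sample '", sample, "' not present in table", call. = FALSE)
  j
}

#' Genotype dosage of one sample
#'
#' ALT allele count per variant (0, 1, 2 or NA for missing calls).
#' @param table a [variant_table()].
#' @param sample sample identifier.
#' @export
genotype_dosage <- function(table, sample) {
  j <- sample_col(table, sample)
  table$gt_a[, j] + table$gt_b[, j]
}

#' Verify REF alleles against a reference sequence
#'
#' Checks the two attachment invariants: every variant fits on its contig and
#' its REF allele matches the reference bases at `[pos, pos + nchar(ref) - 1]`
#' (case-insensitive; the reference may be soft-masked).
#'
#' @param table a [variant_table()].
#' @param reference a [Biostrings::DNAStringSet] named by contig.
#' @return Invisibly `TRUE`; stops with a data-integrity error naming the
#'   offending `contig:pos` otherwise.
#' @export
check_reference_match <- function(table, reference) {
  v <- table$variants
  for (i in seq_len(nrow(v))) {
    len <- contig_length(reference, v$contig[i])
    if (is.na(len)) {
      stop("contig '", v$contig[i], "' absent from reference", call. = FALSE)
    }
    end <- v$pos[i] + nchar(v$ref[i]) - 1L
    if (end > len) {
      stop("variant at ", v$contig[i], ":", v$pos[i],
           " extends beyond contig end", call. = FALSE)
    }
    obs <- toupper(ref_subseq(reference, v$contig[i], v$pos[i], end))
    if (obs != v$ref[i]) {
      stop("REF mismatch at ", v$contig[i], ":", v$pos[i],
           " (expected ", v$ref[i], ", reference has ", obs, ")",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
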