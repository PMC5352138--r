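#' Read a VCF file into a variant table
#'
#' Reads a VCF 4.x file (via \pkg{vcfR}), decomposes multiallelic rows into
#' biallelic records and extracts GT plus the optional DP/AD/GQ FORMAT
#' fields. For a decomposed record, genotype alleles equal to the record's
#' ALT become ALT, reference alleles stay REF, and any allele referencing a
#' *different* ALT renders the whole diploid call missing for that record.
#' Missing DP/AD/GQ fields default to 0 (one warning per file per field).
#' Total depth is taken from DP when present, otherwise from the sum of AD.
#'
#' Contig names are matched by exact string equality throughout the package
#' (no "chr" aliasing).
#'
#' @param path path to a VCF file.
#' @param sample_subset optional character vector restricting (and ordering)
#'   the samples kept; an absent sample is an error naming it.
#' @return A [variant_table()].
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcfR::getFIX(vcf)
  all_samples <- colnames(vcf@gt)[-1]
  if (is.null(all_samples)) all_samples <- character(0)
  samples <- sample_subset %||% all_samples
  missing <- setdiff(samples, all_samples)
  if (length(missing) > 0) {
    stop("sample(s) not present in '", path, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  if (is.null(fix) || nrow(fix) == 0) {
    return(variant_table(
      data.frame(contig = character(0), pos = integer(0),
                 ref = character(0), alt = character(0)),
      samples, matrix(integer(0), 0, length(samples)),
      matrix(integer(0), 0, length(samples))))
  }

  grab <- function(element, as.numeric = FALSE) {
    tryCatch(
      vcfR::extract.gt(vcf, element = element, as.numeric = as.numeric),
      error = function(e) NULL
    )
  }
  gt_raw <- grab("GT")
  if (is.null(gt_raw)) stop("VCF '", path, "' has no GT field", call. = FALSE)
  dp_raw <- grab("DP", as.numeric = TRUE)
  ad_raw <- grab("AD")
  gq_raw <- grab("GQ", as.numeric = TRUE)
  for (f in c("DP", "AD", "GQ")) {
    raw <- switch(f, DP = dp_raw, AD = ad_raw, GQ = gq_raw)
    if (is.null(raw) || all(is.na(raw))) {
      warning("VCF '", path, "' lacks ", f, "; defaulting to 0", call. = FALSE)
    }
  }
  keep_j <- match(samples, all_samples)

  contig <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- toupper(fix[, "REF"])
  alt_field <- fix[, "ALT"]
  alts <- strsplit(ifelse(is.na(alt_field), "", alt_field), ",", fixed = TRUE)

  out <- list()
  for (i in seq_along(pos)) {
    row_alts <- toupper(alts[[i]])
    row_alts <- row_alts[nzchar(row_alts) & row_alts != "." & row_alts != "*"]
    gt_row <- gt_raw[i, keep_j]
    dp_row <- if (is.null(dp_raw)) rep(NA_real_, length(keep_j)) else dp_raw[i, keep_j]
    ad_row <- if (is.null(ad_raw)) rep(NA_character_, length(keep_j)) else ad_raw[i, keep_j]
    gq_row <- if (is.null(gq_raw)) rep(NA_real_, length(keep_j)) else gq_raw[i, keep_j]
    ad_split <- lapply(ad_row, function(s) {
      if (is.na(s)) return(NULL)
      suppressWarnings(as.integer(strsplit(s, ",", fixed = TRUE)[[1]]))
    })
    for (k in seq_along(row_alts)) {
      a <- b <- integer(length(keep_j))
      ad_k <- dp_k <- integer(length(keep_j))
      for (s in seq_along(keep_j)) {
        al <- parse_gt_alleles(gt_row[s])
        if (length(al) != 2 || anyNA(al) || any(!al %in% c(0L, k))) {
          a[s] <- NA_integer_; b[s] <- NA_integer_
        } else {
          a[s] <- as.integer(al[1] == k); b[s] <- as.integer(al[2] == k)
        }
        ads <- ad_split[[s]]
        ad_k[s] <- if (!is.null(ads) && length(ads) >= k + 1 && !is.na(ads[k + 1])) {
          ads[k + 1]
        } else 0L
        dp_k[s] <- if (!is.na(dp_row[s])) {
          as.integer(dp_row[s])
        } else if (!is.null(ads) && !anyNA(ads)) {
          sum(ads)
        } else 0L
      }
      out[[length(out) + 1]] <- list(
        contig = contig[i], pos = pos[i], ref = ref[i], alt = row_alts[k],
        a = a, b = b, dp = dp_k, ad = pmin(ad_k, dp_k),
        gq = ifelse(is.na(gq_row), 0L, as.integer(gq_row))
      )
    }
  }
  if (length(out) == 0) {
    return(variant_table(
      data.frame(contig = character(0), pos = integer(0),
                 ref = character(0), alt = character(0)),
      samples, matrix(integer(0), 0, length(samples)),
      matrix(integer(0), 0, length(samples))))
  }
  variants <- data.frame(
    contig = vapply(out, `[[`, character(1), "contig"),
    pos = vapply(out, `[[`, integer(1), "pos"),
    ref = vapply(out, `[[`, character(1), "ref"),
    alt = vapply(out, `[[`, character(1), "alt")
  )
  bind <- function(f) do.call(rbind, lapply(out, `[[`, f))
  variant_table(variants, samples, bind("a"), bind("b"),
                bind("dp"), bind("ad"), bind("gq"))
}

# "0/1", "0|1", "./." -> integer allele indices; anything unparseable -> NA.
parse_gt_alleles <- function(gt) {
  if (is.na(gt) || !nzchar(gt)) return(c(NA_integer_, NA_integer_))
  al <- strsplit(gt, "[/|]")[[1]]
  if (length(al) != 2) return(c(NA_integer_, NA_integer_))
  suppressWarnings(as.integer(al))
}

#' Write a variant table as VCF 4.2
#'
#' Emits a sorted VCF with a `GT:DP:AD:GQ` FORMAT block (AD as
#' `ref_depth,alt_depth` with `ref_depth = DP - alt_depth`). Reading the file
#' back with [read_vcf()] reproduces the table exactly.
#'
#' @param table a [variant_table()].
#' @param path output path.
#' @param info optional character vector (length `n_variants(table)`) of
#'   INFO strings, e.g. `"DNV=1"`; defaults to ".".
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path, info = NULL) {
  v <- table$variants
  n <- nrow(v)
  if (!is.null(info) && length(info) != n) {
    stop("info must have one entry per variant")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=denovotrio",
    "##INFO=<ID=DNV,Number=0,Type=Flag,Description=\"De novo candidate\">",
    "##INFO=<ID=VERDICT,Number=1,Type=String,Description=\"Trio verdict\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", table$samples), collapse = "\t")
  )
  lines <- header
  if (n > 0) {
    gt_chr <- matrix("./.", n, length(table$samples))
    ok <- !is.na(table$gt_a)
    gt_chr[ok] <- paste(table$gt_a[ok], table$gt_b[ok], sep = "/")
    ad_chr <- matrix(paste(pmax(table$dp - table$ad, 0L), table$ad, sep = ","),
                     n, length(table$samples))
    cells <- matrix(paste(gt_chr, table$dp, ad_chr, table$gq, sep = ":"),
                    n, length(table$samples))
    geno <- apply(cells, 1, paste, collapse = "\t")
    lines <- c(lines, paste(v$contig, v$pos, ".", v$ref, v$alt, ".", "PASS",
                            info %||% ".", "GT:DP:AD:GQ", geno, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
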