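# The filtering cascade: zygosity selection, private-variant filtering
# against the control panel, protein-changing restriction, artifact flags.

#' Build a control panel carrier index from a genotype table
#'
#' A site -> carriers index over the control cohort: any non-hom-ref,
#' non-missing genotype makes a sample a carrier. Privacy filtering only
#' needs carrier absence, so full panel genotypes are reduced to this index.
#'
#' @param table a [variant_table()] containing the control samples.
#' @param control_samples character vector of panel sample ids.
#' @return An object of class `control_panel` with fields `n_controls`,
#'   `keys`, `n_carriers`, `carriers` (list of carrier ids per site) and
#'   `n_missing`.
#' @export
control_panel <- function(table, control_samples) {
  j <- match(control_samples, table$samples)
  if (anyNA(j)) {
    stop("control sample(s) absent from table: ",
         paste(control_samples[is.na(j)], collapse = ", "), call. = FALSE)
  }
  d <- table$gt_a[, j, drop = FALSE] + table$gt_b[, j, drop = FALSE]
  carrier <- !is.na(d) & d >= 1L
  n_carriers <- rowSums(carrier)
  n_missing <- rowSums(is.na(d))
  hits <- which(carrier, arr.ind = TRUE)
  carriers <- vector("list", nrow(table$variants))
  if (nrow(hits) > 0) {
    by_row <- split(control_samples[hits[, 2]], hits[, 1])
    carriers[as.integer(names(by_row))] <- by_row
  }
  structure(list(
    n_controls = length(control_samples),
    keys = variant_keys(table),
    n_carriers = as.integer(n_carriers),
    carriers = carriers,
    n_missing = as.integer(n_missing)
  ), class = "control_panel")
}

#' Build a control panel from a precomputed site list
#'
#' For workflows where the cohort's carried sites are already tabulated:
#' a TSV with columns `contig`, `pos`, `ref`, `alt` and optionally
#' `n_carriers` (default 1). Sites absent from the list have zero carriers.
#'
#' @param path TSV path.
#' @param n_controls panel size the list was derived from.
#' @return A `control_panel`.
#' @export
panel_from_sites <- function(path, n_controls) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("contig", "pos", "ref", "alt") %in% names(df)))
  n_carriers <- if ("n_carriers" %in% names(df)) {
    as.integer(df$n_carriers)
  } else rep(1L, nrow(df))
  structure(list(
    n_controls = as.integer(n_controls),
    keys = paste(df$contig, df$pos, df$ref, df$alt, sep = ":"),
    n_carriers = n_carriers,
    carriers = vector("list", nrow(df)),
    n_missing = rep(0L, nrow(df))
  ), class = "control_panel")
}

panel_lookup <- function(panel, keys, field) {
  i <- match(keys, panel$keys)
  out <- panel[[field]][i]
  out[is.na(i)] <- 0L
  out
}

#' Select variants by proband zygosity
#'
#' `"homozygous"` keeps ALT/ALT proband calls, `"heterozygous"` keeps
#' REF/ALT; missing proband genotypes are excluded from both branches.
#'
#' @param table a [variant_table()].
#' @param proband proband sample id.
#' @param mode `"homozygous"` or `"heterozygous"`.
#' @return A [variant_table()] subset.
#' @export
select_zygosity <- function(table, proband,
                            mode = c("homozygous", "heterozygous")) {
  mode <- match.arg(mode)
  d <- genotype_dosage(table, proband)
  keep <- !is.na(d) & d == if (mode == "homozygous") 2L else 1L
  subset_variants(table, keep)
}

#' Retain variants absent from the control panel
#'
#' A variant is private when no panel sample carries its ALT allele. Under
#' the default `"lenient"` policy a panel sample with a missing genotype is
#' treated as a non-carrier (what joint-genotyped cohort output implies);
#' `"strict"` additionally drops variants with any panel missingness.
#'
#' @param table a [variant_table()].
#' @param panel a [control_panel()].
#' @param missing_policy `"lenient"` or `"strict"`.
#' @return A [variant_table()] subset.
#' @export
filter_private <- function(table, panel,
                           missing_policy = c("lenient", "strict")) {
  missing_policy <- match.arg(missing_policy)
  keys <- variant_keys(table)
  keep <- panel_lookup(panel, keys, "n_carriers") == 0L
  if (missing_policy == "strict") {
    keep <- keep & panel_lookup(panel, keys, "n_missing") == 0L
  }
  subset_variants(table, keep)
}

#' Retain protein-changing variants
#'
#' Applies the any-transcript rule over the supplied annotations, which must
#' cover every variant in the table (a missing annotation indicates the
#' cascade was run out of order and is an error).
#'
#' @param table a [variant_table()].
#' @param annotations output of [annotate_all()] covering the table.
#' @return A [variant_table()] subset.
#' @export
filter_protein_changing <- function(table, annotations) {
  keys <- variant_keys(table)
  pc <- protein_changing_any(annotations)
  missing <- setdiff(keys, names(pc))
  if (length(missing) > 0) {
    stop("internal error: unannotated variant(s) reached the ",
         "protein-changing filter: ", paste(head(missing, 3), collapse = ", "),
         call. = FALSE)
  }
  subset_variants(table, unname(pc[keys]))
}

#' Artifact context flags for a candidate variant
#'
#' Operationalises manual inspection of dubious calls: proximity to assembly
#' gaps (an N-run of length >= `gap_min` within `gap_window` bp of the
#' variant), repetitive context (fraction of soft-masked lowercase bases, or
#' of bases inside tandem runs of a single dinucleotide, exceeding
#' `repeat_frac` in a `repeat_window` bp window centred on the variant), and
#' low coverage (mean depth over a `cov_window` bp window below `cov_min`).
#'
#' @param variant single-row data.frame or list with `contig`, `pos`.
#' @param reference [Biostrings::DNAStringSet], or a named character vector
#'   of contig sequences. Soft-masking is only visible in the character
#'   form: Biostrings stores bases uppercased, so a masked genome should be
#'   passed as plain strings if the lowercase criterion is wanted.
#' @param coverage_track optional named list of per-base integer depth
#'   vectors, one per contig; when absent `low_coverage` is `NA` (unknown),
#'   not `FALSE`.
#' @param gap_min,gap_window,repeat_window,repeat_frac,cov_window,cov_min
#'   thresholds as described above.
#' @return List with logical `near_gap`, `repetitive` and `low_coverage`
#'   (possibly `NA`).
#' @export
flag_artifacts <- function(variant, reference, coverage_track = NULL,
                           gap_min = 10, gap_window = 500,
                           repeat_window = 200, repeat_frac = 0.8,
                           cov_window = 50, cov_min = 5) {
  contig <- variant$contig
  pos <- as.integer(variant$pos)

  win <- ref_subseq(reference, contig, pos - gap_window, pos + gap_window)
  near_gap <- grepl(paste0("N{", gap_min, ",}"), toupper(win))

  half <- floor(repeat_window / 2)
  rwin <- ref_subseq(reference, contig, pos - half, pos + half - 1L)
  repetitive <- FALSE
  if (nchar(rwin) > 0) {
    chars <- strsplit(rwin, "")[[1]]
    frac_masked <- mean(chars %in% c("a", "c", "g", "t", "n"))
    repetitive <- frac_masked > repeat_frac ||
      dinucleotide_dominance(toupper(rwin)) > repeat_frac
  }

  low_coverage <- NA
  if (!is.null(coverage_track)) {
    cov <- coverage_track[[contig]]
    if (!is.null(cov)) {
      chalf <- floor(cov_window / 2)
      i0 <- max(1L, pos - chalf)
      i1 <- min(length(cov), pos + chalf)
      low_coverage <- mean(cov[i0:i1]) < cov_min
    }
  }
  list(near_gap = near_gap, repetitive = repetitive,
       low_coverage = low_coverage)
}

# Largest fraction of a window covered by tandem runs (>= 3 copies) of any
# single dinucleotide; homopolymers count via the XX dinucleotides.
dinucleotide_dominance <- function(window) {
  if (nchar(window) < 6) return(0)
  bases <- c("A", "C", "G", "T")
  best <- 0
  for (x in bases) for (y in bases) {
    pat <- paste0("(", x, y, "){3,}")
    m <- gregexpr(pat, window)[[1]]
    covered <- if (m[1] == -1) 0 else sum(attr(m, "match.length"))
    best <- max(best, covered / nchar(window))
  }
  best
}

#' Artifact flags for every variant in a table
#'
#' @inheritParams flag_artifacts
#' @param table a [variant_table()].
#' @param ... thresholds passed to [flag_artifacts()].
#' @return data.frame with key, position and the three flags.
#' @export
flag_artifacts_all <- function(table, reference, coverage_track = NULL, ...) {
  v <- table$variants
  flags <- lapply(seq_len(nrow(v)), function(i) {
    flag_artifacts(v[i, ], reference, coverage_track, ...)
  })
  data.frame(
    key = variant_keys(table), contig = v$contig, pos = v$pos,
    near_gap = vapply(flags, `[[`, logical(1), "near_gap"),
    repetitive = vapply(flags, `[[`, logical(1), "repetitive"),
    low_coverage = vapply(flags, function(f) {
      if (is.na(f$low_coverage)) NA else f$low_coverage
    }, logical(1)),
    stringsAsFactors = FALSE
  )
}

#' Run one zygosity branch of the filtering cascade
#'
#' Applies [select_zygosity()], [filter_private()] and
#' [filter_protein_changing()] in that order, recording counts at every
#' stage. Each stage's output is asserted to be a subset of its input.
#'
#' @param table a [variant_table()].
#' @param proband proband sample id.
#' @param panel a [control_panel()].
#' @param annotations output of [annotate_all()]; must cover at least the
#'   private variants of the branch.
#' @param mode `"homozygous"` or `"heterozygous"`.
#' @param missing_policy passed to [filter_private()].
#' @return List with `table` (surviving variants) and `report` (a
#'   `stage_report` data.frame of stage labels and counts).
#' @export
run_cascade <- function(table, proband, panel, annotations,
                        mode = c("homozygous", "heterozygous"),
                        missing_policy = "lenient") {
  mode <- match.arg(mode)
  zyg <- select_zygosity(table, proband, mode)
  priv <- filter_private(zyg, panel, missing_policy)
  pc <- filter_protein_changing(priv, annotations)
  stopifnot(all(variant_keys(priv) %in% variant_keys(zyg)),
            all(variant_keys(pc) %in% variant_keys(priv)))
  labels <- c(
    sprintf("%s variants in the whole genome", tools::toTitleCase(mode)),
    sprintf("Private %s variants (absent from %d control genomes)",
            mode, panel$n_controls),
    sprintf("Protein-changing private %s variants (absent from %d control genomes)",
            mode, panel$n_controls)
  )
  report <- structure(
    data.frame(stage = labels,
               count = c(n_variants(zyg), n_variants(priv), n_variants(pc)),
               stringsAsFactors = FALSE),
    class = c("stage_report", "data.frame"))
  list(table = pc, report = report)
}

#' @export
print.stage_report <- function(x, ...) {
  w <- max(nchar(x$stage))
  cat(sprintf(paste0("%-", w, "s  %s\n"), "Filtering step", "Number of variants"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf(paste0("%-", w, "s  %s\n"), x$stage[i],
                format(x$count[i], big.mark = ",")))
  }
  invisible(x)
}

#' Write a stage report as TSV
#' @param report a `stage_report` (or several rbind-ed together).
#' @param path output path.
#' @export
write_stage_report <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
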