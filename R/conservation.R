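# Residue conservation from protein multiple alignments.

GAP_CHARS <- c("-", ".")

#' Read an aligned protein FASTA
#'
#' All sequences must have equal (aligned) length.
#'
#' @param path aligned FASTA path.
#' @return [Biostrings::AAStringSet] named by species/accession.
#' @export
read_protein_alignment <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  if (length(unique(Biostrings::width(aln))) > 1) {
    stop("aligned sequences have unequal lengths in '", path, "'",
         call. = FALSE)
  }
  aln
}

aln_char_matrix <- function(aln) {
  if (inherits(aln, "AAStringSet")) {
    m <- do.call(rbind, strsplit(as.character(aln), ""))
    rownames(m) <- names(aln)
    m
  } else if (is.character(aln)) {
    m <- do.call(rbind, strsplit(aln, ""))
    rownames(m) <- names(aln)
    m
  } else stop("unsupported alignment representation")
}

#' Alignment column of a reference residue
#'
#' Locates the alignment column holding the `residue_index`-th non-gap
#' residue of the designated reference sequence and returns all species'
#' characters at that column.
#'
#' @param aln [Biostrings::AAStringSet] (or named character vector) of
#'   aligned sequences.
#' @param ref_species name of the reference sequence.
#' @param residue_index 1-based ungapped residue index in the reference.
#' @return List of class `alignment_column` with `position` (1-based
#'   alignment column), `residues` (named character vector), `ref_species`
#'   and `residue_index`.
#' @export
column_for_residue <- function(aln, ref_species, residue_index) {
  m <- aln_char_matrix(aln)
  if (!ref_species %in% rownames(m)) {
    stop("reference species '", ref_species, "' absent from alignment",
         call. = FALSE)
  }
  refrow <- m[ref_species, ]
  nongap <- !refrow %in% GAP_CHARS
  if (residue_index < 1 || residue_index > sum(nongap)) {
    stop("residue index ", residue_index, " beyond ungapped length ",
         sum(nongap), " of '", ref_species, "'", call. = FALSE)
  }
  col <- which(nongap)[residue_index]
  structure(list(
    position = col,
    residues = setNames(m[, col], rownames(m)),
    ref_species = ref_species,
    residue_index = as.integer(residue_index)
  ), class = "alignment_column")
}

#' Conservation summary of an alignment column
#'
#' Gaps are excluded from distinct-residue counting; a column is strictly
#' conserved iff exactly one distinct non-gap residue occurs across
#' species. An all-gap column returns `strictly_conserved = NA` (undefined
#' conservation). The summary is invariant to species ordering; majority
#' ties break alphabetically.
#'
#' @param column an [column_for_residue()] result.
#' @return List with `n_species`, `n_distinct_nongap`, `strictly_conserved`
#'   and `majority_residue`.
#' @export
conservation_summary <- function(column) {
  res <- column$residues
  nongap <- res[!res %in% GAP_CHARS]
  if (length(nongap) == 0) {
    return(list(n_species = length(res), n_distinct_nongap = 0L,
                strictly_conserved = NA, majority_residue = NA_character_))
  }
  tab <- table(nongap)
  tab <- tab[order(-tab, names(tab))]
  list(
    n_species = length(res),
    n_distinct_nongap = length(tab),
    strictly_conserved = length(tab) == 1L,
    majority_residue = names(tab)[1]
  )
}

#' Write a conservation summary as TSV
#'
#' @param column an [column_for_residue()] result.
#' @param summary matching [conservation_summary()] result.
#' @param path output path.
#' @export
write_conservation_tsv <- function(column, summary, path) {
  df <- data.frame(
    ref_species = column$ref_species,
    residue_index = column$residue_index,
    alignment_position = column$position,
    n_species = summary$n_species,
    distinct_residues = summary$n_distinct_nongap,
    strictly_conserved = summary$strictly_conserved,
    majority_residue = summary$majority_residue
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
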