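# Trio verification and parentage QC: de novo verdicts, Mendel errors,
# method-of-moments IBD, microsatellite transmission.

#' Default evidence thresholds for de novo verdicts
#'
#' `dn_alt_min`: minimum proband alt-supporting reads; `dn_alt_frac`:
#' admissible proband alt fraction; `dn_parent_depth_min`: minimum parental
#' depth; `dn_parent_alt_max`: maximum alt-supporting reads tolerated in a
#' hom-ref parent. These operationalise manual read-level inspection of
#' candidate sites in a well-covered (~30x) genome.
#'
#' @return Named list of thresholds.
#' @export
denovo_thresholds <- function() {
  list(dn_alt_min = 5L, dn_alt_frac = c(0.2, 0.8),
       dn_parent_depth_min = 10L, dn_parent_alt_max = 0L)
}

#' Classify candidate variants as de novo, inherited or unresolved
#'
#' A candidate is `de_novo` iff the proband is REF/ALT with sufficient,
#' balanced alt evidence AND each parent is REF/REF with sufficient depth
#' and no more than `dn_parent_alt_max` alt reads. Any parent carrying the
#' ALT allele makes the verdict `inherited`; anything else (including
#' stray parental alt reads or thin coverage) is `unresolved` with reasons.
#'
#' @param table a [variant_table()] restricted to the candidate variants,
#'   containing all three samples.
#' @param proband,sire,dam sample ids.
#' @param thresholds list as returned by [denovo_thresholds()].
#' @return data.frame with one row per candidate: coordinates, trio
#'   genotypes/depths, `verdict` and semicolon-separated `reasons`.
#' @export
detect_de_novo <- function(table, proband, sire, dam,
                           thresholds = denovo_thresholds()) {
  jp <- sample_col(table, proband)
  js <- sample_col(table, sire)
  jd <- sample_col(table, dam)
  th <- thresholds
  v <- table$variants
  n <- nrow(v)
  verdict <- character(n)
  reasons <- character(n)
  dp_ <- function(j, i) table$dp[i, j]
  ad_ <- function(j, i) table$ad[i, j]
  dos <- function(j, i) table$gt_a[i, j] + table$gt_b[i, j]

  for (i in seq_len(n)) {
    rs <- character(0)
    d_pro <- dos(jp, i); d_sire <- dos(js, i); d_dam <- dos(jd, i)
    if (!is.na(d_sire) && d_sire >= 1L) {
      verdict[i] <- "inherited"; reasons[i] <- "sire carries ALT"; next
    }
    if (!is.na(d_dam) && d_dam >= 1L) {
      verdict[i] <- "inherited"; reasons[i] <- "dam carries ALT"; next
    }
    if (is.na(d_pro)) rs <- c(rs, "proband genotype missing")
    else if (d_pro != 1L) rs <- c(rs, "proband not heterozygous")
    else {
      dp <- dp_(jp, i); ad <- ad_(jp, i)
      frac <- if (dp > 0) ad / dp else 0
      if (ad < th$dn_alt_min) rs <- c(rs, "proband alt reads below minimum")
      if (frac < th$dn_alt_frac[1] || frac > th$dn_alt_frac[2]) {
        rs <- c(rs, "proband alt fraction out of range")
      }
    }
    for (par in c("sire", "dam")) {
      j <- if (par == "sire") js else jd
      d <- if (par == "sire") d_sire else d_dam
      if (is.na(d)) { rs <- c(rs, paste(par, "genotype missing")); next }
      if (dp_(j, i) < th$dn_parent_depth_min) {
        rs <- c(rs, paste(par, "depth below minimum"))
      }
      if (ad_(j, i) > th$dn_parent_alt_max) {
        rs <- c(rs, paste("alt reads in", par))
      }
    }
    if (length(rs) == 0) {
      verdict[i] <- "de_novo"
      reasons[i] <- ""
    } else {
      verdict[i] <- "unresolved"
      reasons[i] <- paste(rs, collapse = "; ")
    }
  }
  data.frame(
    key = variant_keys(table), contig = v$contig, pos = v$pos,
    ref = v$ref, alt = v$alt,
    proband_gt = genotype_dosage(table, proband),
    sire_gt = genotype_dosage(table, sire),
    dam_gt = genotype_dosage(table, dam),
    proband_dp = table$dp[, jp], proband_ad = table$ad[, jp],
    sire_dp = table$dp[, js], sire_ad = table$ad[, js],
    dam_dp = table$dp[, jd], dam_ad = table$ad[, jd],
    verdict = verdict, reasons = reasons,
    stringsAsFactors = FALSE
  )
}

# Trio compatibility rules on dosages (0/1/2). The het-child/two-hom-ref
# configuration is the de novo discovery signature: routed out of the error
# count by default, counted under strict = TRUE.
mendel_site_verdict <- function(child, sire, dam, strict = FALSE) {
  if (is.na(child) || is.na(sire) || is.na(dam)) return("untested")
  if (child == 0L && (sire == 2L || dam == 2L)) return("error")
  if (child == 2L && (sire == 0L || dam == 0L)) return("error")
  if (child == 1L && sire == 2L && dam == 2L) return("error")
  if (child == 1L && sire == 0L && dam == 0L) {
    return(if (strict) "error" else "de_novo_signature")
  }
  "consistent"
}

#' Count Mendelian inheritance errors in a trio
#'
#' A site is an error iff the proband genotype cannot be formed by taking
#' one allele from each parent. Sites with any missing genotype are
#' excluded from `n_tested`. By default the REF/ALT child with two REF/REF
#' parents is *not* counted -- it is the de novo discovery signature and is
#' routed to [detect_de_novo()] -- while `strict = TRUE` counts it.
#'
#' @param table a [variant_table()] of biallelic sites.
#' @param proband,sire,dam sample ids.
#' @param strict count the de novo signature as an error.
#' @return List with `errors`, `n_tested` and `verdicts` (per-site
#'   data.frame; verdict in consistent/error/de_novo_signature/untested).
#' @export
count_mendel_errors <- function(table, proband, sire, dam, strict = FALSE) {
  dc <- genotype_dosage(table, proband)
  ds <- genotype_dosage(table, sire)
  dd <- genotype_dosage(table, dam)
  verdict <- mapply(mendel_site_verdict, dc, ds, dd,
                    MoreArgs = list(strict = strict))
  list(
    errors = sum(verdict == "error"),
    n_tested = sum(verdict != "untested"),
    verdicts = data.frame(key = variant_keys(table), child = dc, sire = ds,
                          dam = dd, verdict = verdict,
                          stringsAsFactors = FALSE)
  )
}

#' Method-of-moments IBD estimation for a sample pair
#'
#' Estimates the probabilities `Z0/Z1/Z2` of sharing 0/1/2 alleles identical
#' by descent from observed identity-by-state counts versus their
#' allele-frequency expectations, then truncates to `[0, 1]` and
#' renormalises; `pi_hat = Z2 + Z1/2`. Sites are thinned to one per
#' `thin_bp` along each contig to approximate independence, and sites with
#' a missing genotype in either sample or a monomorphic allele frequency
#' are dropped. When frequencies are estimated from panel genotypes, the
#' IBS expectations use unbiased falling-factorial estimators of the
#' frequency monomials (the finite-sample correction classically applied in
#' method-of-moments relatedness estimation); supplied frequencies are
#' treated as known and used directly.
#'
#' @param table a [variant_table()].
#' @param sample1,sample2 sample ids (the estimate is symmetric).
#' @param freqs optional ALT allele frequencies: numeric vector named by
#'   variant key, or unnamed and aligned with the table rows. When `NULL`,
#'   frequencies are estimated from `freq_samples`.
#' @param freq_samples samples used to estimate frequencies; default all
#'   samples except the pair.
#' @param thin_bp minimum spacing between used sites (default 100 kb).
#' @param min_sites refuse the estimate below this many usable sites.
#' @return List with `z0`, `z1`, `z2`, `pi_hat`, `n_sites`.
#' @export
estimate_ibd <- function(table, sample1, sample2, freqs = NULL,
                         freq_samples = NULL, thin_bp = 1e5, min_sites = 50) {
  d1 <- genotype_dosage(table, sample1)
  d2 <- genotype_dosage(table, sample2)
  keys <- variant_keys(table)

  kcount <- NULL  # alt-allele counts when freqs come from a finite panel
  if (is.null(freqs)) {
    freq_samples <- freq_samples %||%
      setdiff(table$samples, c(sample1, sample2))
    if (length(freq_samples) == 0) {
      stop("no samples left to estimate allele frequencies from; ",
           "supply freqs", call. = FALSE)
    }
    js <- match(freq_samples, table$samples)
    dos <- table$gt_a[, js, drop = FALSE] + table$gt_b[, js, drop = FALSE]
    kcount <- rowSums(dos, na.rm = TRUE)
    tall <- 2 * rowSums(!is.na(dos))
    p <- kcount / tall
    p[tall == 0] <- NA
  } else if (!is.null(names(freqs))) {
    p <- unname(freqs[keys])
  } else {
    stopifnot(length(freqs) == length(keys))
    p <- freqs
  }

  usable <- !is.na(d1) & !is.na(d2) & !is.na(p) & p > 0 & p < 1
  if (!is.null(kcount)) usable <- usable & tall >= 8
  # Distance thinning, greedy left-to-right per contig.
  v <- table$variants
  keep <- rep(FALSE, nrow(v))
  for (ctg in unique(v$contig)) {
    idx <- which(v$contig == ctg & usable)
    last <- -Inf
    for (i in idx) {
      if (v$pos[i] - last >= thin_bp) {
        keep[i] <- TRUE
        last <- v$pos[i]
      }
    }
  }
  if (sum(keep) < min_sites) {
    stop("only ", sum(keep), " usable sites after thinning (need >= ",
         min_sites, "); IBD estimate refused", call. = FALSE)
  }
  d1 <- d1[keep]; d2 <- d2[keep]; p <- p[keep]
  q <- 1 - p

  ibs <- 2L - abs(d1 - d2)
  n <- length(ibs)
  n0 <- sum(ibs == 0L); n1 <- sum(ibs == 1L); n2 <- sum(ibs == 2L)

  if (is.null(kcount)) {
    # Frequencies are known: plain monomials.
    m_pq <- p * q
    m_p2q2 <- p^2 * q^2
    m_p3q <- p^3 * q
    m_pq3 <- p * q^3
    m_p4 <- p^4
    m_q4 <- q^4
  } else {
    # Frequencies estimated from K alt alleles out of T sampled: unbiased
    # estimators of the monomials via falling factorials.
    K <- kcount[keep]; T2 <- tall[keep]
    ff <- function(x, r) {
      out <- rep(1, length(x))
      for (i in 0:(r - 1)) out <- out * (x - i)
      out
    }
    m_pq <- ff(K, 1) * ff(T2 - K, 1) / ff(T2, 2)
    m_p2q2 <- ff(K, 2) * ff(T2 - K, 2) / ff(T2, 4)
    m_p3q <- ff(K, 3) * ff(T2 - K, 1) / ff(T2, 4)
    m_pq3 <- ff(K, 1) * ff(T2 - K, 3) / ff(T2, 4)
    m_p4 <- ff(K, 4) / ff(T2, 4)
    m_q4 <- ff(T2 - K, 4) / ff(T2, 4)
  }
  e0_z0 <- sum(2 * m_p2q2)
  e1_z0 <- sum(4 * m_p3q + 4 * m_pq3)
  e2_z0 <- sum(m_p4 + m_q4 + 4 * m_p2q2)
  e1_z1 <- sum(2 * m_pq)
  e2_z1 <- sum(1 - 2 * m_pq)

  z0 <- n0 / e0_z0
  z1 <- (n1 - z0 * e1_z0) / e1_z1
  z2 <- (n2 - z0 * e2_z0 - z1 * e2_z1) / n

  z <- pmin(pmax(c(z0, z1, z2), 0), 1)
  z <- z / sum(z)
  list(z0 = z[1], z1 = z[2], z2 = z[3], pi_hat = z[3] + z[2] / 2,
       n_sites = n)
}

#' Read a microsatellite genotype table
#'
#' TSV with columns `locus`, `sample`, `allele1`, `allele2` (allele lengths;
#' both NA for a failed call).
#'
#' @param path TSV path.
#' @return data.frame of class `microsat_table`.
#' @export
read_microsats <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("locus", "sample", "allele1", "allele2") %in% names(df)))
  structure(df, class = c("microsat_table", "data.frame"))
}

#' Write a microsatellite genotype table
#' @param ms a `microsat_table`.
#' @param path output path.
#' @export
write_microsats <- function(ms, path) {
  write.table(as.data.frame(ms), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

ms_pair <- function(ms, locus, sample) {
  row <- ms[ms$locus == locus & ms$sample == sample, , drop = FALSE]
  if (nrow(row) != 1) return(NULL)
  al <- c(row$allele1, row$allele2)
  if (anyNA(al)) return(NULL)
  as.integer(al)
}

#' Check Mendelian transmission of microsatellite alleles in a trio
#'
#' A locus is consistent iff the child's unordered allele pair can be split
#' into one allele present in the sire's pair and one in the dam's pair
#' (both assignments of the two child alleles are tried, which covers the
#' shared-allele cases). Loci with missing calls in any trio member are
#' excluded from the total with a warning.
#'
#' @param ms a `microsat_table` (see [read_microsats()]).
#' @param proband,sire,dam sample ids.
#' @return List with `consistent_loci`, `total_loci` and per-locus
#'   `verdicts` data.frame.
#' @export
check_microsat_transmission <- function(ms, proband, sire, dam) {
  loci <- unique(ms$locus)
  verdicts <- character(0)
  used <- character(0)
  for (loc in loci) {
    ch <- ms_pair(ms, loc, proband)
    si <- ms_pair(ms, loc, sire)
    da <- ms_pair(ms, loc, dam)
    if (is.null(ch) || is.null(si) || is.null(da)) {
      warning("locus ", loc, " has missing calls; excluded", call. = FALSE)
      next
    }
    ok <- (ch[1] %in% si && ch[2] %in% da) || (ch[2] %in% si && ch[1] %in% da)
    used <- c(used, loc)
    verdicts <- c(verdicts, if (ok) "consistent" else "inconsistent")
  }
  list(
    consistent_loci = sum(verdicts == "consistent"),
    total_loci = length(used),
    verdicts = data.frame(locus = used, verdict = verdicts,
                          stringsAsFactors = FALSE)
  )
}

#' Expected number of protein-changing de novo variants per trio
#'
#' Per-trio counts are modelled as Binomial(Poisson(`lambda_dn`), `p_pc`):
#' a Poisson number of de novo mutation events of which each is
#' protein-changing independently. Returns the analytic mean
#' `lambda_dn * p_pc` alongside a Monte-Carlo mean over `n_trios`
#' simulated trios.
#'
#' @param lambda_dn mean de novo events per trio.
#' @param p_pc probability an event is protein-changing.
#' @param n_trios number of simulated trios.
#' @param seed optional RNG seed.
#' @return List with `analytic`, `mc_mean`, `mc_se`, `n_trios`.
#' @export
expected_protein_changing_dn <- function(lambda_dn = 73, p_pc = 0.013,
                                         n_trios = 10000, seed = NULL) {
  stopifnot(lambda_dn > 0, p_pc >= 0, p_pc <= 1)
  if (!is.null(seed)) set.seed(seed)
  counts <- rbinom(n_trios, rpois(n_trios, lambda_dn), p_pc)
  list(analytic = lambda_dn * p_pc,
       mc_mean = mean(counts),
       mc_se = sd(counts) / sqrt(n_trios),
       n_trios = n_trios)
}

#' Assemble a parentage QC report
#'
#' Bundles Mendel-error counting, pairwise IBD estimates and (optionally)
#' microsatellite transmission into one structure, serialisable as JSON or
#' TSV.
#'
#' @param table a [variant_table()] with the trio (and ideally the cohort,
#'   for allele frequencies).
#' @param proband,sire,dam sample ids.
#' @param ms optional `microsat_table`.
#' @param freqs,freq_samples,thin_bp,min_sites passed to [estimate_ibd()].
#' @return List of class `parentage_report`.
#' @export
parentage_report <- function(table, proband, sire, dam, ms = NULL,
                             freqs = NULL, freq_samples = NULL,
                             thin_bp = 1e5, min_sites = 50) {
  mend <- count_mendel_errors(table, proband, sire, dam)
  pairs <- list(proband_sire = c(proband, sire),
                proband_dam = c(proband, dam),
                sire_dam = c(sire, dam))
  ibd <- lapply(pairs, function(pr) {
    est <- tryCatch(
      estimate_ibd(table, pr[1], pr[2], freqs = freqs,
                   freq_samples = freq_samples, thin_bp = thin_bp,
                   min_sites = min_sites),
      error = function(e) list(error = conditionMessage(e)))
    est
  })
  msat <- if (!is.null(ms)) {
    chk <- check_microsat_transmission(ms, proband, sire, dam)
    list(consistent_loci = chk$consistent_loci, total_loci = chk$total_loci)
  } else NULL
  structure(list(
    n_sites_tested = mend$n_tested,
    mendel_errors = mend$errors,
    ibd = ibd,
    microsatellites = msat
  ), class = "parentage_report")
}

#' Write a parentage report as JSON
#' @param report a [parentage_report()].
#' @param path output path.
#' @export
write_parentage_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
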