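---
title: "Methods: trio-based de novo variant discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio-based de novo variant discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An isolated case of a severe Mendelian phenotype in an outbred-within-breed
population admits two genetic hypotheses: a recessive allele hidden in
homozygous state, or a dominant allele that arose by a new (de novo)
mutation in a parental germline. `denovotrio` implements the whole-genome
filtering strategy used to discriminate between them: every variant called
in the affected individual is (i) split by zygosity, (ii) filtered for
*privacy* against a panel of control genomes, (iii) restricted to
protein-changing consequences, and then (iv) adjudicated — homozygous
survivors against sequencing-artifact context, heterozygous survivors
against both parental genomes for de novo status. Parentage itself is
verified independently (Mendelian-error counting, method-of-moments IBD,
microsatellite transmission), because the de novo argument collapses if
the nominal parents are wrong.

## The filtering cascade

Let $G_p(v) \in \{0, 1, 2\}$ be the proband's ALT dosage at variant $v$
and $C(v)$ the set of control-panel samples carrying any ALT allele at
$v$. A branch of the cascade computes

$$ \{v : G_p(v) = g\} \;\supseteq\; \{v : G_p(v) = g,\, C(v) = \emptyset\}
   \;\supseteq\; \{v : G_p(v) = g,\, C(v) = \emptyset,\, \mathrm{PC}(v)\} $$

for $g = 2$ (homozygous branch, recessive hypothesis, examined first) and
$g = 1$ (heterozygous branch, dominant/de novo hypothesis). $\mathrm{PC}$
is protein-changing status under the **any-transcript rule**: a variant
counts as protein-changing if *any* overlapping transcript model yields a
protein-changing consequence. This maximises sensitivity, which is the
right operating point for a screen whose candidate list is later verified
by hand (or, here, by the trio step). The two filters commute — privacy
depends only on panel genotypes and PC only on the annotation — and each
stage is asserted to be a subset of its input on every run.

Panel missingness is ambiguous in joint-genotyped cohorts. The default
(`lenient`) policy treats a missing panel genotype as a non-carrier, which
is what cohort VCF output implies; a `strict` policy that drops any site
with panel missingness is provided because the choice is genuinely open.
Multiallelic sites are decomposed on read into biallelic records
(privacy is judged per allele, not per site); in a decomposed record, a
genotype that references a *different* ALT allele becomes a missing call,
so it can neither rescue nor kill the record's privacy.

## Consequence annotation

The annotator is deliberately small: it maps a genomic position through a
strand-aware exon/CDS model to a coding position, extracts the affected
codon from the spliced CDS, substitutes the strand-corrected alternate
base, and translates both codons with the standard genetic code. HGVS
output covers the subset this analysis needs — `c.{pos}{REF}>{ALT}` in
transcript-strand alleles and `p.(Xaa{idx}Yaa)` in three-letter code — and
nothing else (no dup/del/ins nomenclature, no intronic `c.` offsets).
The protein-changing class set is missense, stop gain/loss, start loss,
frameshift, in-frame indel, and splice site, where "splice site" means
the two intronic bases flanking each exon–intron junction (the canonical
donor/acceptor dinucleotides). Whether a wider splice *region* should
count is not decidable from first principles; ±2 is the conservative,
mechanistically defensible choice. CDS indels are classified frameshift
when the length change is not a multiple of 3, in-frame otherwise, with
no attempt at HGVS indel naming. Codons containing ambiguity bases are
`unresolvable` and never protein-changing.

Correctness is enforced by a re-translation oracle in the test suite: for
over a thousand random coding SNVs per run, the whole mutated CDS is
translated independently (via `Biostrings::translate`) and must agree
with the class and residue index the annotator reports, on both strands.
One fact worth recording: of the six leucine codons, a T→C change at the
middle base yields proline only for the four CTN codons; TTA and TTG
yield serine. The worked example in this package (a CTG codon at residue
351, c.1052T>C → p.(Leu351Pro)) sits in the CTN family.

## Trio verification

A heterozygous private candidate is **de novo** when the proband carries
balanced, well-supported ALT evidence and both parents are confidently
hom-ref:

* proband REF/ALT with `alt_depth >= 5` and ALT fraction in `[0.2, 0.8]`;
* each parent REF/REF with `total_depth >= 10` and zero ALT reads.

Any parent carrying the ALT allele makes the verdict `inherited`;
anything short of the evidence bar is `unresolved`, with machine-readable
reasons. The thresholds operationalise manual read-level inspection of a
~30× genome and are all configurable; they are deliberately strict on
parental ALT reads (a single read is enough to withhold a de novo call)
because false de novo claims are expensive to retract.

**Mendel errors.** A site is an error when the child's genotype cannot be
assembled from one allele of each parent. The REF/ALT child with two
REF/REF parents is excluded from the error count by default: it is
exactly the de novo discovery signature and is routed to the detector
instead (a `strict` flag restores the classic definition). The rules are
validated against brute-force enumeration of all 27 trio dosage
combinations.

**IBD.** Relatedness is estimated by the method of moments on
identity-by-state counts, exactly in the `--genome` tradition: observed
IBS0/1/2 counts are compared with their allele-frequency expectations
under IBD states Z0/Z1/Z2, solved sequentially, truncated to $[0,1]$ and
renormalised; $\hat{\pi} = Z_2 + Z_1/2$. Two numerical points matter.
First, when frequencies are estimated from a finite panel, the plain
plug-in expectations are biased at rare sites; the implementation uses
unbiased falling-factorial estimators of the frequency monomials
($p^2q^2$, $p^3q$, …) computed from allele counts, the classical
finite-sample correction for moment-based relatedness estimation.
Second, sites are thinned to one per 100 kb by default to approximate
independence on real genomes, where nearby sites are in linkage
disequilibrium. The synthetic generator draws sites independently, so
thinning carries no benefit there and the simulation-facing entry points
use a much smaller spacing (200 bp in `simulate_and_run()`); on a 2 Mb
toy genome the 100 kb default would also leave fewer than the 50-site
minimum below which the estimator refuses to answer. Truncation at zero
means $\hat\pi$ for truly unrelated pairs is a non-negative noise
variable, typically a few hundredths at the simulated panel sizes — it
should be read as "indistinguishable from unrelated", not as literal
sharing.

**Microsatellites.** A locus is transmission-consistent when the child's
unordered allele pair splits into one allele found in the sire's pair and
one in the dam's; both assignments are tried, which resolves the shared-
allele cases. Loci with failed calls are excluded from the denominator.

**Expectation.** The number of protein-changing de novo events per trio
is modelled as $\mathrm{Binomial}(\mathrm{Poisson}(\lambda), p)$ with
$\lambda = 73$ events and $p = 0.013$; the analytic mean
$\lambda p = 0.949$ ("roughly one per genome") is reported alongside a
Monte-Carlo mean, which the tests require to agree within three standard
errors at 10,000 trios.

## Artifact flags

Manual inspection of dubious homozygous candidates is operationalised as
three context flags, each with an explicit window and threshold (all
configurable):

| flag | rule | default |
|---|---|---|
| `near_gap` | N-run of ≥ `gap_min` bases within `gap_window` of the site | 10 within 500 bp |
| `repetitive` | fraction of soft-masked or single-dinucleotide-run bases in a centred `repeat_window` above `repeat_frac` | 0.8 over 200 bp |
| `low_coverage` | mean depth over `cov_window` below `cov_min` | 5 over 50 bp |

When no coverage track is supplied, `low_coverage` is reported as
*unknown* (`NA`), never silently `FALSE`. Because Biostrings stores
sequences uppercased, the soft-masking criterion only engages when the
reference is supplied as plain character strings; the dinucleotide-run
criterion is case-independent.

## The synthetic data generator

The generator exists so the entire cascade can be exercised, with a known
answer, without any external download. Its defaults are the study
conditions the pipeline is meant to emulate: a control panel of **288**
genomes, a Poisson mean of **73** de novo events per trio, a
protein-changing fraction of **1.3%**, **7** microsatellite loci, and
**4** planted artifact-prone homozygous candidates — on a miniature
2 Mb, 2-contig genome carrying 20 genes (single- and multi-exon, both
strands, valid start/stop codons, CDS lengths divisible by 3). Cohort
site frequencies follow a U-shaped Beta(0.3, 0.3) spectrum so that
private-variant filtering is non-trivial: most sites are rare, and a
realistic handful of genuinely private inherited variants survives the
panel. Parents draw genotypes from those frequencies; the proband
inherits one allele from each parent; de novo events are added on top,
each engineered into a coding missense with probability 1.3% (rejection
sampling, capped at 1000 tries) and placed anywhere non-protein-changing
otherwise. Artifact candidates are engineered missense sites in artifact
context — one gene carries a 50 bp N-run in an intron, another a 400 bp
AT tract *inside* its CDS (alternating Ile/Tyr codons, so the tract is
still translatable), and coverage dropouts are written into the emitted
depth track. Trio depth evidence is drawn to satisfy the de novo evidence
thresholds whenever the genotypes do (a well-covered genome), so verdicts
are decided by genotypes, not depth noise.

Every emitted variant carries a manifest record: origin
(cohort/de novo/artifact), planted consequence, panel carrier count,
and its expected fate in the cascade, computed at planting time. The
master acceptance property is that a full run reproduces the manifest
exactly — stage counts, de novo verdicts, artifact flags — at the default
scale, under any seed.

What the generator does *not* model, and hence what passing tests do not
show about real data: linkage disequilibrium (sites are independent),
alignment and calling error beyond the explicit genotype-error switch,
indels and multiallelic sites (exercised through hand-built I/O fixtures
instead), population structure in the panel, and read-level evidence
(the VCF is the ground floor; BAM-level simulation is out of scope).

## Problem sizes

Module tests run the generator at reduced scale (0.3–0.6 Mb genomes,
24–48 controls, 600–2,500 sites) where study-scale conditions are not the
point of the test; the acceptance suite runs the full default
configuration (2 Mb, 288 controls, 20,000 sites) once end-to-end, which
completes in well under two minutes on a single CPU. The de novo
expectation check uses 10,000 Monte-Carlo trios; the re-translation
oracle checks ≥ 1,000 random coding SNVs per run; the Poisson-mean check
averages 60 seeded simulations at reduced genome scale.

## Known limitations

* The annotator handles substitutions fully; indel consequences are
  classified (frameshift/in-frame) but not HGVS-named, and complex or
  multi-codon substitutions report a class without a residue-level
  protein change.
* Contig names match by exact string equality; no "chr" aliasing.
* X-chromosome-specific Mendel rules, mosaicism, and phasing-based
  parental-origin assignment are out of scope.
* The IBD estimator assumes a homogeneous reference population for its
  allele frequencies; strong structure in the panel will bias
  $\hat{\pi}$ upward for same-subpopulation pairs.
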