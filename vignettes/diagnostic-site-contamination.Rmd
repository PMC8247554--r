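---
title: "Estimating human contamination in great-ape sequencing data from clade-diagnostic sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating human contamination in great-ape sequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apecontam)
```

## The problem

Sequencing libraries from great-ape samples — especially fecal, museum and
other low-endogenous-DNA material, and anything handled by humans — are
routinely contaminated with modern human DNA. Because apes are our closest
relatives, contaminating human reads map happily to the human reference
genome alongside the host's reads, and mitochondrial fixed differences only
help when coverage of the mitochondrion is deep. `apecontam` implements an
autosomal alternative that works on sparse shotgun or capture data: score
reads at *clade-diagnostic sites*, positions where the target species
complex (e.g. *Pan* = chimpanzee + bonobo) is essentially fixed for an
allele different from the human reference while a human cohort is fixed for
the reference allele. At such sites, reads carrying the human reference
allele — more precisely, reads *not* carrying the species allele — indicate
contamination.

## The estimator

Let $d_i$ be the filtered read depth at diagnostic site $i$ and $s_i$ the
number of those reads matching the species allele. The contamination
estimate is the subtraction ratio

$$\hat c \;=\; 1 - \frac{\sum_i s_i}{\sum_i d_i},$$

pooled over all sites. The same quantity is computed per chromosome,
$\hat c_k = 1 - \sum_{i \in k} s_i / \sum_{i \in k} d_i$, and the dispersion
reported alongside the point estimate is the sample standard deviation
(denominator $n-1$) of $\{\hat c_k\}$ over chromosomes with data. The pooled
estimate is exactly the depth-weighted mean of the per-chromosome estimates —
an identity the test suite asserts on every input. The number of positions
with at least one passing read, $N$, is reported as a reliability indicator:
with very shallow data the point estimate can be trusted only to roughly a
binomial standard error $\sqrt{\hat c (1-\hat c)/\sum_i d_i}$.

Two deliberate readings of under-specified details, both switchable or
documented:

* the point estimate pools counts rather than averaging the per-chromosome
  ratios (maximum information; the unweighted mean would up-weight sparse
  chromosomes), and
* the standard deviation is the *sample* SD across chromosomes; with fewer
  than two covered chromosomes it is reported as `NA`/`null`.

Counting is over base calls: deletions and reference skips spanning a site
contribute nothing, and a third allele (neither species allele nor human
reference) counts toward contamination, consistent with the subtraction
definition. Reads that are unmapped, non-primary, duplicates, below mapping
quality 30, or from fragments shorter than 35 bp are excluded; base calls
below quality 13 (the samtools mpileup default; the method description is
silent on base quality) are ignored. Fragment length is `|TLEN|` for
properly paired reads and the aligned query length otherwise, because
"fragment/insert length" is ambiguous for single-end data. When both mates
of a pair overlap a site, both are counted by default (matching plain
mpileup without overlap removal); `dedup_overlaps = TRUE` keeps only the
higher-quality call.

## Panel building

Candidate sites come from a cohort VCF of the species complex plus a human
cohort, all mapped to the human reference. The pipeline applies, in order:

1. **Masks** — repeats and low 35-mer mappability intervals (BED, 0-based
   half-open; panel coordinates are 1-based VCF-style — conversion happens
   only at I/O boundaries).
2. **Per-genotype filters** — genotypes with depth < 6 or > 100, or mapping
   quality < 20, are set to missing. The comparatives are strict, so depths
   6 and 100 and MQ 20 pass.
3. **Biallelic restriction** — exactly one alternative allele observed
   across both cohorts, both alleles single bases. Multi-allelic records are
   rejected, not decomposed.
4. **Diagnostic criteria** — (a) at least 98% (inclusive) of the observed
   species chromosomes carry the alternative allele; (b) fewer than 5%
   (strict) of all species chromosomes are missing; (c) every human
   chromosome is observed and carries the reference allele.

The 2% allowance in (a) tolerates residual reference-like genotypes from
errors in the cohort call set; criterion (c) admits no missing human data.
Whether the 98% denominator includes missing chromosomes is not specified
anywhere authoritative; this implementation uses *observed* chromosomes
(keeping (a) and (b) orthogonal) and exposes
`alt_denominator = "total"` as the alternative. Rejections are tagged with
the first failing criterion in the order (a), (b), (c), and the panel is
restricted to autosome-named contigs by default, since sex chromosomes have
different copy number and diagnostic-density properties. Filtering order —
human filter before or after the species filters — does not change the
result; the pipeline order above is nevertheless fixed and deterministic:
identical inputs give a byte-identical panel.

## The synthetic world

Because the published panels and validation libraries hinge on external
cohort genomes and sequencing accessions, correctness is established on a
fully synthetic world with planted truth:

* **Reference + truth table**: random multi-chromosome "human reference"
  (default three 100-kb autosome-named chromosomes) with diagnostic sites
  planted at 1/500 bp (~200 per 100 kb), plus deliberately failing site
  classes — within-clade polymorphism, human polymorphism, a missing human
  genotype, genotype-filter failures pushing species missingness over 5%,
  multi-allelic sites, and diagnostic-quality sites inside a mask — so every
  rejection path is exercised. Planted sites are kept > 60 bp apart so a
  masked site's interval cannot swallow a neighbour.
* **Cohort VCF**: default 68 species and 19 human diploid individuals,
  mirroring the published *Pan*-plus-human cohort. Each failing class breaks
  exactly one criterion *by construction*, so the expected panel is implied
  directly by the planted truth; a tenth of the clean diagnostic sites carry
  one heterozygous species individual to exercise the inclusive 98%
  boundary (only planted when the cohort is large enough that it passes).
* **Reads**: exact haplotype substrings as proper pairs (insert 250–400 bp,
  so mates never overlap a site), MQ 60, Q37 bases, correct coordinates and
  TLEN. Individuals are homozygous composites (no linkage model — the
  method is single-site, so LD is irrelevant to its correctness). With
  `error_rate = 0` the pure-sample limits are exact: host reads give
  estimate 0, human reads give 1. Optional substitution errors with a
  configurable base quality, and low-MQ decoy fragments, exercise the read
  filters.

What a green test does **not** establish: behaviour under reference bias
(human-allele reads mapping preferentially, which makes real blood-sample
estimates conservative), ancient-DNA damage, capture-enrichment bias,
realistic coalescent allele-frequency spectra, or indel-containing
alignments at scale. These are properties of real data the generator does
not emulate.

## Validation machinery

`mix_alignments()` adds a seeded random subset of contaminant fragments
(mates kept together, sampling without replacement so fragment-length
semantics survive) to all host reads, targeting a contaminant share of
aligned **base pairs** — not reads — because read lengths differ between
libraries; the realized fraction is recomputed from actual bases and
reported alongside the nominal one. The simulator targets fractions
directly rather than any library-specific absolute read count.
`gradient_experiment()` spans fractions 0.1–39%, `downsample_series()`
draws production-read subsets (primary, mapped, non-duplicate) down to
~1,000 reads, and `crosstest()` runs a panel against a sample from a
different clade. Acceptance tolerances are binomial: an estimate must fall
within $4\sqrt{c(1-c)/n}$ of the realized fraction, with $n$ the observed
base count — a sampling bound, not a tuned number. The cross-clade fixture
plants the human-like allele at an exact fraction (default experiments use
0.6) of another clade's diagnostic sites, emulating the allele sharing that
produces large cross-species estimates in practice.

## Numerical and interface choices

* Reports use six significant digits and are byte-stable; TSV reports
  round-trip through `read_report()` exactly.
* Contig naming ("chr1" vs "1") is reconciled centrally with an explicit
  override; if *no* panel contig matches the alignment header the run
  aborts, since that almost always means the wrong assembly.
* The mpileup-text path parses the classic 6-column format (`^X`, `$`,
  `+n`/`-n` indels, `*` deletions, `<`/`>` skips) and must produce counts
  identical to the BAM path on the same data — asserted in the suite
  against `samtools mpileup` output with matching filters.
* Zero-coverage sites contribute nothing (they are unobserved, not zeros)
  and are excluded from $N$.
* All randomness flows from a single integer seed per operation; fixed
  seeds give byte-identical FASTA/VCF/BAM outputs.

## Limitations

The estimator attributes *any* non-species base to contamination, so
sequencing error puts a floor under estimates (~2/3 of errors at a
diagnostic site move away from the species allele); real estimates are
conservative for the same reason. Panels must be built per assembly —
coordinate liftover is out of scope. Species-of-origin assignment for
detected contamination (competitive mapping) and mitochondrial methods are
likewise out of scope; large cross-clade estimates should be followed up
with competitive mapping.
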