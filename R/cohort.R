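# Cohort genotype container: per-site diploid genotypes for a species
# complex plus a human cohort, with per-genotype depth and mapping quality.
# Alleles are stored as integer indices (0 = reference, k = k-th alternative,
# NA = missing) in site x sample matrices, which keeps panel building
# vectorised over sites.

#' Construct a cohort genotype set
#'
#' Holds genotypes of the species complex and the human cohort at candidate
#' sites, the substrate for diagnostic-site panel building. Normally built by
#' [read_cohort_vcf()]; the constructor is exported so synthetic cohorts can
#' be assembled directly.
#'
#' @param chrom,pos,ref contig name, 1-based position, reference (human)
#'   allele per site.
#' @param alt list of character vectors: alternative alleles per site.
#' @param A1,A2 integer matrices (sites x samples) of allele indices for the
#'   two chromosomes of each diploid genotype: 0 = ref, k = k-th alternative,
#'   NA = missing.
#' @param DP integer matrix of per-genotype depth.
#' @param MQ numeric matrix of per-genotype mapping quality (phred).
#' @param cohort character vector, one of "species" or "human" per sample;
#'   names are sample identifiers.
#' @return an object of class `cohort_genotypes`.
#' @export
cohort_genotypes <- function(chrom, pos, ref, alt, A1, A2, DP, MQ, cohort) {
  n <- length(pos)
  m <- length(cohort)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n,
            all(dim(A1) == c(n, m)), all(dim(A2) == c(n, m)),
            all(dim(DP) == c(n, m)), all(dim(MQ) == c(n, m)))
  pos <- as.integer(pos)
  if (n > 0L && any(pos < 1L)) stopf("positions must be >= 1")
  if (!all(cohort %in% c("species", "human")))
    stopf("cohort must be 'species' or 'human' for every sample")
  bad <- which(mapply(function(r, a) r %in% a, ref, alt, SIMPLIFY = TRUE,
                      USE.NAMES = FALSE) %in% TRUE)
  if (length(bad))
    stopf("ref allele listed among alt alleles at %s:%d", chrom[bad[1]], pos[bad[1]])
  n_alt <- lengths(alt)
  for (M in list(A1, A2)) {
    over <- which(rowSums(M > matrix(n_alt, n, m), na.rm = TRUE) > 0 |
                  rowSums(M < 0L, na.rm = TRUE) > 0)
    if (length(over))
      stopf("allele index out of range at %s:%d", chrom[over[1]], pos[over[1]])
  }
  if (any(DP < 0L, na.rm = TRUE) || any(MQ < 0, na.rm = TRUE))
    stopf("depth and mapping quality must be non-negative")
  structure(list(chrom = as.character(chrom), pos = pos,
                 ref = as.character(ref), alt = alt,
                 A1 = A1, A2 = A2, DP = DP, MQ = MQ,
                 cohort = cohort),
            class = "cohort_genotypes")
}

#' @export
length.cohort_genotypes <- function(x) length(x$pos)

#' Subset sites of a cohort genotype set
#' @param x a `cohort_genotypes` object.
#' @param i site index.
#' @param ... ignored.
#' @export
`[.cohort_genotypes` <- function(x, i, ...) {
  cohort_genotypes(x$chrom[i], x$pos[i], x$ref[i], x$alt[i],
                   x$A1[i, , drop = FALSE], x$A2[i, , drop = FALSE],
                   x$DP[i, , drop = FALSE], x$MQ[i, , drop = FALSE],
                   x$cohort)
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  cat(sprintf("cohort_genotypes: %d sites, %d species + %d human samples\n",
              length(x), sum(x$cohort == "species"), sum(x$cohort == "human")))
  invisible(x)
}

#' Read a sample-to-cohort assignment table
#'
#' Two-column tab-separated file without header: sample identifier and
#' cohort, the latter one of `species` or `human`.
#'
#' @param path file path.
#' @return named character vector of cohorts.
#' @export
read_sample_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("sample", "cohort"),
                           colClasses = "character")
  if (!all(tab$cohort %in% c("species", "human")))
    stopf("sample map cohorts must be 'species' or 'human'")
  stats::setNames(tab$cohort, tab$sample)
}

#' Read cohort genotypes from a VCF
#'
#' Loads one record per site with per-sample genotypes, depth (FORMAT/DP)
#' and mapping quality. Mapping quality is taken from a FORMAT field when
#' present, otherwise from the named INFO field (site-level, broadcast to
#' all samples).
#'
#' @param path VCF file (plain or bgzipped).
#' @param sample_map named character vector from [read_sample_map()], or a
#'   path to such a file. Samples absent from the map are dropped.
#' @param mq_field name of the mapping-quality field. Default "MQ".
#' @return a `cohort_genotypes` object, sites in file order.
#' @export
read_cohort_vcf <- function(path, sample_map, mq_field = "MQ") {
  if (is.character(sample_map) && length(sample_map) == 1L &&
      file.exists(sample_map) && is.null(names(sample_map)))
    sample_map <- read_sample_map(sample_map)
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  alt <- lapply(as.list(rr$ALT), as.character)

  gt <- VariantAnnotation::geno(vcf)$GT
  samples <- colnames(gt)
  keep <- samples %in% names(sample_map)
  if (!any(keep)) stopf("no VCF sample matches the sample map")
  gt <- gt[, keep, drop = FALSE]
  samples <- samples[keep]
  cohort <- unname(sample_map[samples])
  names(cohort) <- samples

  parse_allele <- function(k) {
    # k-th allele of "a/b" or "a|b"; "." -> NA
    part <- vapply(strsplit(gt, "[/|]"), function(p) {
      if (length(p) >= k) p[k] else "."
    }, character(1))
    suppressWarnings(matrix(as.integer(ifelse(part == ".", NA, part)),
                            nrow = nrow(gt), dimnames = dimnames(gt)))
  }
  A1 <- parse_allele(1L)
  A2 <- parse_allele(2L)

  gfields <- VariantAnnotation::geno(vcf)
  if (!"DP" %in% names(gfields))
    stopf("VCF lacks a FORMAT/DP field, needed for the depth filter")
  DP <- gfields$DP[, keep, drop = FALSE]
  storage.mode(DP) <- "integer"
  if (mq_field %in% names(gfields)) {
    MQ <- gfields[[mq_field]][, keep, drop = FALSE]
    storage.mode(MQ) <- "double"
  } else if (mq_field %in% names(VariantAnnotation::info(vcf))) {
    site_mq <- as.numeric(VariantAnnotation::info(vcf)[[mq_field]])
    MQ <- matrix(site_mq, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  } else {
    stopf("mapping-quality field '%s' found neither in FORMAT nor INFO", mq_field)
  }
  DP[is.na(DP)] <- 0L
  MQ[is.na(MQ)] <- 0
  cohort_genotypes(chrom, pos, ref, alt, A1, A2, DP, MQ, cohort)
}
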