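# Threshold configurations. Defaults are the published operating point of
# the diagnostic-site test: genotype depth in [6, 100], genotype MQ >= 20,
# species alternative-allele fraction >= 0.98, species missingness < 0.05,
# read MQ >= 30, fragment length >= 35 bp.

#' Genotype-level and site-level filter configuration for panel building
#'
#' Thresholds applied when deriving clade-diagnostic sites from cohort
#' genotypes. Per-genotype filters set individual genotypes to missing;
#' site-level criteria then decide whether a site is diagnostic.
#'
#' @param min_depth minimum per-genotype sequencing depth (reads); genotypes
#'   with depth strictly below this are set to missing. Default 6.
#' @param max_depth maximum per-genotype depth; genotypes strictly above are
#'   set to missing (collapsed repeats, CNVs). Default 100.
#' @param min_genotype_mq minimum per-genotype mapping quality (phred);
#'   genotypes strictly below are set to missing. Default 20.
#' @param min_alt_fraction minimum fraction of species chromosomes carrying
#'   the alternative (non-human-reference) allele, inclusive. Default 0.98,
#'   which tolerates residual reference-like genotypes from errors in the
#'   cohort call set.
#' @param max_species_missing maximum tolerated fraction of missing species
#'   chromosomes, exclusive (a site with exactly this fraction missing is
#'   rejected). Default 0.05.
#' @param human_missing_allowed if `FALSE` (default) a site is rejected as
#'   soon as any human genotype is missing; the human all-reference
#'   criterion admits no missing data.
#' @param alt_denominator denominator for the alternative-allele fraction:
#'   `"observed"` (default) uses non-missing species chromosomes only, so the
#'   fraction and the missingness criterion stay orthogonal; `"total"` uses
#'   all species chromosomes.
#' @return an object of class `genotype_filter_config`.
#' @export
genotype_filter_config <- function(min_depth = 6L, max_depth = 100L,
                                   min_genotype_mq = 20,
                                   min_alt_fraction = 0.98,
                                   max_species_missing = 0.05,
                                   human_missing_allowed = FALSE,
                                   alt_denominator = c("observed", "total")) {
  alt_denominator <- match.arg(alt_denominator)
  stopifnot(min_depth >= 0, max_depth >= min_depth, min_genotype_mq >= 0,
            min_alt_fraction >= 0, min_alt_fraction <= 1,
            max_species_missing >= 0, max_species_missing <= 1,
            is.logical(human_missing_allowed))
  structure(list(min_depth = as.integer(min_depth),
                 max_depth = as.integer(max_depth),
                 min_genotype_mq = min_genotype_mq,
                 min_alt_fraction = min_alt_fraction,
                 max_species_missing = max_species_missing,
                 human_missing_allowed = human_missing_allowed,
                 alt_denominator = alt_denominator),
            class = "genotype_filter_config")
}

#' Read-level filter configuration for allele counting
#'
#' Filters applied to each aligned read before it contributes a base call to
#' the pileup at diagnostic sites. Short spurious alignments (common in
#' samples dominated by bacterial DNA) are removed by the fragment-length
#' floor.
#'
#' @param min_read_mq minimum read mapping quality (phred); reads strictly
#'   below are excluded. Default 30.
#' @param min_fragment_length minimum fragment/insert length in base pairs,
#'   inclusive. For properly paired reads this is `|TLEN|`; for other reads
#'   the aligned query length is used. Default 35.
#' @param exclude_duplicates drop PCR/optical duplicate-flagged reads so the
#'   estimate reflects the unique contaminant fraction. Default `TRUE`.
#' @param exclude_secondary_supplementary drop non-primary alignments.
#'   Default `TRUE`.
#' @param exclude_unmapped drop unmapped reads. Default `TRUE`.
#' @param min_base_quality minimum base quality (phred) for a base call to be
#'   counted, inclusive. Default 13, matching the samtools mpileup default.
#' @param dedup_overlaps if `TRUE`, when both mates of a pair cover the same
#'   site only one base call is counted (the higher-quality one). Default
#'   `FALSE`: both mates count, as in plain mpileup without overlap removal.
#' @return an object of class `read_filter_config`.
#' @export
read_filter_config <- function(min_read_mq = 30, min_fragment_length = 35,
                               exclude_duplicates = TRUE,
                               exclude_secondary_supplementary = TRUE,
                               exclude_unmapped = TRUE,
                               min_base_quality = 13,
                               dedup_overlaps = FALSE) {
  stopifnot(min_read_mq >= 0, min_fragment_length >= 0, min_base_quality >= 0)
  structure(list(min_read_mq = min_read_mq,
                 min_fragment_length = min_fragment_length,
                 exclude_duplicates = exclude_duplicates,
                 exclude_secondary_supplementary = exclude_secondary_supplementary,
                 exclude_unmapped = exclude_unmapped,
                 min_base_quality = min_base_quality,
                 dedup_overlaps = dedup_overlaps),
            class = "read_filter_config")
}
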