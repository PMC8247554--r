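# Contamination estimator. At each diagnostic site the species complex
# carries the alternative allele and humans the reference; the contamination
# fraction is the proportion of filtered read bases NOT matching the species
# allele, obtained by subtracting the species-matching depth from the total
# depth. The calculation is repeated per chromosome to get a dispersion
# (one standard deviation across chromosomes); the genome-wide point
# estimate pools counts over all sites, which equals the depth-weighted
# mean of the per-chromosome estimates.

#' Estimate contamination from allele counts
#'
#' @param counts data frame from [count_alleles()] or [read_mpileup()]:
#'   columns `chrom`, `pos`, `total_depth`, `species_depth`. Sites with zero
#'   depth, if present, are dropped (they are unobserved, not zeros).
#' @return an object of class `contamination_estimate` with fields
#'   `point_estimate` (pooled, in `[0,1]`), `sd` (sample standard deviation
#'   of per-chromosome estimates; `NA` when fewer than two chromosomes have
#'   data), `n_positions` (diagnostic positions with depth >= 1) and
#'   `per_chromosome` (data frame `chrom`, `n_sites`, `total_depth`,
#'   `species_depth`, `estimate`).
#' @export
estimate_contamination <- function(counts) {
  stopifnot(all(c("chrom", "pos", "total_depth", "species_depth") %in%
                names(counts)))
  counts <- counts[counts$total_depth >= 1L, , drop = FALSE]
  if (nrow(counts) == 0L)
    stopf("no diagnostic positions observed")
  if (any(counts$species_depth > counts$total_depth |
          counts$species_depth < 0L))
    stopf("invalid counts: need 0 <= species_depth <= total_depth")

  chroms <- unique(counts$chrom)
  per <- data.frame(
    chrom = chroms,
    n_sites = as.integer(tapply(counts$total_depth >= 1L, counts$chrom, sum)[chroms]),
    total_depth = as.numeric(tapply(counts$total_depth, counts$chrom, sum)[chroms]),
    species_depth = as.numeric(tapply(counts$species_depth, counts$chrom, sum)[chroms]),
    stringsAsFactors = FALSE)
  per <- per[chrom_order(per$chrom), , drop = FALSE]
  rownames(per) <- NULL
  per$estimate <- 1 - per$species_depth / per$total_depth

  point <- 1 - sum(counts$species_depth) / sum(counts$total_depth)
  sdev <- if (nrow(per) >= 2L) stats::sd(per$estimate) else NA_real_
  structure(list(point_estimate = point, sd = sdev,
                 n_positions = nrow(counts), per_chromosome = per),
            class = "contamination_estimate")
}

#' @export
print.contamination_estimate <- function(x, ...) {
  cat(sprintf("contamination estimate: %.4g%% (+/- %s%%) over %d positions, %d chromosome(s)\n",
              100 * x$point_estimate,
              if (is.na(x$sd)) "NA" else sprintf("%.4g", 100 * x$sd),
              x$n_positions, nrow(x$per_chromosome)))
  invisible(x)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}

#' Write a contamination report
#'
#' TSV: one line per chromosome (`chrom`, `n_sites`, `total_depth`,
#' `species_depth`, `estimate`) plus a final `GENOME` line whose estimate
#' column is the pooled point estimate and whose last column carries the
#' across-chromosome standard deviation (`NA` with fewer than two
#' chromosomes). JSON: `point_estimate`, `sd` (null when undefined),
#' `n_positions`, `per_chromosome`. Numbers use six significant digits;
#' output is byte-stable for identical input.
#'
#' @param estimate a `contamination_estimate`.
#' @param path output file.
#' @param format "tsv" or "json".
#' @export
write_report <- function(estimate, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(estimate, "contamination_estimate"))
  if (format == "tsv") {
    per <- estimate$per_chromosome
    lines <- c(
      "chrom\tn_sites\ttotal_depth\tspecies_depth\testimate\tsd",
      sprintf("%s\t%d\t%d\t%d\t%s\tNA", per$chrom, per$n_sites,
              as.integer(per$total_depth), as.integer(per$species_depth),
              fmt_num(per$estimate)),
      sprintf("GENOME\t%d\t%d\t%d\t%s\t%s",
              estimate$n_positions,
              as.integer(sum(per$total_depth)),
              as.integer(sum(per$species_depth)),
              fmt_num(estimate$point_estimate),
              fmt_num(estimate$sd)))
    writeLines(lines, path)
  } else {
    obj <- list(point_estimate = as.numeric(fmt_num(estimate$point_estimate)),
                sd = if (is.na(estimate$sd)) NULL
                     else as.numeric(fmt_num(estimate$sd)),
                n_positions = estimate$n_positions,
                per_chromosome = transform(estimate$per_chromosome,
                                           estimate = as.numeric(fmt_num(estimate))))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read back a TSV contamination report
#'
#' Inverse of [write_report()] for the TSV format; re-serialising the
#' result reproduces the file byte for byte.
#'
#' @param path report path.
#' @return a `contamination_estimate`.
#' @export
read_report <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "integer", "numeric",
                                          "numeric", "numeric", "numeric"))
  gen <- tab[tab$chrom == "GENOME", , drop = FALSE]
  per <- tab[tab$chrom != "GENOME", c("chrom", "n_sites", "total_depth",
                                      "species_depth", "estimate")]
  rownames(per) <- NULL
  structure(list(point_estimate = gen$estimate[1],
                 sd = gen$sd[1],
                 n_positions = gen$n_sites[1],
                 per_chromosome = per),
            class = "contamination_estimate")
}

#' One-call contamination test on an alignment
#'
#' Convenience wrapper: count alleles at the panel sites and estimate
#' contamination. This is also the entry point for cross-clade testing —
#' supplying a panel built for a different clade than the sample measures
#' the fraction of reads not carrying that clade's diagnostic alleles.
#'
#' @inheritParams count_alleles
#' @return a `contamination_estimate`.
#' @export
contamination_test <- function(bam, panel, config = read_filter_config(),
                               contig_style = "auto", reference = NULL) {
  estimate_contamination(
    count_alleles(bam, panel, config, contig_style, reference))
}
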