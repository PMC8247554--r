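# Diagnostic-site panel builder. A site is clade-diagnostic when, after
# per-genotype filtering, (a) at least `min_alt_fraction` of the species
# complex chromosomes carry the single alternative allele, (b) fewer than
# `max_species_missing` of the species chromosomes are missing, and (c)
# every human chromosome is observed and carries the human reference allele.
# Reads carrying the reference allele at such sites indicate human
# contamination.

#' Apply per-genotype depth and mapping-quality filters
#'
#' Sets a genotype (both alleles) to missing when its depth is strictly
#' below `min_depth`, strictly above `max_depth`, or its mapping quality is
#' strictly below `min_genotype_mq`; boundary values pass. All other
#' genotypes are untouched.
#'
#' @param x a [cohort_genotypes()] object.
#' @param config a [genotype_filter_config()].
#' @return the filtered `cohort_genotypes` object.
#' @export
apply_genotype_filters <- function(x, config = genotype_filter_config()) {
  stopifnot(inherits(x, "cohort_genotypes"),
            inherits(config, "genotype_filter_config"))
  drop <- x$DP < config$min_depth | x$DP > config$max_depth |
          x$MQ < config$min_genotype_mq
  x$A1[drop] <- NA_integer_
  x$A2[drop] <- NA_integer_
  x
}

# Per-site allele bookkeeping on the (already filtered) allele matrices.
# Returns one row per site.
site_allele_stats <- function(x) {
  sp <- x$cohort == "species"
  hu <- x$cohort == "human"
  n <- length(x)
  A1s <- x$A1[, sp, drop = FALSE]; A2s <- x$A2[, sp, drop = FALSE]
  A1h <- x$A1[, hu, drop = FALSE]; A2h <- x$A2[, hu, drop = FALSE]

  max_alt <- max(1L, lengths(x$alt), na.rm = TRUE)
  alt_obs <- matrix(0L, n, max_alt)      # observed count of alt k, all cohorts
  sp_alt <- matrix(0L, n, max_alt)       # observed count of alt k, species only
  for (k in seq_len(max_alt)) {
    alt_obs[, k] <- rowSums(x$A1 == k, na.rm = TRUE) +
                    rowSums(x$A2 == k, na.rm = TRUE)
    sp_alt[, k] <- rowSums(A1s == k, na.rm = TRUE) +
                   rowSums(A2s == k, na.rm = TRUE)
  }
  n_distinct_alt <- rowSums(alt_obs > 0L)
  # index of the single observed alt (valid only where n_distinct_alt == 1)
  alt_index <- max.col(alt_obs, ties.method = "first")
  alt_index[n_distinct_alt == 0L] <- NA_integer_

  species_total <- 2L * sum(sp)
  species_missing <- rowSums(is.na(A1s)) + rowSums(is.na(A2s))
  species_obs <- species_total - species_missing
  species_alt <- sp_alt[cbind(seq_len(n), ifelse(is.na(alt_index), 1L, alt_index))]
  species_alt[is.na(alt_index)] <- 0L

  human_missing <- rowSums(is.na(A1h)) + rowSums(is.na(A2h))
  human_nonref <- rowSums(A1h != 0L, na.rm = TRUE) +
                  rowSums(A2h != 0L, na.rm = TRUE)

  alt_base <- rep(NA_character_, n)
  has_alt <- which(!is.na(alt_index))
  alt_base[has_alt] <- vapply(has_alt, function(i) {
    k <- alt_index[i]
    if (k <= length(x$alt[[i]])) x$alt[[i]][k] else NA_character_
  }, character(1))
  data.frame(n_distinct_alt = n_distinct_alt, alt_index = alt_index,
             alt_base = alt_base,
             species_total = species_total, species_obs = species_obs,
             species_missing = species_missing, species_alt = species_alt,
             human_missing = human_missing, human_nonref = human_nonref,
             stringsAsFactors = FALSE)
}

#' Test whether sites are biallelic SNPs
#'
#' A site qualifies when exactly one alternative allele is observed across
#' the species and human cohorts combined, and both the reference and that
#' alternative allele are single bases (no indels).
#'
#' @inheritParams apply_genotype_filters
#' @return logical vector, one element per site.
#' @export
is_biallelic_snp <- function(x) {
  stopifnot(inherits(x, "cohort_genotypes"))
  st <- site_allele_stats(x)
  st$n_distinct_alt == 1L & nchar(x$ref) == 1L &
    !is.na(st$alt_base) & nchar(st$alt_base) == 1L
}

#' Classify sites as diagnostic or rejected
#'
#' Applies the three diagnostic criteria in order and labels each site
#' `"diagnostic"` or with the first failing criterion:
#' `"not_biallelic"`, `"species_alt_fraction"`, `"species_missingness"`,
#' `"human_not_ref"`.
#'
#' @inheritParams apply_genotype_filters
#' @return character vector of statuses, one per site.
#' @export
classify_sites <- function(x, config = genotype_filter_config()) {
  stopifnot(inherits(x, "cohort_genotypes"),
            inherits(config, "genotype_filter_config"))
  if (sum(x$cohort == "species") == 0L) stopf("species cohort is empty")
  st <- site_allele_stats(x)
  biallelic <- is_biallelic_snp(x)

  denom <- if (config$alt_denominator == "observed") st$species_obs
           else st$species_total
  alt_frac <- ifelse(denom > 0L, st$species_alt / denom, 0)
  miss_frac <- st$species_missing / st$species_total
  human_ok <- st$human_nonref == 0L &
    (config$human_missing_allowed | st$human_missing == 0L)

  status <- rep("diagnostic", length(x))
  status[!human_ok] <- "human_not_ref"
  status[miss_frac >= config$max_species_missing] <- "species_missingness"
  status[alt_frac < config$min_alt_fraction] <- "species_alt_fraction"
  status[!biallelic] <- "not_biallelic"
  status
}

#' Classify a single site
#'
#' Single-record interface over [classify_sites()]: expects genotype filters
#' already applied and the site outside all masks.
#'
#' @param record a one-site [cohort_genotypes()] object.
#' @inheritParams apply_genotype_filters
#' @return for a diagnostic site, a one-row data frame with columns
#'   `chrom`, `pos`, `ref` (human reference allele) and `alt` (species
#'   alternative allele); otherwise a list with elements `rejected = TRUE`
#'   and `reason`.
#' @export
classify_site <- function(record, config = genotype_filter_config()) {
  stopifnot(length(record) == 1L)
  status <- classify_sites(record, config)
  if (status == "diagnostic") {
    st <- site_allele_stats(record)
    data.frame(chrom = record$chrom, pos = record$pos, ref = record$ref,
               alt = st$alt_base, stringsAsFactors = FALSE)
  } else {
    list(rejected = TRUE, reason = status)
  }
}

#' Build a diagnostic-site panel from cohort genotypes
#'
#' Runs the full pipeline: mask exclusion, per-genotype filtering,
#' biallelic-SNP restriction, and the three diagnostic criteria. The input
#' must be sorted by (chromosome, position) with unique positions; the
#' output panel preserves that order, so the run is fully deterministic.
#'
#' @param x a [cohort_genotypes()] object, sites sorted by (chromosome,
#'   position).
#' @param masks a GRanges (or list of GRanges) of excluded intervals, e.g.
#'   repeats and low 35-mer mappability, or `NULL`.
#' @param config a [genotype_filter_config()].
#' @param autosomes_only restrict the panel to numerically named
#'   (autosomal) contigs. Default `TRUE`.
#' @return a list of class `diagnostic_panel` with elements `panel` (data
#'   frame `chrom`, `pos`, `ref`, `alt`) and `summary` (named counts:
#'   sites examined, rejected per reason, retained).
#' @export
build_panel <- function(x, masks = NULL, config = genotype_filter_config(),
                        autosomes_only = TRUE) {
  stopifnot(inherits(x, "cohort_genotypes"))
  check_sorted(x$chrom, x$pos)

  n <- length(x)
  status <- rep(NA_character_, n)
  if (autosomes_only) status[!is_autosome(x$chrom)] <- "not_autosome"
  if (!is.null(masks)) {
    masked <- in_mask(x$chrom, x$pos, masks)
    status[is.na(status) & masked] <- "masked"
  }
  todo <- which(is.na(status))
  if (length(todo)) {
    xf <- apply_genotype_filters(x[todo], config)
    status[todo] <- classify_sites(xf, config)
  }

  keep <- which(status == "diagnostic")
  if (length(keep)) {
    st <- site_allele_stats(apply_genotype_filters(x[keep], config))
    panel <- data.frame(chrom = x$chrom[keep], pos = x$pos[keep],
                        ref = x$ref[keep], alt = st$alt_base,
                        stringsAsFactors = FALSE)
  } else {
    panel <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        stringsAsFactors = FALSE)
  }
  reasons <- c("not_autosome", "masked", "not_biallelic",
               "species_alt_fraction", "species_missingness", "human_not_ref")
  summary <- c(examined = n,
               stats::setNames(vapply(reasons, function(r) sum(status == r), 0L),
                               paste0("rejected_", reasons)),
               retained = length(keep))
  structure(list(panel = panel, summary = summary), class = "diagnostic_panel")
}

check_sorted <- function(chrom, pos) {
  if (!length(pos)) return(invisible(TRUE))
  r <- rle(chrom)
  if (any(duplicated(r$values)))
    stopf("input records not sorted: chromosome %s appears in disjoint blocks",
          r$values[duplicated(r$values)][1])
  samechrom <- chrom[-1] == chrom[-length(chrom)]
  nondec <- which(samechrom & diff(pos) <= 0L) + 1L
  if (length(nondec))
    stopf("input records not sorted (or duplicated) at %s:%d",
          chrom[nondec[1]], pos[nondec[1]])
  invisible(TRUE)
}

#' @export
print.diagnostic_panel <- function(x, ...) {
  cat(sprintf("diagnostic_panel: %d sites retained of %d examined\n",
              x$summary[["retained"]], x$summary[["examined"]]))
  rej <- x$summary[grep("^rejected_", names(x$summary))]
  rej <- rej[rej > 0]
  if (length(rej)) {
    cat("rejections:\n")
    for (i in seq_along(rej))
      cat(sprintf("  %-24s %d\n", sub("rejected_", "", names(rej)[i]), rej[i]))
  }
  invisible(x)
}

#' Write / read a diagnostic-site panel
#'
#' Tab-separated with header `chrom  pos  ref  alt`; positions 1-based.
#'
#' @param panel a `diagnostic_panel` or its `panel` data frame.
#' @param path output path (".gz" suffix writes gzip).
#' @export
write_panel <- function(panel, path) {
  if (inherits(panel, "diagnostic_panel")) panel <- panel$panel
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(panel, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @return `read_panel()` returns the panel data frame.
#' @export
read_panel <- function(path) {
  panel <- utils::read.table(path, sep = "\t", header = TRUE,
                             colClasses = c("character", "integer",
                                            "character", "character"))
  if (!identical(names(panel), c("chrom", "pos", "ref", "alt")))
    stopf("panel %s lacks the expected header 'chrom pos ref alt'", path)
  if (any(panel$ref == panel$alt))
    stopf("panel %s has sites where ref equals alt", path)
  check_sorted(panel$chrom, panel$pos)
  panel
}
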