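# In-silico contamination machinery: mixes reads from a host and a
# contaminant alignment at a target BASE-PAIR fraction (not read counts,
# since read lengths differ between libraries), runs contamination
# gradients, cross-clade tests and downsampling series. Every stochastic
# step is seeded; a fixed seed reproduces the mixture byte for byte.

#' Mix host and contaminant alignments at a base-pair fraction
#'
#' All host reads are kept; a seeded random subset of contaminant
#' fragments (mate pairs kept or dropped together) is added so that the
#' contaminant share of aligned base pairs is as close to
#' `target_fraction` as fragment granularity allows. The realized fraction
#' is computed from the actual aligned bases and returned alongside.
#'
#' @param host,contaminant paths to BAM files over the same reference, or
#'   pre-parsed sources from [parse_alignment_source()] (used by
#'   [gradient_experiment()] to avoid re-reading per fraction).
#' @param target_fraction desired contaminant base-pair fraction in
#'   `[0, 1)`.
#' @param seed integer seed.
#' @param out_bam output path; written coordinate-sorted and indexed.
#' @param max_reads optional cap on contaminant fragments considered.
#' @return list with `bam`, `realized_fraction`, `host_bp`,
#'   `contaminant_bp`, `n_host_reads`, `n_contaminant_reads`.
#' @export
mix_alignments <- function(host, contaminant, target_fraction, seed = 1L,
                           out_bam = tempfile(fileext = ".bam"),
                           max_reads = NULL) {
  stopifnot(target_fraction >= 0, target_fraction < 1)
  h <- parse_alignment_source(host)
  host_bp <- sum(sam_aligned_bp(h$body))

  if (target_fraction == 0) {
    sam_to_bam(h$header, h$body, out_bam)
    return(list(bam = out_bam, realized_fraction = 0,
                host_bp = host_bp, contaminant_bp = 0L,
                n_host_reads = length(h$body), n_contaminant_reads = 0L))
  }

  cont <- parse_alignment_source(contaminant)
  if (!all(sam_header_contigs(cont$header) %in% sam_header_contigs(h$header)))
    stopf("host and contaminant alignments use different references")

  qname <- sam_field(cont$body, 1L)
  frag <- split(seq_along(cont$body), qname)
  if (!is.null(max_reads)) frag <- frag[seq_len(min(length(frag), max_reads))]
  frag_bp <- unname(vapply(frag, function(i) sum(sam_aligned_bp(cont$body[i])), 0))

  target_bp <- target_fraction / (1 - target_fraction) * host_bp
  max_frac <- sum(frag_bp) / (host_bp + sum(frag_bp))
  if (sum(frag_bp) < target_bp && abs(max_frac - target_fraction) > 0.001)
    stopf("contaminant source too small: maximum achievable fraction is %.4g",
          max_frac)

  set.seed(seed)
  ord <- sample.int(length(frag))
  cum <- cumsum(frag_bp[ord])
  k <- findInterval(target_bp, cum) # fragments strictly below target
  # read granularity: pick whichever of k / k+1 fragments lands closer
  frac_at <- function(kk) {
    bp <- if (kk == 0L) 0 else cum[kk]
    bp / (host_bp + bp)
  }
  if (k < length(frag) &&
      abs(frac_at(k + 1L) - target_fraction) < abs(frac_at(k) - target_fraction))
    k <- k + 1L
  sel <- ord[seq_len(k)]
  sel_rows <- unlist(frag[sel], use.names = FALSE)
  cont_bp <- if (k == 0L) 0 else cum[k]

  sam_to_bam(h$header, c(h$body, cont$body[sel_rows]), out_bam)
  list(bam = out_bam,
       realized_fraction = cont_bp / (host_bp + cont_bp),
       host_bp = host_bp, contaminant_bp = cont_bp,
       n_host_reads = length(h$body), n_contaminant_reads = length(sel_rows))
}

#' Contamination gradient experiment
#'
#' Mixes the contaminant into the host at each nominal fraction and runs
#' the contamination test, mirroring the published in-silico validation
#' gradient (~0.1% to ~39%).
#'
#' @param host,contaminant BAM paths.
#' @param fractions ascending numeric vector of nominal base-pair
#'   fractions.
#' @param panel diagnostic-site panel data frame.
#' @param config a [read_filter_config()].
#' @param seed integer seed (one derived seed per fraction).
#' @return data frame with one row per fraction: `nominal`, `realized`,
#'   `estimate`, `sd`, `n_positions`.
#' @export
gradient_experiment <- function(host, contaminant, fractions, panel,
                                config = read_filter_config(), seed = 1L) {
  stopifnot(!is.unsorted(fractions))
  host <- parse_alignment_source(host)
  contaminant <- parse_alignment_source(contaminant)
  rows <- lapply(seq_along(fractions), function(i) {
    out <- tempfile(fileext = ".bam")
    on.exit(unlink(c(out, paste0(out, ".bai"))), add = TRUE)
    mx <- mix_alignments(host, contaminant, fractions[i],
                         seed = seed * 1000L + i, out_bam = out)
    est <- contamination_test(mx$bam, panel, config)
    data.frame(nominal = fractions[i], realized = mx$realized_fraction,
               estimate = est$point_estimate, sd = est$sd,
               n_positions = est$n_positions,
               total_depth = sum(est$per_chromosome$total_depth))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Pre-parse an alignment for repeated mixing
#'
#' Reads a BAM into its SAM-text representation once, so that
#' [mix_alignments()] can be called repeatedly without re-reading the file.
#'
#' @param x BAM path, or an already parsed source (returned unchanged).
#' @return an object of class `alignment_source`.
#' @export
parse_alignment_source <- function(x) {
  if (inherits(x, "alignment_source")) return(x)
  structure(bam_to_sam(x), class = "alignment_source")
}

#' Cross-clade contamination test
#'
#' Runs the standard contamination test on a sample from one clade against
#' a panel built for another clade. Where the sampled clade shares the
#' human-like allele at a fraction f of the panel's diagnostic sites, the
#' expected estimate is ~f — large apparent "contamination" flags a sample
#' from the wrong clade.
#'
#' @param bam sample alignment.
#' @param panel panel for a (possibly different) clade.
#' @param config a [read_filter_config()].
#' @return a `contamination_estimate`.
#' @export
crosstest <- function(bam, panel, config = read_filter_config()) {
  contamination_test(bam, panel, config)
}

#' Downsampling robustness series
#'
#' Draws seeded random subsets of the source's production reads (primary,
#' mapped, non-duplicate; mates kept together) at each target read count
#' and re-estimates contamination, emulating shallow-sequencing conditions
#' down to ~1,000 reads.
#'
#' @param bam source alignment with known or previously estimated
#'   contamination.
#' @param target_read_counts descending vector of production-read targets.
#' @param replicates replicate subsets per target.
#' @param panel diagnostic-site panel data frame.
#' @param config a [read_filter_config()].
#' @param seed integer seed.
#' @return data frame: `target_reads`, `replicate`, `realized_reads`,
#'   `estimate`, `sd`, `n_positions`.
#' @export
downsample_series <- function(bam, target_read_counts, replicates = 1L,
                              panel, config = read_filter_config(),
                              seed = 1L) {
  stopifnot(replicates >= 1L, all(target_read_counts >= 1))
  src <- bam_to_sam(bam)
  production <- sam_is_production(src$body)
  n_prod <- sum(production)
  if (any(target_read_counts > n_prod))
    stopf("target read count exceeds the %d production reads in the source",
          n_prod)
  body <- src$body[production]
  qname <- sam_field(body, 1L)
  frag <- split(seq_along(body), qname)
  frag_reads <- lengths(frag)

  rows <- list()
  for (ti in seq_along(target_read_counts)) {
    target <- target_read_counts[ti]
    for (rep in seq_len(replicates)) {
      set.seed(seed + 7919L * ti + rep)
      if (target == n_prod) {
        sel_rows <- seq_along(body)
      } else {
        ord <- sample.int(length(frag))
        cum <- cumsum(frag_reads[ord])
        k <- findInterval(target, cum)
        if (k < length(frag) && abs(cum[k + 1L] - target) < abs(ifelse(k == 0L, 0L, cum[k]) - target))
          k <- k + 1L
        sel_rows <- unlist(frag[ord[seq_len(max(k, 1L))]], use.names = FALSE)
      }
      out <- tempfile(fileext = ".bam")
      sam_to_bam(src$header, body[sel_rows], out)
      est <- contamination_test(out, panel, config)
      unlink(c(out, paste0(out, ".bai")))
      rows[[length(rows) + 1L]] <-
        data.frame(target_reads = target, replicate = rep,
                   realized_reads = length(sel_rows),
                   estimate = est$point_estimate, sd = est$sd,
                   n_positions = est$n_positions)
    }
  }
  do.call(rbind, rows)
}
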