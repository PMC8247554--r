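# Allele counting at diagnostic sites. Two input paths produce the same
# per-site counts: a direct BAM pileup (per-read filters, CIGAR-aware
# base extraction) and a parser for samtools-mpileup text. Counts feed the
# contamination estimator: reads NOT carrying the species alternative allele
# at diagnostic sites are attributed to contamination.

#' Per-read filter decisions
#'
#' Applies the read-level filters to a table of alignment fields and returns
#' which reads survive. Fragment length is `|TLEN|` for properly paired
#' reads and the aligned query length (CIGAR M/I/=/X, soft clips excluded)
#' otherwise; the floor is inclusive, so a 35-bp fragment passes the default.
#'
#' @param reads data frame with columns `flag` (SAM bitflag), `mapq`,
#'   `isize` (template length, may be NA) and `cigar`.
#' @param config a [read_filter_config()].
#' @return logical vector: `TRUE` for reads that pass every enabled filter.
#' @export
filter_read <- function(reads, config = read_filter_config()) {
  stopifnot(inherits(config, "read_filter_config"),
            all(c("flag", "mapq", "isize", "cigar") %in% names(reads)))
  flag <- as.integer(reads$flag)
  keep <- rep(TRUE, nrow(reads))
  if (config$exclude_unmapped)
    keep <- keep & bitwAnd(flag, 4L) == 0L
  if (config$exclude_secondary_supplementary)
    keep <- keep & bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  if (config$exclude_duplicates)
    keep <- keep & bitwAnd(flag, 1024L) == 0L
  keep <- keep & !is.na(reads$mapq) & reads$mapq >= config$min_read_mq

  proper <- bitwAnd(flag, 1L) != 0L & bitwAnd(flag, 2L) != 0L &
            !is.na(reads$isize) & reads$isize != 0L
  fraglen <- ifelse(proper, abs(reads$isize),
                    GenomicAlignments::cigarWidthAlongQuerySpace(
                      reads$cigar, after.soft.clipping = TRUE))
  keep & fraglen >= config$min_fragment_length
}

#' Count filtered read bases at diagnostic sites in a BAM
#'
#' Pileup restricted to panel positions: every passing read contributes at
#' most one base call per site (deletions and reference skips spanning the
#' site contribute nothing). Base calls below `min_base_quality` are
#' discarded. Only sites with at least one passing call are reported.
#' CRAM input should be converted to BAM first (e.g. `samtools view -b`);
#' the mpileup-text path ([read_mpileup()]) accepts pileups generated from
#' CRAM directly.
#'
#' @param bam path to a coordinate-sorted, indexed BAM.
#' @param panel panel data frame from [read_panel()] / [build_panel()].
#' @param config a [read_filter_config()].
#' @param contig_style how to reconcile panel contig names with the
#'   alignment's ("auto" tries as-is, adding and stripping "chr").
#' @param reference FASTA path (reserved for future CRAM support; unused
#'   for BAM).
#' @return data frame of allele counts: `chrom`, `pos` (panel naming),
#'   `total_depth`, `species_depth` with `0 <= species_depth <= total_depth`.
#' @export
count_alleles <- function(bam, panel, config = read_filter_config(),
                          contig_style = "auto", reference = NULL) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(panel)))
  bf <- open_alignment(bam, reference)
  header_contigs <- names(Rsamtools::scanBamHeader(bf)$targets)
  aln_chrom <- reconcile_contigs(panel$chrom, header_contigs, contig_style)

  out <- vector("list", 0L)
  for (chr in unique(aln_chrom)) {
    if (!chr %in% header_contigs) next
    idx <- which(aln_chrom == chr)
    counts <- pileup_chromosome(bf, chr, panel$pos[idx], panel$alt[idx], config)
    if (!is.null(counts)) {
      counts$chrom <- panel$chrom[idx][counts$site]
      out[[length(out) + 1L]] <- counts[counts$total_depth > 0L,
                                        c("chrom", "pos", "total_depth",
                                          "species_depth")]
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos = integer(),
                      total_depth = integer(), species_depth = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

open_alignment <- function(bam, reference = NULL) {
  if (!file.exists(bam)) stopf("alignment file not found: %s", bam)
  idx <- paste0(bam, if (grepl("\\.cram$", bam)) ".crai" else ".bai")
  if (!file.exists(idx) && !file.exists(sub("\\.[^.]+$", ".bai", bam)))
    stopf("alignment index not found for %s (expected %s)", bam, idx)
  Rsamtools::BamFile(bam)
}

# pileup over one chromosome's panel positions; returns per-site counts
pileup_chromosome <- function(bf, chr, pos, alt, config) {
  which <- GenomicRanges::GRanges(chr, IRanges::IRanges(min(pos), max(pos)))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq", "isize", "seq", "qual"),
    which = which)
  ga <- GenomicAlignments::readGAlignments(bf, param = param)
  if (length(ga) == 0L) return(NULL)

  md <- S4Vectors::mcols(ga)
  reads <- data.frame(flag = md$flag, mapq = md$mapq, isize = md$isize,
                      cigar = GenomicAlignments::cigar(ga))
  ga <- ga[filter_read(reads, config)]
  if (length(ga) == 0L) return(NULL)
  md <- S4Vectors::mcols(ga)
  cig <- GenomicAlignments::cigar(ga)

  ops <- c("M", "=", "X")
  refblocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = IRanges::start(ga), ops = ops)
  qryblocks <- GenomicAlignments::cigarRangesAlongQuerySpace(cig, ops = ops)
  ref_flat <- unlist(refblocks)
  qry_flat <- unlist(qryblocks)
  block_read <- rep(seq_along(ga), S4Vectors::elementNROWS(refblocks))

  hits <- IRanges::findOverlaps(IRanges::IRanges(pos, pos), ref_flat)
  if (length(hits) == 0L) return(NULL)
  site <- S4Vectors::queryHits(hits)
  blk <- S4Vectors::subjectHits(hits)
  readidx <- block_read[blk]
  qpos <- IRanges::start(qry_flat)[blk] +
          (pos[site] - IRanges::start(ref_flat)[blk])

  base <- as.character(Biostrings::subseq(md$seq[readidx], qpos, qpos))
  qualchr <- as.character(Biostrings::subseq(md$qual[readidx], qpos, qpos))
  qual <- utf8ToInt(paste(qualchr, collapse = "")) - 33L

  ok <- qual >= config$min_base_quality
  site <- site[ok]; base <- base[ok]; qual <- qual[ok]
  qname <- md$qname[readidx][ok]
  if (!length(site)) return(NULL)

  if (config$dedup_overlaps) {
    key <- paste(site, qname)
    o <- order(key, -qual)
    first <- !duplicated(key[o])
    keep <- sort(o[first])
    site <- site[keep]; base <- base[keep]
  }

  total <- tabulate(site, nbins = length(pos))
  is_species <- toupper(base) == alt[site]
  species <- tabulate(site[is_species], nbins = length(pos))
  data.frame(site = seq_along(pos), pos = pos,
             total_depth = total, species_depth = species)
}

#' Count alleles from samtools-mpileup text
#'
#' Parses the classic 6-column mpileup format (chrom, pos, ref, depth, read
#' bases, base qualities), handling `^X`/`$` read boundaries, `+n`/`-n`
#' indel insertions, `*` deletion placeholders and `<`/`>` reference skips.
#' Deletions and skips are not counted as base calls. Only panel positions
#' are returned; read-level filtering (mapping quality, flags) must have
#' been applied when the pileup was generated, base quality is filtered
#' here.
#'
#' @param path mpileup text file, or a connection (e.g. stdin).
#' @param panel panel data frame.
#' @param min_base_quality phred floor for counting a base call, inclusive.
#' @return data frame as [count_alleles()].
#' @export
read_mpileup <- function(path, panel, min_base_quality = 13) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(chrom = character(), pos = integer(),
                      total_depth = integer(), species_depth = integer(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    # depth-0 lines may have missing base/qual columns; pad them
    fields[nf < 6L] <- lapply(fields[nf < 6L], function(f) c(f, "*", "*")[1:6])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  pos <- as.integer(vapply(fields, `[[`, "", 2L))
  bases <- vapply(fields, `[[`, "", 5L)
  quals <- vapply(fields, `[[`, "", 6L)

  key <- paste(chrom, pos)
  pkey <- paste(panel$chrom, panel$pos)
  m <- match(key, pkey)
  keep <- !is.na(m)
  if (!any(keep)) return(empty)

  res <- mapply(function(b, q, alt) {
    parsed <- parse_pileup_bases(b)
    if (!length(parsed)) return(c(0L, 0L))
    qv <- utf8ToInt(q) - 33L
    if (length(qv) != length(parsed))
      stopf("mpileup base/quality length mismatch ('%s' vs '%s')", b, q)
    call <- parsed %in% c(".", ",", "A", "C", "G", "T", "N",
                          "a", "c", "g", "t", "n") & qv >= min_base_quality
    c(sum(call), sum(call & toupper(parsed) == alt))
  }, bases[keep], quals[keep], panel$alt[m[keep]], SIMPLIFY = FALSE)
  res <- do.call(rbind, res)

  out <- data.frame(chrom = chrom[keep], pos = pos[keep],
                    total_depth = as.integer(res[, 1L]),
                    species_depth = as.integer(res[, 2L]),
                    stringsAsFactors = FALSE)
  out <- out[out$total_depth > 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# split an mpileup base string into one symbol per pileup entry
# (entries: . , ACGTN acgtn * > <), dropping ^X, $ and indel runs
parse_pileup_bases <- function(s) {
  if (s == "*" || !nzchar(s)) return(character())
  chars <- strsplit(s, "")[[1]]
  out <- character(length(chars))
  n_out <- 0L
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L                     # start marker + mapq char
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= length(chars) && grepl("[0-9]", chars[j])) j <- j + 1L
      nins <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + nins                   # skip the inserted/deleted sequence
    } else {
      n_out <- n_out + 1L
      out[n_out] <- ch
      i <- i + 1L
    }
  }
  out[seq_len(n_out)]
}
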