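# Genomic masks (repeats, 35-mer mappability): BED intervals excluded from
# panels. BED is 0-based half-open; panel positions are 1-based. The
# conversion happens here and nowhere else.

#' Read a genomic mask from a BED file
#'
#' @param path BED file (first three columns used).
#' @return a [GenomicRanges::GRanges] of the masked intervals (1-based,
#'   closed, as GRanges convention).
#' @export
read_mask_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          rep("NULL", max(0, count_bed_cols(path) - 3L))))
  if (any(bed[[2]] < 0L) || any(bed[[3]] <= bed[[2]]))
    stopf("malformed BED interval in %s (need 0 <= start < end)", path)
  GenomicRanges::GRanges(bed[[1]], IRanges::IRanges(bed[[2]] + 1L, bed[[3]]))
}

count_bed_cols <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) return(3L)
  length(strsplit(first, "\t")[[1]])
}

#' Write mask intervals to BED
#' @param mask a GRanges (1-based, closed).
#' @param path output BED path (written 0-based half-open).
#' @export
write_mask_bed <- function(mask, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(mask)),
                   start = GenomicRanges::start(mask) - 1L,
                   end = GenomicRanges::end(mask))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Test positions against masks
#'
#' @param chrom,pos contig names and 1-based positions.
#' @param masks a GRanges, or a list of GRanges which are combined.
#' @return logical: `TRUE` where the position falls inside any mask.
#' @export
in_mask <- function(chrom, pos, masks) {
  if (is.list(masks)) masks <- do.call(c, unname(masks))
  if (length(masks) == 0L) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  GenomicRanges::countOverlaps(q, masks) > 0L
}
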