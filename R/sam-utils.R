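# Internal SAM-text plumbing shared by the fixture generator and the
# in-silico mixer. Alignments are manipulated as SAM lines (text is the
# deliverable-friendly form) and converted to sorted, indexed BAM via
# Rsamtools.

# Write SAM lines (header + body) to a sorted, indexed BAM.
# Returns the BAM path ("<prefix>.bam", with "<prefix>.bam.bai").
sam_to_bam <- function(header, body, out_bam) {
  stopifnot(grepl("\\.bam$", out_bam))
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  writeLines(c(header, body), sam)
  tmp_bam <- tempfile(fileext = ".bam")
  on.exit(unlink(tmp_bam), add = TRUE)
  Rsamtools::asBam(sam, sub("\\.bam$", "", tmp_bam), overwrite = TRUE,
                   indexDestination = FALSE)
  Rsamtools::sortBam(tmp_bam, sub("\\.bam$", "", out_bam))
  Rsamtools::indexBam(out_bam)
  invisible(out_bam)
}

# Read a BAM back into SAM lines: list(header=..., body=...)
bam_to_sam <- function(bam) {
  sam <- Rsamtools::asSam(bam, tempfile(), overwrite = TRUE)
  on.exit(unlink(sam), add = TRUE)
  lines <- readLines(sam)
  is_header <- startsWith(lines, "@")
  list(header = lines[is_header], body = lines[!is_header])
}

sam_field <- function(body, i) {
  vapply(strsplit(body, "\t"), `[[`, "", i)
}

# aligned query bases (CIGAR M/I/=/X) per SAM body line; the base-pair
# currency used for mixture fraction accounting
sam_aligned_bp <- function(body) {
  cig <- sam_field(body, 6L)
  bp <- integer(length(cig))
  aligned <- cig != "*"
  bp[aligned] <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cig[aligned], after.soft.clipping = TRUE)
  bp
}

sam_flag <- function(body) as.integer(sam_field(body, 2L))

# primary, mapped, non-duplicate records ("production reads")
sam_is_production <- function(body) {
  flag <- sam_flag(body)
  bitwAnd(flag, 4L) == 0L & bitwAnd(flag, 256L) == 0L &
    bitwAnd(flag, 2048L) == 0L & bitwAnd(flag, 1024L) == 0L
}

sam_header_contigs <- function(header) {
  sq <- header[startsWith(header, "@SQ")]
  sub(".*\tSN:([^\t]+).*", "\\1", sq)
}
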