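# Shared low-level helpers: chromosome naming/order, contig-style
# reconciliation, phred decoding.

#' Order chromosome names naturally
#'
#' Sorts chromosome names so that numeric autosomes come in numeric order
#' ("chr2" before "chr10"), followed by non-numeric contigs alphabetically.
#' Used whenever panels or reports are written.
#'
#' @param chrom character vector of contig names (with or without a "chr"
#'   prefix).
#' @return integer permutation, as from [order()].
#' @export
chrom_order <- function(chrom) {
  stripped <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.numeric(stripped))
  order(is.na(num), num, stripped)
}

#' @rdname chrom_order
#' @export
is_autosome <- function(chrom) {
  grepl("^(chr)?[0-9]+$", chrom)
}

# Translate panel contig names to the style used by an alignment.
# style "auto" picks whichever of as-is / add-chr / strip-chr matches the
# target contig set best; an error is raised when nothing matches at all
# (almost always the wrong assembly).
reconcile_contigs <- function(chrom, target_contigs,
                              style = c("auto", "asis", "chr", "nochr")) {
  style <- match.arg(style)
  candidates <- switch(style,
    asis  = list(chrom),
    chr   = list(ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))),
    nochr = list(sub("^chr", "", chrom)),
    auto  = list(chrom,
                 ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom)),
                 sub("^chr", "", chrom))
  )
  hits <- vapply(candidates, function(x) sum(unique(x) %in% target_contigs), 0L)
  if (max(hits) == 0L) {
    stop("none of the panel contigs (", paste(utils::head(unique(chrom), 3),
         collapse = ", "), ", ...) are present in the alignment; ",
         "wrong assembly or contig naming style?")
  }
  candidates[[which.max(hits)]]
}

# phred string (offset 33) -> integer qualities
phred_from_string <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
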