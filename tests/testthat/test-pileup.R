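# Allele counting: read filters, CIGAR-aware base extraction on a
# hand-crafted alignment with known per-read truth, the mpileup-text
# parser, and the identity between the BAM and mpileup-text paths.

test_that("filter_read honours thresholds, boundaries and flags", {
  reads <- data.frame(
    flag  = c(0L, 0L, 1024L, 256L, 2048L, 4L, 99L, 99L),
    mapq  = c(29, 30, 60, 60, 60, 60, 60, 60),
    isize = c(NA, NA, NA, NA, NA, NA, 34L, 35L),
    cigar = c("50M", "50M", "50M", "50M", "50M", "*", "50M", "50M"))
  keep <- filter_read(reads, read_filter_config())
  # MQ 29 fails, MQ 30 passes; dup/secondary/supplementary/unmapped fail;
  # fragment 34 fails, 35 passes (inclusive)
  expect_equal(keep, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  # aligned query length is the fallback fragment length: 34M fails, 35M passes
  single <- data.frame(flag = 0L, mapq = 60, isize = NA,
                       cigar = c("34M", "35M", "10S35M"))
  expect_equal(filter_read(single, read_filter_config()),
               c(FALSE, TRUE, TRUE))
})

# one diagnostic site chr1:100 (ref A, species allele G) covered by reads
# whose fate is known per read; expected counts tallied by hand
planted_bam <- function(dir = tempfile("planted")) {
  dir.create(dir)
  G <- strrep("G", 50); A <- strrep("A", 50); Tt <- strrep("T", 50)
  q <- strrep("F", 50)
  lowq <- strrep("#", 50)
  rec <- function(qname, flag, pos, mq, cigar, seq, qual = q,
                  rnext = "*", pnext = 0, tlen = 0)
    paste(qname, flag, "chr1", pos, mq, cigar, rnext, pnext, tlen,
          seq, qual, sep = "\t")
  body <- c(
    rec("rA", 0, 60, 60, "50M", G),              # species base      -> counted
    rec("rB", 0, 60, 60, "50M", A),              # human ref         -> contamination
    rec("rC", 0, 90, 60, "8M5D37M", substr(G, 1, 45),
        qual = substr(q, 1, 45)),                # deletion over site -> no call
    rec("rD", 0, 60, 20, "50M", G),              # MQ < 30           -> excluded
    rec("rE", 1024, 60, 60, "50M", G),           # duplicate         -> excluded
    rec("rF", 0, 60, 60, "50M", G, qual = lowq), # base qual 2 < 13  -> no call
    rec("rG", 0, 60, 60, "50M", Tt),             # third allele      -> counted, not species
    rec("rH", 256, 60, 60, "50M", G),            # secondary         -> excluded
    rec("rI", 0, 95, 60, "20M", substr(G, 1, 20),
        qual = substr(q, 1, 20)),                # fragment 20 < 35  -> excluded
    rec("rJ", 0, 70, 60, "10S40M", G),           # soft clip, site at query 41
    rec("rK", 99, 80, 60, "50M", G,                  # |TLEN| 34  -> excluded
        rnext = "=", pnext = 300, tlen = 34),
    rec("rK", 147, 300, 60, "50M", G, rnext = "=", pnext = 80, tlen = -34),
    rec("rM", 99, 82, 60, "50M", G,                  # |TLEN| 35  -> counted
        rnext = "=", pnext = 400, tlen = 35),
    rec("rM", 147, 400, 60, "50M", G, rnext = "=", pnext = 82, tlen = -35),
    rec("rOP", 99, 60, 60, "50M", A,                 # overlapping mates,
        rnext = "=", pnext = 90, tlen = 80),         # both cover the site
    rec("rOP", 147, 90, 60, "50M", A, rnext = "=", pnext = 60, tlen = -80))
  bam <- file.path(dir, "planted.bam")
  apecontam:::sam_to_bam(c("@HD\tVN:1.6\tSO:unsorted",
                           "@SQ\tSN:chr1\tLN:1000"), body, bam)
  bam
}

planted_panel <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                            stringsAsFactors = FALSE)

test_that("count_alleles matches the hand-tallied truth on planted reads", {
  bam <- planted_bam()
  counts <- count_alleles(bam, planted_panel)
  # counted calls: rA(G) rB(A) rG(T) rJ(G) rM(G) rOP(A) rOP(A)
  expect_equal(counts,
               data.frame(chrom = "chr1", pos = 100L,
                          total_depth = 7L, species_depth = 3L,
                          stringsAsFactors = FALSE))
  # overlap deduplication collapses the rOP pair to one call
  dedup <- count_alleles(bam, planted_panel,
                         read_filter_config(dedup_overlaps = TRUE))
  expect_equal(dedup$total_depth, 6L)
  expect_equal(dedup$species_depth, 3L)
  # third-allele reads count toward contamination
  est <- estimate_contamination(counts)
  expect_equal(est$point_estimate, 1 - 3 / 7)
})

test_that("count_alleles validates index and contig compatibility", {
  bam <- planted_bam()
  noindex <- file.path(tempfile("ni", fileext = ".d"), "copy.bam")
  dir.create(dirname(noindex))
  file.copy(bam, noindex)
  expect_error(count_alleles(noindex, planted_panel), "index")
  wrong <- data.frame(chrom = "chr99", pos = 1L, ref = "A", alt = "G")
  expect_error(count_alleles(bam, wrong), "assembly|contig")
})

test_that("count_alleles reconciles chr-prefix naming styles", {
  bam <- planted_bam()
  nochr <- planted_panel
  nochr$chrom <- "1"
  counts <- count_alleles(bam, nochr)
  expect_equal(counts$total_depth, 7L)
  expect_equal(counts$chrom, "1")  # panel naming preserved in output
})

test_that("mpileup base-string parser handles the full syntax", {
  p <- apecontam:::parse_pileup_bases
  expect_equal(p(".,.,"), c(".", ",", ".", ","))
  expect_equal(p("^]..$"), c(".", "."))
  expect_equal(p(".+2AT,"), c(".", ","))
  expect_equal(p(".-1A,"), c(".", ","))
  expect_equal(p(".GgN*"), c(".", "G", "g", "N", "*"))
  expect_equal(p(".+12ACGTACGTACGT,"), c(".", ","))
  expect_equal(p("><."), c(">", "<", "."))
  expect_equal(p("*"), character())
})

test_that("read_mpileup counts calls, skips deletions, filters base quality", {
  panel <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                      ref = c("A", "C", "T"), alt = c("G", "T", "A"),
                      stringsAsFactors = FALSE)
  txt <- tempfile()
  writeLines(c(
    "chr1\t100\tA\t5\t.GgN*\tFFFFF",   # 4 calls, 2 species (G, g)
    "chr1\t150\tA\t2\t..\tFF",         # not a panel site -> ignored
    "chr1\t200\tC\t3\t.T,\tF!F",       # qual 0 drops the T call
    "chr1\t300\tT\t0\t*\t*"),          # zero depth -> no record
    txt)
  counts <- read_mpileup(txt, panel)
  expect_equal(counts,
               data.frame(chrom = "chr1", pos = c(100L, 200L),
                          total_depth = c(4L, 2L), species_depth = c(2L, 0L),
                          stringsAsFactors = FALSE))
})

test_that("BAM pileup and samtools mpileup text give identical counts", {
  fx <- fx_default()
  panel <- fx$expected_panel
  mx <- mix_alignments(fx$host_bam, fx$human_bam, 0.05, seed = 3)
  from_bam <- count_alleles(mx$bam, panel)

  bed <- tempfile(fileext = ".bed")
  write.table(data.frame(panel$chrom, panel$pos - 1L, panel$pos), bed,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  txt <- tempfile()
  # same filters: MQ >= 30, no BAQ, no overlap dedup, default flag mask
  system2("samtools", c("mpileup", "-q", "30", "-Q", "0", "-x", "-B",
                        "--ff", "UNMAP,SECONDARY,QCFAIL,DUP",
                        "-l", bed, mx$bam),
          stdout = txt, stderr = FALSE)
  from_text <- read_mpileup(txt, panel)
  expect_identical(from_bam, from_text)
  unlink(c(mx$bam, paste0(mx$bam, ".bai"), bed, txt))
})
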