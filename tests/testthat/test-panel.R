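# Panel builder: genotype filters, biallelic restriction, the three
# diagnostic criteria, masks, and agreement with a brute-force oracle.

test_that("genotype filters blank exactly the out-of-range genotypes", {
  gt <- function(dp, mq) c(1, 1, dp, mq)
  rec <- record1(sp = list(gt(5, 60), gt(6, 60), gt(100, 60), gt(101, 60),
                           gt(30, 19), gt(30, 20)),
                 hu = reps(c(0, 0, 30, 60), 2))
  f <- apply_genotype_filters(rec)
  sp_idx <- 1:6
  # depth 5 and 101 and MQ 19 -> missing; boundaries 6, 100, 20 survive
  expect_equal(is.na(f$A1[1, sp_idx]), c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(is.na(f$A2[1, sp_idx]), c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
  # surviving genotypes unchanged
  expect_equal(f$A1[1, c(2, 3, 6)], rep(1L, 3))
  # human genotypes untouched here
  expect_equal(f$A1[1, 7:8], rep(0L, 2))
})

test_that("biallelic-SNP test requires exactly one observed single-base alt", {
  two_alleles <- record1(sp = c(reps(c(1, 1, 30, 60), 4), list(c(2, 2, 30, 60))),
                         hu = reps(c(0, 0, 30, 60), 2),
                         ref = "A", alt = list(c("G", "T")))
  expect_false(is_biallelic_snp(two_alleles))

  one_observed <- record1(sp = reps(c(1, 1, 30, 60), 5),
                          hu = reps(c(0, 0, 30, 60), 2),
                          ref = "A", alt = list(c("G", "T")))
  expect_true(is_biallelic_snp(one_observed))

  indel <- record1(sp = reps(c(1, 1, 30, 60), 5),
                   hu = reps(c(0, 0, 30, 60), 2),
                   ref = "A", alt = list("AT"))
  expect_false(is_biallelic_snp(indel))

  no_alt <- record1(sp = reps(c(0, 0, 30, 60), 5),
                    hu = reps(c(0, 0, 30, 60), 2))
  expect_false(is_biallelic_snp(no_alt))
})

test_that("classify_site applies the three criteria in order", {
  ok <- record1(sp = reps(c(1, 1, 30, 60), 50),
                hu = reps(c(0, 0, 30, 60), 19))
  res <- classify_site(ok)
  expect_equal(res, data.frame(chrom = "chr1", pos = 100L, ref = "A",
                               alt = "G", stringsAsFactors = FALSE))

  # 97 alt of 100 observed chromosomes: 0.97 < 0.98
  frac97 <- record1(sp = c(reps(c(1, 1, 30, 60), 47), reps(c(0, 1, 30, 60), 3)),
                    hu = reps(c(0, 0, 30, 60), 19))
  expect_equal(classify_site(frac97)$reason, "species_alt_fraction")

  # one of ten species genotypes missing: 2/20 = 10% >= 5%
  miss10 <- record1(sp = c(reps(c(1, 1, 30, 60), 9), list(c(NA, NA, 30, 60))),
                    hu = reps(c(0, 0, 30, 60), 19))
  expect_equal(classify_site(miss10)$reason, "species_missingness")

  # exactly at the 98% boundary passes (inclusive)
  frac98 <- record1(sp = c(reps(c(1, 1, 30, 60), 49), list(c(0, 1, 30, 60))),
                    hu = reps(c(0, 0, 30, 60), 19))
  expect_equal(classify_site(frac98)$alt, "G")

  # one human genotype missing is disqualifying
  hu_miss <- record1(sp = reps(c(1, 1, 30, 60), 50),
                     hu = c(reps(c(0, 0, 30, 60), 18), list(c(NA, NA, 30, 60))))
  expect_equal(classify_site(hu_miss)$reason, "human_not_ref")
  cfg <- genotype_filter_config(human_missing_allowed = TRUE)
  expect_equal(classify_site(hu_miss, cfg)$alt, "G")

  # a heterozygous human is disqualifying
  hu_het <- record1(sp = reps(c(1, 1, 30, 60), 50),
                    hu = c(reps(c(0, 0, 30, 60), 18), list(c(0, 1, 30, 60))))
  expect_equal(classify_site(hu_het)$reason, "human_not_ref")

  empty_species <- record1(sp = list(), hu = reps(c(0, 0, 30, 60), 2))
  expect_error(classify_sites(empty_species), "species cohort")
})

test_that("alt-fraction denominator switch changes the marginal call", {
  # 50 individuals: 48 hom-alt observed, 2 missing
  # observed: 96/96 = 1; total: 96/100 = 0.96
  rec <- record1(sp = c(reps(c(1, 1, 30, 60), 48), reps(c(NA, NA, 30, 60), 2)),
                 hu = reps(c(0, 0, 30, 60), 19))
  rec2 <- rec
  obs <- classify_site(rec, genotype_filter_config(max_species_missing = 0.2))
  tot <- classify_site(rec2, genotype_filter_config(max_species_missing = 0.2,
                                                    alt_denominator = "total"))
  expect_equal(obs$alt, "G")
  expect_equal(tot$reason, "species_alt_fraction")
})

test_that("classify_site is idempotent on a diagnostic record", {
  rec <- record1(sp = reps(c(1, 1, 30, 60), 50),
                 hu = reps(c(0, 0, 30, 60), 19))
  first <- classify_site(rec)
  expect_equal(classify_site(rec), first)
})

test_that("build_panel rejects masked sites and validates sorting", {
  fx <- fx_default()
  cohort <- read_cohort_vcf(fx$vcf, read_sample_map(fx$samples_tsv))
  masks <- read_mask_bed(fx$masks_bed)
  res <- build_panel(cohort, masks)
  expect_identical(res$panel, fx$expected_panel)
  expect_equal(res$summary[["retained"]], nrow(fx$expected_panel))
  expect_gt(res$summary[["rejected_masked"]], 0)
  # every emitted site lies outside every mask
  expect_false(any(in_mask(res$panel$chrom, res$panel$pos, masks)))
  # all sites inside a mask -> empty panel
  all_masked <- GenomicRanges::GRanges(
    unique(cohort$chrom),
    IRanges::IRanges(1, max(cohort$pos) + 1))
  res2 <- build_panel(cohort, all_masked)
  expect_equal(nrow(res2$panel), 0L)
  expect_equal(res2$summary[["rejected_masked"]] +
               res2$summary[["rejected_not_autosome"]],
               res2$summary[["examined"]])
  # unsorted input errors, naming the position
  shuffled <- cohort[c(2L, 1L, seq_along(cohort$pos)[-(1:2)])]
  expect_error(build_panel(shuffled), "not sorted")
  # empty input -> empty panel
  expect_equal(nrow(build_panel(cohort[integer(0)])$panel), 0L)
})

test_that("build_panel equals the brute-force oracle on random cohorts", {
  for (seed in 1:10) {
    x <- random_cohort(seed)
    masks <- random_masks(seed)
    got <- build_panel(x, masks)$panel
    want <- oracle_panel(x, masks)
    expect_identical(got, want)
  }
})

test_that("stricter thresholds never add panel sites", {
  loose <- genotype_filter_config(min_alt_fraction = 0.9,
                                  max_species_missing = 0.2)
  key <- function(p) paste(p$chrom, p$pos)
  for (seed in 11:16) {
    x <- random_cohort(seed)
    base <- key(build_panel(x, config = loose)$panel)
    stricter_alt <- genotype_filter_config(min_alt_fraction = 0.99,
                                           max_species_missing = 0.2)
    stricter_miss <- genotype_filter_config(min_alt_fraction = 0.9,
                                            max_species_missing = 0.03)
    expect_true(all(key(build_panel(x, config = stricter_alt)$panel) %in% base))
    expect_true(all(key(build_panel(x, config = stricter_miss)$panel) %in% base))
  }
})

test_that("panels round-trip through TSV", {
  fx <- fx_default()
  p <- fx$expected_panel
  path <- tempfile(fileext = ".tsv")
  write_panel(p, path)
  expect_identical(read_panel(path), p)
  # gzip path too
  pathgz <- tempfile(fileext = ".tsv.gz")
  write_panel(p, pathgz)
  expect_identical(read_panel(pathgz), p)
})
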