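# Shared synthetic fixture set, generated once per session into tempdir()
# and reloaded from disk by later test files.

fx_dir <- function() file.path(tempdir(), "apecontam-fixtures")

fx_default <- function() {
  d <- fx_dir()
  marker <- file.path(d, "expected_panel.tsv")
  if (!file.exists(marker)) {
    m <- clade_model(n_chromosomes = 3, chromosome_length = 30000, seed = 42)
    write_fixture_set(d, m, read_model(mean_depth = 20, seed = 42),
                      n_species = 30, n_human = 10, seed = 42)
  }
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  list(dir = d,
       fasta = file.path(d, "reference.fa"),
       vcf = file.path(d, "cohort.vcf"),
       samples_tsv = file.path(d, "samples.tsv"),
       masks_bed = file.path(d, "masks.bed"),
       expected_panel = read_panel(marker),
       host_bam = file.path(d, "host.bam"),
       human_bam = file.path(d, "human.bam"),
       truth = truth$sites)
}

# one-site cohort record builder for boundary tests:
# sp / hu are lists of c(a1, a2, dp, mq) per individual (NA allele = missing)
record1 <- function(sp, hu, ref = "A", alt = list("G"),
                    chrom = "chr1", pos = 100L) {
  all <- c(sp, hu)
  mat <- function(k) matrix(vapply(all, `[`, numeric(1), k), nrow = 1)
  A1 <- mat(1); A2 <- mat(2)
  storage.mode(A1) <- "integer"; storage.mode(A2) <- "integer"
  DP <- mat(3); storage.mode(DP) <- "integer"
  cohort_genotypes(chrom, pos, ref, alt, A1, A2, DP, mat(4),
                   cohort = rep(c("species", "human"),
                                c(length(sp), length(hu))))
}

# n identical individuals
reps <- function(gt, n) rep(list(gt), n)
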