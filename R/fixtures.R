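# Synthetic fixture generator: a toy multi-chromosome "human reference", a
# great-ape clade cohort with planted fixed differences, deliberately
# failing candidate sites exercising every rejection path of the panel
# builder, and error-free (or error-rate-parameterised) aligned reads from
# host, human and cross-clade individuals. Everything is seeded and
# generated in code; no external data are touched.

#' Clade model for synthetic fixtures
#'
#' Describes the planted truth: how many chromosomes, how dense the
#' clade-diagnostic fixed differences are (default one per 500 bp, giving
#' ~200 diagnostic sites per 100-kb chromosome), how much within-clade
#' polymorphism to plant, and — for cross-clade experiments — the fraction
#' of another clade's diagnostic sites at which this clade carries the
#' human-like (reference) allele.
#'
#' @param n_chromosomes number of autosome-named chromosomes. Default 3.
#' @param chromosome_length length of each chromosome in bp. Default 1e5.
#' @param diagnostic_density planted fixed differences per bp. Default 1/500.
#' @param polymorphic_fraction sites segregating within the clade, as a
#'   fraction of the diagnostic count. Default 0.1.
#' @param human_like_fraction fraction of diagnostic sites at which a
#'   cross-clade individual carries the human reference allele. Default 0.
#' @param seed integer seed; fixed seed gives byte-identical fixtures.
#' @return an object of class `clade_model`.
#' @export
clade_model <- function(n_chromosomes = 3L, chromosome_length = 1e5,
                        diagnostic_density = 1 / 500,
                        polymorphic_fraction = 0.1,
                        human_like_fraction = 0, seed = 1L) {
  stopifnot(n_chromosomes >= 1, chromosome_length >= 1000,
            diagnostic_density >= 0, diagnostic_density <= 1,
            polymorphic_fraction >= 0, polymorphic_fraction <= 1,
            human_like_fraction >= 0, human_like_fraction <= 1)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length = as.integer(chromosome_length),
                 diagnostic_density = diagnostic_density,
                 polymorphic_fraction = polymorphic_fraction,
                 human_like_fraction = human_like_fraction,
                 seed = as.integer(seed)),
            class = "clade_model")
}

#' Read model for synthetic alignments
#'
#' @param read_length read length in bp. Default 100.
#' @param paired generate proper pairs (insert 250-400 bp, so mates never
#'   overlap). Default `TRUE`.
#' @param mean_depth target fold-coverage. Default 20.
#' @param error_rate per-base substitution error rate. Default 0
#'   (error-free, so pure-sample estimates are exact).
#' @param error_base_quality phred quality assigned to erroneous bases
#'   (correct bases get Q37). Default 37.
#' @param low_mq_fraction fraction of fragments written with MQ 10 to
#'   exercise the mapping-quality read filter. Default 0.
#' @param seed integer seed.
#' @return an object of class `read_model`.
#' @export
read_model <- function(read_length = 100L, paired = TRUE, mean_depth = 20,
                       error_rate = 0, error_base_quality = 37L,
                       low_mq_fraction = 0, seed = 1L) {
  stopifnot(read_length >= 20, mean_depth > 0,
            error_rate >= 0, error_rate < 1,
            low_mq_fraction >= 0, low_mq_fraction <= 1)
  structure(list(read_length = as.integer(read_length), paired = paired,
                 mean_depth = mean_depth, error_rate = error_rate,
                 error_base_quality = as.integer(error_base_quality),
                 low_mq_fraction = low_mq_fraction, seed = as.integer(seed)),
            class = "read_model")
}

BASES <- c("A", "C", "G", "T")

# n sorted positions in [lo, hi], pairwise at least min_gap apart
sample_spaced <- function(n, lo, hi, min_gap) {
  slots <- (hi - lo) %/% min_gap
  if (n > slots) stopf("cannot place %d sites with %d bp spacing", n, min_gap)
  base <- sort(sample.int(slots, n) - 1L) * min_gap
  lo + base + sample.int(min_gap, 1L) - 1L
}

other_base <- function(base) {
  vapply(base, function(b) sample(setdiff(BASES, b), 1L), "",
         USE.NAMES = FALSE)
}

#' Generate a toy reference genome with planted site classes
#'
#' Writes a random reference FASTA (the "human reference" stand-in) and
#' returns a truth table of planted candidate sites. Besides clean
#' diagnostic sites, a fixed share of deliberately failing sites is planted
#' so every rejection path of the panel builder is exercised:
#' within-clade polymorphism, human polymorphism, missing human genotypes,
#' genotype-filter failures driving species missingness, multi-allelic
#' sites, and diagnostic-quality sites inside a mask.
#'
#' @param model a [clade_model()].
#' @param dir output directory (created if needed).
#' @return list with `fasta` (path, .fai alongside), `truth` (data frame
#'   `chrom`, `pos`, `class`, `ref`, `alt`, `alt2`, `species_af`) and
#'   `masks` (GRanges covering the masked sites plus decoy intervals).
#' @export
make_reference <- function(model, dir = tempfile("fixtures")) {
  stopifnot(inherits(model, "clade_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(model$seed)
  L <- model$chromosome_length
  chroms <- paste0("chr", seq_len(model$n_chromosomes))

  seqs <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
    paste(sample(BASES, L, replace = TRUE), collapse = ""), ""))
  names(seqs) <- chroms

  n_diag <- round(L * model$diagnostic_density)
  class_counts <- c(diagnostic = n_diag,
                    species_polymorphic = round(n_diag * model$polymorphic_fraction),
                    human_polymorphic = max(if (n_diag > 0) 2L else 0L,
                                            round(n_diag * 0.05)),
                    human_missing = if (n_diag > 0) 2L else 0L,
                    species_missingness = if (n_diag > 0) 3L else 0L,
                    multiallelic = if (n_diag > 0) 2L else 0L,
                    masked_diagnostic = max(if (n_diag > 0) 2L else 0L,
                                            round(n_diag * 0.05)))
  truth <- do.call(rbind, lapply(chroms, function(ch) {
    n_tot <- sum(class_counts)
    if (n_tot == 0L)
      return(data.frame(chrom = character(), pos = integer(),
                        class = character(), ref = character(),
                        alt = character(), alt2 = character(),
                        species_af = numeric(), stringsAsFactors = FALSE))
    # keep planted sites away from chromosome ends and from each other
    # (> 60 bp apart, so a masked site's interval cannot swallow a neighbour)
    pos <- sample_spaced(n_tot, 200L, L - 200L, 61L)
    cls <- sample(rep(names(class_counts), class_counts))
    ref <- strsplit(as.character(seqs[[ch]]), "")[[1]][pos]
    alt <- other_base(ref)
    alt2 <- ifelse(cls == "multiallelic",
                   vapply(seq_along(ref), function(i)
                     sample(setdiff(BASES, c(ref[i], alt[i])), 1L), ""),
                   NA_character_)
    af <- ifelse(cls == "species_polymorphic", stats::runif(n_tot, 0.2, 0.8),
                 NA_real_)
    data.frame(chrom = ch, pos = pos, class = cls, ref = ref, alt = alt,
               alt2 = alt2, species_af = af, stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL

  fasta <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(seqs, fasta)
  Rsamtools::indexFa(fasta)

  masked <- truth[truth$class == "masked_diagnostic", , drop = FALSE]
  mask_iv <- GenomicRanges::GRanges(masked$chrom,
                                    IRanges::IRanges(pmax(1L, masked$pos - 25L),
                                                     masked$pos + 25L))
  # decoy intervals not containing any planted site
  decoys <- GenomicRanges::GRanges(chroms, IRanges::IRanges(1L, 100L))
  masks <- sort(c(mask_iv, decoys))

  list(fasta = fasta, truth = truth, masks = masks, dir = dir,
       chromosomes = stats::setNames(rep(L, length(chroms)), chroms))
}

#' Generate a cohort VCF with an exact expected panel
#'
#' Writes per-sample genotypes (FORMAT GT:DP:MQ) for the species complex
#' and the human cohort at all planted sites. Default cohort sizes mirror
#' the published chimpanzee/bonobo panel: 68 species individuals and 19
#' humans. Diagnostic sites are fixed for the alternative allele in the
#' species (a 10% subset carries one heterozygous individual, exercising
#' the inclusive >= 98% boundary when the cohort is large enough for it to
#' pass); each failing class breaks exactly one criterion by construction,
#' so the expected panel is implied directly by the planted truth.
#'
#' @param ref result of [make_reference()].
#' @param n_species,n_human cohort sizes (diploid individuals).
#'   Defaults 68 and 19.
#' @param path output VCF path. Default `cohort.vcf` next to the reference.
#' @param seed integer seed.
#' @return list with `vcf`, `sample_map` (named cohort vector),
#'   `samples_tsv`, `expected_panel` (data frame `chrom`, `pos`, `ref`,
#'   `alt`) and `masks_bed`.
#' @export
make_cohort_vcf <- function(ref, n_species = 68L, n_human = 19L,
                            path = file.path(ref$dir, "cohort.vcf"),
                            seed = 1L) {
  truth <- ref$truth
  set.seed(seed + 1L)
  sp_names <- sprintf("SPC%03d", seq_len(n_species))
  hu_names <- sprintf("HUM%03d", seq_len(n_human))
  n <- nrow(truth)

  # residual heterozygote only if one ref chromosome keeps the site >= 98%
  residual_ok <- 1 / (2 * n_species) <= 0.02
  residual <- truth$class == "diagnostic" &
    stats::runif(n) < 0.1 & residual_ok
  # species missingness: smallest k with 2k/(2n) >= 5%
  k_miss <- ceiling(0.05 * n_species)

  gt_lines <- character(n)
  for (i in seq_len(n)) {
    cls <- truth$class[i]
    sp_gt <- rep("1/1", n_species)
    sp_dp <- sample(10:60, n_species, replace = TRUE)
    sp_mq <- rep(60L, n_species)
    hu_gt <- rep("0/0", n_human)
    hu_dp <- sample(10:60, n_human, replace = TRUE)
    hu_mq <- rep(60L, n_human)

    if (cls == "diagnostic" && residual[i]) {
      sp_gt[sample(n_species, 1L)] <- "0/1"
    } else if (cls == "species_polymorphic") {
      n_alt <- min(2L * n_species, round(truth$species_af[i] * 2L * n_species))
      n_alt <- min(n_alt, floor(0.97 * 2L * n_species))  # guaranteed < 98%
      alleles <- sample(c(rep(1L, n_alt), rep(0L, 2L * n_species - n_alt)))
      sp_gt <- paste(alleles[seq(1, 2 * n_species, 2)],
                     alleles[seq(2, 2 * n_species, 2)], sep = "/")
    } else if (cls == "human_polymorphic") {
      hu_gt[sample(n_human, 1L)] <- "0/1"
    } else if (cls == "human_missing") {
      hu_dp[sample(n_human, 1L)] <- 5L
    } else if (cls == "species_missingness") {
      fail <- sample(n_species, k_miss)
      mode <- rep_len(c("low", "high", "mq"), k_miss)
      sp_dp[fail[mode == "low"]] <- 5L
      sp_dp[fail[mode == "high"]] <- 101L
      sp_mq[fail[mode == "mq"]] <- 19L
    } else if (cls == "multiallelic") {
      sp_gt[sample(n_species, 2L)] <- "2/2"
    }
    gt_lines[i] <- paste(c(paste(sp_gt, sp_dp, sp_mq, sep = ":"),
                           paste(hu_gt, hu_dp, hu_mq, sep = ":")),
                         collapse = "\t")
  }

  alt_field <- ifelse(is.na(truth$alt2), truth$alt,
                      paste(truth$alt, truth$alt2, sep = ","))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(ref$chromosomes),
            ref$chromosomes),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=MQ,Number=1,Type=Integer,Description=\"Mapping quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sp_names, hu_names), collapse = "\t"))
  body <- paste(truth$chrom, truth$pos, ".", truth$ref, alt_field, ".", ".",
                ".", "GT:DP:MQ", gt_lines, sep = "\t")
  writeLines(c(header, body), path)

  sample_map <- stats::setNames(c(rep("species", n_species),
                                  rep("human", n_human)),
                                c(sp_names, hu_names))
  samples_tsv <- file.path(dirname(path), "samples.tsv")
  utils::write.table(data.frame(names(sample_map), unname(sample_map)),
                     samples_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  masks_bed <- file.path(dirname(path), "masks.bed")
  write_mask_bed(ref$masks, masks_bed)

  expected <- truth[truth$class == "diagnostic",
                    c("chrom", "pos", "ref", "alt")]
  rownames(expected) <- NULL
  list(vcf = path, sample_map = sample_map, samples_tsv = samples_tsv,
       expected_panel = expected, masks_bed = masks_bed)
}

#' Haplotype of a synthetic individual
#'
#' Builds the (homozygous) genome of one individual by substituting planted
#' alleles into the reference. `"host"` carries the species alternative
#' allele at every species-fixed site and a Bernoulli(af) draw at
#' polymorphic sites; `"human"` is the reference itself; `"cross"` models an
#' individual from a different clade that carries the human-like reference
#' allele at an exact `human_like_fraction` of the diagnostic sites and the
#' species allele elsewhere.
#'
#' @param ref result of [make_reference()].
#' @param type "host", "human" or "cross".
#' @param human_like_fraction for `"cross"`: fraction of diagnostic sites
#'   carrying the reference allele; defaults to the clade model's value via
#'   the caller.
#' @param seed integer seed.
#' @return list with `haplotypes` ([Biostrings::DNAStringSet]) and
#'   `human_like_sites` (data frame of diagnostic sites where the
#'   individual carries the reference allele; empty for `"host"`).
#' @export
make_individual <- function(ref, type = c("host", "human", "cross"),
                            human_like_fraction = 0, seed = 1L) {
  type <- match.arg(type)
  set.seed(seed + 2L)
  seqs <- Biostrings::readDNAStringSet(ref$fasta)
  names(seqs) <- sub(" .*", "", names(seqs))
  truth <- ref$truth
  human_like <- truth[0, ]

  if (type != "human") {
    fixed <- truth$class %in% c("diagnostic", "masked_diagnostic",
                                "human_polymorphic", "human_missing",
                                "species_missingness", "multiallelic")
    carry_alt <- fixed
    poly <- which(truth$class == "species_polymorphic")
    carry_alt[poly] <- stats::runif(length(poly)) < truth$species_af[poly]
    if (type == "cross") {
      diag_idx <- which(truth$class == "diagnostic")
      n_hl <- round(human_like_fraction * length(diag_idx))
      hl <- sample(diag_idx, n_hl)
      carry_alt[hl] <- FALSE
      human_like <- truth[sort(hl), ]
    }
    sub <- truth[carry_alt, , drop = FALSE]
    for (ch in unique(sub$chrom)) {
      rows <- sub[sub$chrom == ch, ]
      seqs[[ch]] <- Biostrings::replaceLetterAt(
        seqs[[ch]], rows$pos, paste(rows$alt, collapse = ""))
    }
  }
  list(haplotypes = seqs, human_like_sites = human_like)
}

#' Simulate aligned reads from an individual
#'
#' Reads are exact substrings of the individual's haplotypes (plus seeded
#' substitution errors at `error_rate`), written as proper pairs with
#' correct coordinates, TLEN and MQ 60 (decoy fragments get MQ 10), then
#' sorted and indexed. Because individuals differ from the reference only
#' by substitutions, haplotype coordinates equal reference coordinates and
#' every read aligns with a pure-match CIGAR.
#'
#' @param haplotypes [Biostrings::DNAStringSet], one sequence per
#'   chromosome (as from [make_individual()]).
#' @param model a [read_model()].
#' @param out_bam output BAM path.
#' @param sample sample name written to the read group/QNAME prefix.
#' @return list with `bam` (sorted, indexed) and `truth` (data frame
#'   `qname`, `chrom`, `start`, `end` per fragment).
#' @export
make_reads <- function(haplotypes, model = read_model(),
                       out_bam = tempfile(fileext = ".bam"),
                       sample = "S1") {
  stopifnot(inherits(model, "read_model"))
  set.seed(model$seed)
  rl <- model$read_length
  chroms <- names(haplotypes)
  lens <- Biostrings::width(haplotypes)
  min_insert <- if (model$paired) 2L * rl + 50L else rl
  if (any(lens < min_insert + 150L))
    stopf("chromosome shorter than the fragment length")

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", chroms, lens),
              sprintf("@RG\tID:%s\tSM:%s", sample, sample))
  body <- character()
  truth <- list()
  qual37 <- strrep(rawToChar(as.raw(37L + 33L)), rl)

  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    L <- lens[ci]
    n_frag <- round(model$mean_depth * L /
                    (if (model$paired) 2L * rl else rl))
    if (n_frag == 0L) next
    insert <- sample(250:400, n_frag, replace = TRUE)
    if (!model$paired) insert <- rep(rl, n_frag)
    start <- vapply(insert, function(ins) sample.int(L - ins + 1L, 1L), 0L)
    qname <- sprintf("%s_%s_f%06d", sample, ch, seq_len(n_frag))
    mq <- ifelse(stats::runif(n_frag) < model$low_mq_fraction, 10L, 60L)

    r1 <- substring(as.character(haplotypes[[ci]]), start, start + rl - 1L)
    if (model$paired) {
      m2s <- start + insert - rl
      # SAM stores SEQ in reference orientation, so the reverse-strand mate
      # is written as the forward-strand substring it covers
      r2f <- substring(as.character(haplotypes[[ci]]), m2s, m2s + rl - 1L)
      s1 <- seq_with_errors(r1, model); s2 <- seq_with_errors(r2f, model)
      body <- c(body,
        paste(qname, 99L, ch, start, mq, paste0(rl, "M"), "=", m2s, insert,
              s1$seq, s1$qual, sep = "\t"),
        paste(qname, 147L, ch, m2s, mq, paste0(rl, "M"), "=", start, -insert,
              s2$seq, s2$qual, sep = "\t"))
      truth[[length(truth) + 1L]] <-
        data.frame(qname = qname, chrom = ch, start = start,
                   end = start + insert - 1L, mq = mq,
                   stringsAsFactors = FALSE)
    } else {
      s1 <- seq_with_errors(r1, model)
      body <- c(body,
        paste(qname, 0L, ch, start, mq, paste0(rl, "M"), "*", 0L, 0L,
              s1$seq, s1$qual, sep = "\t"))
      truth[[length(truth) + 1L]] <-
        data.frame(qname = qname, chrom = ch, start = start,
                   end = start + rl - 1L, mq = mq, stringsAsFactors = FALSE)
    }
  }
  sam_to_bam(header, body, out_bam)
  list(bam = out_bam, truth = do.call(rbind, truth))
}

# plant substitution errors; erroneous bases get the configured quality
seq_with_errors <- function(seqs, model) {
  rl <- model$read_length
  qual <- rep(strrep(rawToChar(as.raw(37L + 33L)), rl), length(seqs))
  if (model$error_rate > 0) {
    errchar <- rawToChar(as.raw(model$error_base_quality + 33L))
    for (i in seq_along(seqs)) {
      hit <- which(stats::runif(rl) < model$error_rate)
      if (length(hit)) {
        s <- strsplit(seqs[i], "")[[1]]
        s[hit] <- other_base(s[hit])
        seqs[i] <- paste(s, collapse = "")
        q <- strsplit(qual[i], "")[[1]]
        q[hit] <- errchar
        qual[i] <- paste(q, collapse = "")
      }
    }
  }
  list(seq = seqs, qual = qual)
}

#' Write a complete fixture set to a directory
#'
#' One-call generator for the CLI and for end-to-end tests: reference FASTA
#' (+ index), cohort VCF, sample map, masks BED, the expected panel TSV,
#' host and human-contaminant BAMs (+ indexes), and a JSON truth summary.
#'
#' @param dir output directory.
#' @param model a [clade_model()].
#' @param reads a [read_model()].
#' @param n_species,n_human cohort sizes for the VCF.
#' @param seed integer master seed (fanned out to the sub-generators).
#' @return invisibly, a list of all paths and truth objects.
#' @export
write_fixture_set <- function(dir, model = clade_model(),
                              reads = read_model(),
                              n_species = 68L, n_human = 19L, seed = 42L) {
  model$seed <- seed
  ref <- make_reference(model, dir)
  cohort <- make_cohort_vcf(ref, n_species, n_human, seed = seed)
  write_panel(cohort$expected_panel, file.path(dir, "expected_panel.tsv"))

  host <- make_individual(ref, "host", seed = seed)
  human <- make_individual(ref, "human", seed = seed)
  reads$seed <- seed + 10L
  host_bam <- make_reads(host$haplotypes, reads,
                         file.path(dir, "host.bam"), sample = "host")
  reads$seed <- seed + 11L
  human_bam <- make_reads(human$haplotypes, reads,
                          file.path(dir, "human.bam"), sample = "human")

  truth_json <- file.path(dir, "truth.json")
  jsonlite::write_json(list(model = unclass(model),
                            sites = ref$truth,
                            n_species = n_species, n_human = n_human),
                       truth_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(reference = ref, cohort = cohort,
                 host_bam = host_bam$bam, human_bam = human_bam$bam,
                 expected_panel = cohort$expected_panel,
                 truth_json = truth_json, dir = dir))
}
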