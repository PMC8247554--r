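# Independent brute-force oracle for the panel builder: evaluates every
# criterion site by site with naive loops, touching only the raw fields of
# the cohort object (no package classification functions), so it can
# disagree with the vectorised pipeline.

oracle_panel <- function(x, masks = NULL, config = genotype_filter_config(),
                         autosomes_only = TRUE) {
  rows <- list()
  sp <- which(x$cohort == "species")
  hu <- which(x$cohort == "human")
  for (i in seq_along(x$pos)) {
    if (autosomes_only && !grepl("^(chr)?[0-9]+$", x$chrom[i])) next
    if (!is.null(masks)) {
      mk <- if (is.list(masks)) do.call(c, unname(masks)) else masks
      hit <- FALSE
      for (j in seq_along(mk)) {
        if (as.character(GenomicRanges::seqnames(mk)[j]) == x$chrom[i] &&
            x$pos[i] >= GenomicRanges::start(mk)[j] &&
            x$pos[i] <= GenomicRanges::end(mk)[j]) hit <- TRUE
      }
      if (hit) next
    }
    # genotype filters
    a1 <- x$A1[i, ]; a2 <- x$A2[i, ]
    for (s in seq_along(a1)) {
      if (x$DP[i, s] < config$min_depth || x$DP[i, s] > config$max_depth ||
          x$MQ[i, s] < config$min_genotype_mq) {
        a1[s] <- NA; a2[s] <- NA
      }
    }
    # biallelic SNP: exactly one alt observed anywhere, both alleles 1 bp
    obs <- c(a1, a2); obs <- obs[!is.na(obs)]
    alts <- sort(unique(obs[obs > 0]))
    if (length(alts) != 1) next
    alt_base <- x$alt[[i]][alts]
    if (nchar(x$ref[i]) != 1 || is.na(alt_base) || nchar(alt_base) != 1) next
    # species criteria
    spall <- c(a1[sp], a2[sp])
    n_total <- length(spall)
    n_missing <- sum(is.na(spall))
    n_obs <- n_total - n_missing
    n_alt <- sum(spall == alts, na.rm = TRUE)
    denom <- if (config$alt_denominator == "observed") n_obs else n_total
    frac <- if (denom > 0) n_alt / denom else 0
    if (frac < config$min_alt_fraction) next
    if (n_missing / n_total >= config$max_species_missing) next
    # human criterion
    huall <- c(a1[hu], a2[hu])
    if (!config$human_missing_allowed && any(is.na(huall))) next
    if (any(huall != 0, na.rm = TRUE)) next
    rows[[length(rows) + 1]] <-
      data.frame(chrom = x$chrom[i], pos = x$pos[i], ref = x$ref[i],
                 alt = alt_base, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# random cohort generator exercising every filter path
random_cohort <- function(seed, n_sites = 200, n_species = 12, n_human = 6) {
  set.seed(seed)
  m <- n_species + n_human
  chroms <- c("chr1", "chr2", "chrX")
  chrom <- sort(sample(chroms, n_sites, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n_sites), chrom)[unique(chrom)],
                       function(i) sort(sample.int(1e6, length(i)))))
  chrom <- rep(unique(chrom), times = table(chrom)[unique(chrom)])
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  # occasionally indel alleles or two alts
  alt <- lapply(seq_len(n_sites), function(i) {
    n_alt <- sample(1:2, 1, prob = c(0.85, 0.15))
    a <- sample(setdiff(bases, ref[i]), n_alt)
    if (runif(1) < 0.08) a[1] <- paste0(a[1], "T")
    if (runif(1) < 0.05) ref[i] <<- paste0(ref[i], "A")
    a
  })
  A1 <- matrix(NA_integer_, n_sites, m)
  A2 <- matrix(NA_integer_, n_sites, m)
  for (i in seq_len(n_sites)) {
    k <- length(alt[[i]])
    p_sp <- sample(c(1, 0.995, 0.985, 0.9, 0.4), 1,
                   prob = c(0.4, 0.15, 0.15, 0.15, 0.15))
    p_hu <- sample(c(0, 0.05, 0.5), 1, prob = c(0.75, 0.15, 0.1))
    sp_draw <- function(n) sample(0:k, n, replace = TRUE,
                                  prob = c(1 - p_sp, p_sp,
                                           rep(0.02, k - 1))[1:(k + 1)])
    hu_draw <- function(n) sample(0:k, n, replace = TRUE,
                                  prob = c(1 - p_hu, p_hu,
                                           rep(0.01, k - 1))[1:(k + 1)])
    A1[i, ] <- c(sp_draw(n_species), hu_draw(n_human))
    A2[i, ] <- c(sp_draw(n_species), hu_draw(n_human))
    miss <- runif(m) < 0.06
    A1[i, miss] <- NA; A2[i, miss] <- NA
  }
  DP <- matrix(sample(c(5L, 6L, 30L, 100L, 101L), n_sites * m, replace = TRUE,
                      prob = c(0.05, 0.05, 0.8, 0.05, 0.05)), n_sites, m)
  MQ <- matrix(sample(c(19, 20, 60), n_sites * m, replace = TRUE,
                      prob = c(0.05, 0.05, 0.9)), n_sites, m)
  cohort_genotypes(chrom, pos, ref, alt, A1, A2, DP, MQ,
                   rep(c("species", "human"), c(n_species, n_human)))
}

random_masks <- function(seed) {
  set.seed(seed + 1000)
  GenomicRanges::GRanges(sample(c("chr1", "chr2"), 5, replace = TRUE),
                         IRanges::IRanges(sample.int(1e6, 5), width = 5000))
}
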