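# shared fixtures and independent oracles, built in code

tiny_map <- function(n, chrom = "1", start = 1000L, spacing = 1000L) {
  marker_map(sprintf("m%03d", seq_len(n)), rep(chrom, n),
             start + (seq_len(n) - 1L) * spacing)
}

# cohort with explicit haplotype rows (one string of 0/1/. per haplotype)
cohort_from_strings <- function(hap_strings, phenotype,
                                map = tiny_map(nchar(hap_strings[1]))) {
  h <- do.call(rbind, strsplit(hap_strings, ""))
  h[h == "."] <- NA
  mode(h) <- "integer"
  samples <- sprintf("s%02d", seq_len(length(hap_strings) / 2L))
  phased_cohort(h, map, samples, phenotype)
}

gm_from_geno <- function(geno, map = tiny_map(ncol(geno)), phenotype = NULL) {
  genotype_matrix(geno, map, sprintf("i%02d", seq_len(nrow(geno))), phenotype)
}

# --- independent oracles ----------------------------------------------------

# Fisher two-sided p by direct enumeration over all tables with the observed
# margins, using exact binomial-coefficient arithmetic (no dhyper)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  logp <- vapply(lo:hi, function(x) {
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  }, numeric(1))
  p <- exp(logp)
  sum(p[p <= p[(lo:hi) == a] * (1 + 1e-7)])
}

# codon-walk translation oracle: walk the genome exon by exon in transcript
# order, collect coding bases, translate codon by codon with a lookup table
translate_oracle <- function(model) {
  ex <- model$exons[order(model$exons$rank), , drop = FALSE]
  bases <- character(0)
  for (i in seq_len(nrow(ex))) {
    lo <- max(ex$start[i], model$cds_lo)
    hi <- min(ex$end[i], model$cds_hi)
    if (hi < lo) next
    piece <- strsplit(substr(model$seq, lo - model$seq_offset + 1L,
                             hi - model$seq_offset + 1L), "")[[1]]
    if (model$strand == "-") piece <- rev(chartr("ACGT", "TGCA", piece))
    bases <- c(bases, piece)
  }
  stopifnot(length(bases) %% 3 == 0)
  code <- Biostrings::GENETIC_CODE
  aa <- character(length(bases) / 3)
  for (j in seq_along(aa)) {
    aa[j] <- code[[paste(bases[(3 * j - 2):(3 * j)], collapse = "")]]
  }
  paste(aa, collapse = "")
}

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# return a copy of a gene model with one plus-strand base replaced
within_seq_replace <- function(model, genomic_pos, base) {
  i <- genomic_pos - model$seq_offset + 1L
  substr(model$seq, i, i) <- base
  model
}

# random gene model with codon-aligned coding exons, random strand/placement
random_gene_model <- function(seed) {
  withr::with_seed(seed, {
    n_exons <- sample(6:20, 1)
    prefix <- sample(0:3, 1)
    lens <- integer(n_exons)
    lens[seq_len(prefix)] <- sample(60:200, prefix, replace = TRUE)
    n_cod <- n_exons - prefix
    lens[(prefix + 1):n_exons] <- 3L * sample(10:80, n_cod, replace = TRUE)
    skippable <- sample((prefix + 1):n_exons, 1)
    strand <- sample(c("+", "-"), 1)
    g <- simulate_gene_model(n_exons = n_exons, exon_lengths = lens,
                             noncoding_prefix_exons = prefix,
                             skippable_exon = skippable,
                             intron_length = sample(80:400, 1),
                             chrom = "5", gene_start = 100000L,
                             strand = strand, seed = seed + 1L)
    g
  })
}
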