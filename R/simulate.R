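#' Cohort simulation specification
#'
#' Defaults mirror an ascertained half-sib mapping design: nine affected and
#' 37 unaffected offspring of a single heterozygous carrier sire, a fully
#' penetrant recessive risk haplotype of ~700 kb, and array-like noise
#' (per-allele genotyping error, per-genotype missingness giving a ~99.4%
#' call-rate).
#'
#' @param n_cases,n_controls offspring quotas.
#' @param n_founder_haplotypes size of the founder haplotype pool.
#' @param risk_segment list `(chrom, start_bp, end_bp)` of the planted
#'   segment; must lie within the marker map extent.
#' @param dam_carrier_freq probability that a dam transmits the risk
#'   haplotype. The study families' dam-side carrier frequency is unknown,
#'   so this is a free parameter; the default 0.25 yields an affected
#'   fraction of ~1/8 among draws.
#' @param dam_flank_mean_bp mean (exponential) extension of the ancestral
#'   risk haplotype beyond the segment on a transmitting dam's gamete:
#'   dams are unrelated carriers, so they share the risk haplotype only
#'   around the mutation, spliced into their own background haplotype.
#'   Default 0: the planted object is the sharp risk segment itself; set a
#'   positive mean to study ancestral IBD decay around it.
#' @param recombination_rate_per_bp Poisson crossover intensity along the
#'   map (default 1e-8 = 1 cM/Mb).
#' @param genotyping_error_rate per-allele flip probability applied after
#'   phenotype assignment. Default 0: the cohort models the *phased*
#'   dataset, and phasing/imputation software emits complete, internally
#'   consistent haplotypes in which shared ancestral copies stay identical
#'   — independent allele flips would misrepresent that product. Set a
#'   positive rate to emulate raw array calls for QC exercises.
#' @param missing_rate per-genotype masking probability applied after
#'   phenotype assignment. Default 0: phasing pipelines impute sporadically
#'   missing genotypes, so the phased product is complete. Set a positive
#'   rate to exercise call-rate QC.
#' @param max_draws cap on offspring draws before the case/control quotas
#'   are declared unreachable.
#' @param seed RNG seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 9L, n_controls = 37L,
                        n_founder_haplotypes = 20L,
                        risk_segment = list(chrom = "17",
                                            start_bp = 65645831L,
                                            end_bp = 66358629L),
                        dam_carrier_freq = 0.25,
                        dam_flank_mean_bp = 0,
                        recombination_rate_per_bp = 1e-8,
                        genotyping_error_rate = 0,
                        missing_rate = 0,
                        max_draws = 1e6,
                        seed = NULL) {
  assert_count(n_cases, "n_cases")
  assert_count(n_controls, "n_controls")
  assert_count(n_founder_haplotypes, "n_founder_haplotypes", positive = TRUE)
  assert_prob(dam_carrier_freq, "dam_carrier_freq")
  assert_prob(genotyping_error_rate, "genotyping_error_rate")
  assert_prob(missing_rate, "missing_rate")
  stopifnot(risk_segment$end_bp > risk_segment$start_bp)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_founder_haplotypes = as.integer(n_founder_haplotypes),
                 risk_segment = risk_segment,
                 dam_carrier_freq = dam_carrier_freq,
                 dam_flank_mean_bp = dam_flank_mean_bp,
                 recombination_rate_per_bp = recombination_rate_per_bp,
                 genotyping_error_rate = genotyping_error_rate,
                 missing_rate = missing_rate,
                 max_draws = max_draws, seed = seed),
            class = "cohort_spec")
}

#' Simulate a founder haplotype pool
#'
#' Draws binary haplotypes over a marker map with per-site allele-1
#' frequencies sampled uniformly from `maf_params`. Haplotype 1 is the
#' designated risk haplotype: its alleles across the risk segment form the
#' planted signature, and every other founder haplotype is guaranteed to
#' differ from the signature at one or more segment markers, so that
#' signature homozygosity identifies two copies of the risk haplotype.
#'
#' @param n_haplotypes pool size (>= 2).
#' @param map a [marker_map].
#' @param maf_params length-2 numeric `c(min, max)` for per-site allele
#'   frequencies, both in (0, 1).
#' @param risk_segment list `(chrom, start_bp, end_bp)`, or `NULL` for a
#'   pool without a planted signature.
#' @param seed RNG seed.
#' @return A list of class `haplotype_pool` with elements `haplotypes`
#'   (matrix), `map`, `risk_haplotype` (row index), `risk_idx` (marker
#'   column indices of the segment) and `signature` (alleles over them).
#' @export
simulate_pool <- function(n_haplotypes, map, maf_params = c(0.1, 0.5),
                          risk_segment = NULL, seed = NULL) {
  n_haplotypes <- assert_count(n_haplotypes, "n_haplotypes", positive = TRUE)
  if (n_haplotypes < 2L) stop("need at least 2 founder haplotypes", call. = FALSE)
  if (is.null(map) || nrow(map) == 0L) stop("marker map is empty", call. = FALSE)
  validate_marker_map(map)
  stopifnot(length(maf_params) == 2L, all(maf_params > 0), all(maf_params < 1),
            maf_params[1] <= maf_params[2])
  m <- nrow(map)
  with_seed(seed, {
    freq <- stats::runif(m, maf_params[1], maf_params[2])
    h <- matrix(stats::rbinom(n_haplotypes * m, 1L, rep(freq, each = n_haplotypes)),
                nrow = n_haplotypes, ncol = m)
    risk_idx <- integer(0)
    signature <- integer(0)
    if (!is.null(risk_segment)) {
      risk_idx <- which(map$chrom == risk_segment$chrom &
                          map$pos >= risk_segment$start_bp &
                          map$pos <= risk_segment$end_bp)
      if (length(risk_idx) == 0L) {
        stop("risk segment contains no markers", call. = FALSE)
      }
      signature <- h[1L, risk_idx]
      # no other founder haplotype may carry the full signature
      for (i in seq_len(n_haplotypes)[-1L]) {
        if (all(h[i, risk_idx] == signature)) {
          j <- resample(risk_idx, 1L)
          h[i, j] <- 1L - h[i, j]
        }
      }
    }
    structure(list(haplotypes = h, map = map, risk_haplotype = 1L,
                   risk_segment = risk_segment, risk_idx = risk_idx,
                   signature = signature),
              class = "haplotype_pool")
  })
}

# one recombined gamete from a pair of parental haplotypes
recombine_gamete <- function(hap1, hap2, pos, rate_per_bp) {
  span <- pos[length(pos)] - pos[1L]
  n_x <- stats::rpois(1L, rate_per_bp * span)
  lead <- sample.int(2L, 1L)
  if (n_x == 0L) {
    return(if (lead == 1L) hap1 else hap2)
  }
  cuts <- sort(stats::runif(n_x, pos[1L], pos[length(pos)]))
  seg <- findInterval(pos, cuts)
  src <- ifelse(seg %% 2L == 0L, lead, 3L - lead)
  ifelse(src == 1L, hap1, hap2)
}

#' Simulate an ascertained half-sib cohort
#'
#' One heterozygous carrier sire (risk haplotype plus one non-risk founder
#' haplotype) is mated to dams drawn from the founder pool. Each offspring
#' receives a recombined sire gamete and one dam haplotype; dams are
#' unrelated to the sire, so their gametes are drawn from the pool
#' haplotypes the sire does not carry, and a transmitting carrier dam
#' (probability `dam_carrier_freq`) contributes the ancestral risk
#' haplotype only over the segment plus decaying flanks, spliced into her
#' own background. Phenotype is fully
#' penetrant recessive: affected iff both haplotypes carry the planted
#' signature across the whole risk segment. Offspring are drawn by
#' rejection until exactly `n_cases` cases and `n_controls` controls have
#' accumulated; genotyping error and missingness are applied after
#' phenotype assignment, so the recorded truth is noise-free.
#'
#' @param pool a [simulate_pool] result carrying a risk segment.
#' @param spec a [cohort_spec].
#' @return A list with elements `cohort` ([phased_cohort]), `sire`
#'   (2 x markers haplotype matrix), and `truth` ([truth_record]).
#' @export
simulate_half_sib_cohort <- function(pool, spec = cohort_spec()) {
  stopifnot(inherits(pool, "haplotype_pool"), inherits(spec, "cohort_spec"))
  if (length(pool$risk_idx) == 0L) {
    stop("pool carries no risk segment; rebuild it with `risk_segment`",
         call. = FALSE)
  }
  map <- pool$map
  m <- nrow(map)
  seg_idx <- pool$risk_idx
  sig <- pool$signature
  n_pool <- nrow(pool$haplotypes)
  if (n_pool < 3L) {
    stop("cohort simulation needs >= 3 founder haplotypes ",
         "(sire carries two; dams draw from the rest)", call. = FALSE)
  }
  sire_other <- if (pool$risk_haplotype == 1L) 2L else 1L
  dam_pool <- setdiff(seq_len(n_pool), c(pool$risk_haplotype, sire_other))
  with_seed(spec$seed, {
    sire <- rbind(pool$haplotypes[pool$risk_haplotype, ],
                  pool$haplotypes[sire_other, ])
    pos <- map$pos
    case_h <- list(); ctrl_h <- list()
    draws <- 0L
    while (length(case_h) < spec$n_cases || length(ctrl_h) < spec$n_controls) {
      draws <- draws + 1L
      if (draws > spec$max_draws) {
        stop(sprintf(
          "case/control quotas unreachable after %d draws (have %d/%d cases, %d/%d controls)",
          spec$max_draws, length(case_h), spec$n_cases,
          length(ctrl_h), spec$n_controls), call. = FALSE)
      }
      gamete <- recombine_gamete(sire[1L, ], sire[2L, ], pos,
                                 spec$recombination_rate_per_bp)
      dam <- pool$haplotypes[resample(dam_pool, 1L), ]
      if (stats::runif(1L) < spec$dam_carrier_freq) {
        # unrelated carrier dam: risk haplotype IBD only around the segment,
        # with exponentially decaying flanks, on her own background
        fl <- if (spec$dam_flank_mean_bp > 0) {
          stats::rexp(2L, 1 / spec$dam_flank_mean_bp)
        } else c(0, 0)
        lo <- pool$risk_segment$start_bp - fl[1L]
        hi <- pool$risk_segment$end_bp + fl[2L]
        ibd <- map$chrom == pool$risk_segment$chrom & pos >= lo & pos <= hi
        dam[ibd] <- pool$haplotypes[pool$risk_haplotype, ibd]
      }
      affected <- all(gamete[seg_idx] == sig) && all(dam[seg_idx] == sig)
      if (affected && length(case_h) < spec$n_cases) {
        case_h[[length(case_h) + 1L]] <- rbind(gamete, dam)
      } else if (!affected && length(ctrl_h) < spec$n_controls) {
        ctrl_h[[length(ctrl_h) + 1L]] <- rbind(gamete, dam)
      }
    }
    n <- spec$n_cases + spec$n_controls
    h <- do.call(rbind, c(case_h, ctrl_h))
    samples <- c(sprintf("case%02d", seq_len(spec$n_cases)),
                 sprintf("ctrl%02d", seq_len(spec$n_controls)))
    phenotype <- rep(c("case", "control"), c(spec$n_cases, spec$n_controls))
    # post-phenotype noise: allele flips, then genotype masking
    if (spec$genotyping_error_rate > 0) {
      flip <- stats::runif(length(h)) < spec$genotyping_error_rate
      h[flip] <- 1L - h[flip]
    }
    if (spec$missing_rate > 0) {
      miss <- matrix(stats::runif(n * m) < spec$missing_rate, n, m)
      idx1 <- which(miss[rep(seq_len(n), each = 2L), , drop = FALSE])
      h[idx1] <- NA_integer_
    }
    cohort <- phased_cohort(h, map, samples, phenotype)
    truth <- truth_record(planted_segment = pool$risk_segment,
                          sire_risk_haplotype_id = pool$risk_haplotype)
    list(cohort = cohort, sire = sire, truth = truth, n_draws = draws)
  })
}

#' Variant-table simulation specification
#'
#' Defaults emulate a regional multi-sample genotype table: 1825 variants
#' (~7.7% indels) over the planted segment, genotyped in a 43-animal
#' reference panel plus the obligate carrier and one affected offspring,
#' with exactly four variants compatible with recessive inheritance.
#'
#' @param region list `(chrom, start_bp, end_bp)`.
#' @param n_variants number of polymorphic sites.
#' @param n_compatible number of planted filter-compatible variants.
#' @param n_panel_samples size of the homozygous-reference control panel.
#' @param fraction_indels fraction of non-planted records with ref/alt of
#'   unequal length.
#' @param seed RNG seed.
#' @return A list of class `variant_spec`.
#' @export
variant_spec <- function(region = list(chrom = "17", start_bp = 65645831L,
                                       end_bp = 66358629L),
                         n_variants = 1825L, n_compatible = 4L,
                         n_panel_samples = 43L,
                         fraction_indels = 141 / 1825, seed = NULL) {
  n_variants <- assert_count(n_variants, "n_variants", positive = TRUE)
  n_compatible <- assert_count(n_compatible, "n_compatible")
  if (n_compatible > n_variants) {
    stop("n_compatible exceeds n_variants", call. = FALSE)
  }
  assert_prob(fraction_indels, "fraction_indels")
  structure(list(region = region, n_variants = n_variants,
                 n_compatible = n_compatible,
                 n_panel_samples = assert_count(n_panel_samples,
                                                "n_panel_samples", TRUE),
                 fraction_indels = fraction_indels, seed = seed),
            class = "variant_spec")
}

#' Simulate a regional multi-sample variant table
#'
#' Emits a [variant_table] over `spec$region` with sample columns
#' `FV01..FVk` (control panel), `carrier` and `affected`. Exactly
#' `spec$n_compatible` planted records satisfy the three-condition
#' recessive filter (affected 1/1, carrier 0/1, panel all 0/0); every other
#' record is guaranteed to violate at least one condition. If `truth`
#' carries a causal variant position (`attr(truth, "causal_pos")` or a
#' `causal_pos` element), that site becomes one of the planted compatibles
#' with the recorded ref/alt alleles.
#'
#' @param truth a [truth_record] (or `NULL`); updated and returned.
#' @param spec a [variant_spec].
#' @return list with `table` ([variant_table]) and `truth` (updated
#'   [truth_record] whose `planted_compatible_variant_ids` resolve in the
#'   table).
#' @export
simulate_variant_table <- function(truth = NULL, spec = variant_spec()) {
  stopifnot(inherits(spec, "variant_spec"))
  region <- spec$region
  nv <- spec$n_variants
  with_seed(spec$seed, {
    pos <- sort(sample(seq.int(region$start_bp, region$end_bp), nv))
    causal_pos <- NA_integer_
    causal_ref <- "G"; causal_alt <- "A"
    if (!is.null(truth)) {
      cp <- truth$causal_pos %||% attr(truth, "causal_pos")
      if (!is.null(cp) && !is.na(cp)) {
        causal_pos <- as.integer(cp)
        causal_ref <- truth$causal_ref %||% attr(truth, "causal_ref") %||% "G"
        causal_alt <- truth$causal_alt %||% attr(truth, "causal_alt") %||% "A"
        if (causal_pos < region$start_bp || causal_pos > region$end_bp) {
          stop("causal position lies outside the variant region", call. = FALSE)
        }
        if (!causal_pos %in% pos) pos[which.min(abs(pos - causal_pos))] <- causal_pos
        pos <- sort(pos)
      }
    }
    ids <- sprintf("sv%s_%d", region$chrom, pos)
    samples <- c(sprintf("FV%02d", seq_len(spec$n_panel_samples)),
                 "carrier", "affected")
    ns <- length(samples)
    # background genotypes under approximate HWE with a low-frequency ALT
    p_alt <- stats::rbeta(nv, 0.8, 8)
    gt_levels <- c("0/0", "0/1", "1/1")
    g <- matrix("0/0", nv, ns, dimnames = list(ids, samples))
    for (j in seq_len(ns)) {
      u <- stats::runif(nv)
      g[, j] <- ifelse(u < (1 - p_alt)^2, "0/0",
                       ifelse(u < (1 - p_alt)^2 + 2 * p_alt * (1 - p_alt),
                              "0/1", "1/1"))
    }
    panel_cols <- seq_len(spec$n_panel_samples)
    # choose planted compatible sites
    planted <- integer(0)
    if (spec$n_compatible > 0L) {
      if (!is.na(causal_pos)) {
        planted <- match(causal_pos, pos)
        extra <- spec$n_compatible - 1L
      } else {
        extra <- spec$n_compatible
      }
      if (extra > 0L) {
        cand <- setdiff(seq_len(nv), planted)
        planted <- sort(c(planted, resample(cand, extra)))
      }
    }
    if (length(planted) > 0L) {
      g[planted, panel_cols] <- "0/0"
      g[planted, "carrier"] <- "0/1"
      g[planted, "affected"] <- "1/1"
    }
    # every non-planted record must violate >= 1 condition and be polymorphic
    other <- setdiff(seq_len(nv), planted)
    compat <- g[other, "affected"] == "1/1" & g[other, "carrier"] == "0/1" &
      rowSums(g[other, panel_cols, drop = FALSE] != "0/0") == 0L
    if (any(compat)) {
      fix <- other[compat]
      g[cbind(fix, resample(panel_cols, length(fix), replace = TRUE))] <- "0/1"
    }
    mono <- rowSums(g != "0/0") == 0L
    if (any(mono)) {
      g[cbind(which(mono),
              resample(seq_len(ns), sum(mono), replace = TRUE))] <- "0/1"
    }
    # alleles: SNPs everywhere, then convert a fraction of non-planted
    # records to indels (unequal ref/alt length)
    ref <- sample(DNA_BASES_SIMPLE, nv, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES_SIMPLE, r), 1L), "")
    n_indel <- round(spec$fraction_indels * nv)
    if (n_indel > 0L) {
      idx <- resample(other, min(n_indel, length(other)))
      ins <- stats::runif(length(idx)) < 0.5
      ext <- vapply(idx, function(i) {
        paste(sample(DNA_BASES_SIMPLE, 1L + sample.int(4L, 1L), replace = TRUE),
              collapse = "")
      }, "")
      alt[idx[ins]] <- paste0(ref[idx[ins]], ext[ins])
      ref[idx[!ins]] <- paste0(ref[idx[!ins]], ext[!ins])
    }
    if (!is.na(causal_pos)) {
      ci <- match(causal_pos, pos)
      ref[ci] <- causal_ref
      alt[ci] <- causal_alt
    }
    variants <- data.frame(chrom = region$chrom, pos = pos, id = ids,
                           ref = unname(ref), alt = unname(alt),
                           stringsAsFactors = FALSE)
    tab <- variant_table(variants, g)
    if (is.null(truth)) {
      truth <- truth_record(planted_segment = region)
    }
    truth$planted_compatible_variant_ids <- ids[planted]
    if (!is.na(causal_pos)) truth$causal_variant_id <- ids[match(causal_pos, pos)]
    list(table = tab, truth = truth)
  })
}

#' Simulate a multi-exon gene model with a planted splice-donor variant
#'
#' Builds a plus- or minus-strand gene whose first `noncoding_prefix_exons`
#' exons are non-coding and whose remaining exons are entirely coding, bound
#' to a generated genomic sequence without internal stop codons. Coding
#' exon lengths must each be a multiple of 3 (codon-aligned exon junctions),
#' so skipping any single coding exon is an in-frame event; the designated
#' skippable exon's length is checked separately so frameshift fixtures can
#' be built by relaxing `enforce_skippable_frame`. A donor-junction variant
#' is planted at the last exonic base of the skippable exon (the final base
#' of its last codon, forced to `G` with alternate allele `A`, a synonymous
#' change in the Glu codon GAG>GAA).
#'
#' @param n_exons total exon count.
#' @param exon_lengths integer vector of exon lengths (transcript order);
#'   `NULL` for defaults mirroring a 32-exon gene whose exon 23 carries
#'   120 coding nt.
#' @param noncoding_prefix_exons leading exons with no CDS.
#' @param skippable_exon transcript rank of the exon whose skipping is
#'   modelled.
#' @param intron_length intron size between consecutive exons.
#' @param flank_bp sequence padding kept on both sides of the gene.
#' @param chrom,gene_start genomic placement.
#' @param strand `"+"` or `"-"`.
#' @param enforce_skippable_frame error if the skippable exon's coding
#'   length is not a multiple of 3 (otherwise only flagged downstream).
#' @param seed RNG seed.
#' @return list with `model` ([gene_model]), and `truth` fields
#'   `causal_pos`, `causal_ref`, `causal_alt`, `causal_exon_index`.
#' @export
simulate_gene_model <- function(n_exons = 32L, exon_lengths = NULL,
                                noncoding_prefix_exons = 6L,
                                skippable_exon = 23L,
                                intron_length = 800L, flank_bp = 500L,
                                chrom = "17", gene_start = 65901000L,
                                strand = "+",
                                enforce_skippable_frame = TRUE,
                                seed = NULL) {
  n_exons <- assert_count(n_exons, "n_exons", positive = TRUE)
  if (is.null(exon_lengths)) {
    exon_lengths <- c(rep(150L, noncoding_prefix_exons),       # non-coding
                      rep(120L, 15L), 156L,                    # coding 7..22
                      120L,                                    # skippable 23
                      rep(120L, n_exons - noncoding_prefix_exons - 17L))
  }
  stopifnot(length(exon_lengths) == n_exons,
            skippable_exon > noncoding_prefix_exons,
            skippable_exon <= n_exons)
  coding_len <- exon_lengths[(noncoding_prefix_exons + 1L):n_exons]
  if (sum(coding_len) %% 3L != 0L) {
    stop("total CDS length is not a multiple of 3", call. = FALSE)
  }
  if (any(coding_len %% 3L != 0L)) {
    bad <- which(coding_len %% 3L != 0L) + noncoding_prefix_exons
    if (enforce_skippable_frame && skippable_exon %in% bad) {
      stop("skippable exon coding length is not a multiple of 3 ",
           "(skipping it would shift the reading frame)", call. = FALSE)
    }
    stop("coding exon lengths must each be a multiple of 3 ",
         "(codon-aligned junctions); offending exon(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    # genomic layout, transcript rank 1..n left->right for "+", right->left
    # for "-" (so the genomic order of exon lengths is reversed)
    glen <- if (strand == "+") exon_lengths else rev(exon_lengths)
    starts <- gene_start + cumsum(c(0L, glen[-n_exons] + intron_length))
    ends <- starts + glen - 1L
    rank <- if (strand == "+") seq_len(n_exons) else rev(seq_len(n_exons))
    exons <- data.frame(rank = rank, start = starts, end = ends)
    gene_end <- max(ends)
    seq_offset <- gene_start - flank_bp
    seq_len_total <- gene_end + flank_bp - seq_offset + 1L
    base <- sample(DNA_BASES_SIMPLE, seq_len_total, replace = TRUE)
    # coding sequence from sense codons only (no stop codons anywhere)
    codons <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
    n_codons <- sum(coding_len) %/% 3L
    cds <- unlist(strsplit(sample(codons, n_codons, replace = TRUE), ""))
    # force the skippable exon's final codon to GAG (planted donor-site G)
    coding_ranks <- (noncoding_prefix_exons + 1L):n_exons
    cum_cds <- cumsum(coding_len)
    k <- match(skippable_exon, coding_ranks)
    last_codon_end <- cum_cds[k]
    cds[(last_codon_end - 2L):last_codon_end] <- c("G", "A", "G")
    # lay CDS onto the genome exon by exon, in transcript order
    cds_i <- 1L
    for (r in coding_ranks) {
      e <- exons[exons$rank == r, ]
      piece <- cds[cds_i:(cds_i + (e$end - e$start))]
      if (strand == "-") piece <- rev(chartr("ACGT", "TGCA", piece))
      base[(e$start:e$end) - seq_offset + 1L] <- piece
      cds_i <- cds_i + (e$end - e$start + 1L)
    }
    # canonical splice dinucleotides on the template strand
    for (i in seq_len(n_exons - 1L)) {
      don <- ends[i] + 1L - seq_offset + 1L
      acc <- starts[i + 1L] - 2L - seq_offset + 1L
      if (strand == "+") {
        base[don:(don + 1L)] <- c("G", "T")
        base[acc:(acc + 1L)] <- c("A", "G")
      } else {
        base[don:(don + 1L)] <- c("C", "T")
        base[acc:(acc + 1L)] <- c("A", "C")
      }
    }
    seqc <- paste(base, collapse = "")
    cds_exons <- exons[exons$rank %in% coding_ranks, ]
    model <- gene_model(gene_id = "GENE1", chrom = chrom, strand = strand,
                        exons = exons, cds_lo = min(cds_exons$start),
                        cds_hi = max(cds_exons$end),
                        seq = seqc, seq_offset = seq_offset)
    # planted donor-junction variant: last exonic base of the skippable exon
    e <- exons[exons$rank == skippable_exon, ]
    causal_pos <- if (strand == "+") e$end else e$start
    # ref/alt follow the VCF convention: alleles on the plus strand
    causal_ref <- substr(seqc, causal_pos - seq_offset + 1L,
                         causal_pos - seq_offset + 1L)
    causal_alt <- c(A = "G", C = "T", G = "A", T = "C")[[causal_ref]]
    list(model = model, causal_pos = as.integer(causal_pos),
         causal_ref = causal_ref, causal_alt = causal_alt,
         causal_exon_index = as.integer(skippable_exon))
  })
}
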