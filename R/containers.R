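#' Phased cohort container
#'
#' Holds two haplotypes per individual over a [marker_map] together with
#' case/control phenotype labels. Haplotype alleles are coded 0/1 with `NA`
#' for a masked (missing) genotype.
#'
#' @param haplotypes integer matrix with `2 * n` rows (individual i occupies
#'   rows `2i - 1` and `2i`) and one column per marker.
#' @param map a [marker_map].
#' @param samples character vector of individual ids.
#' @param phenotype character vector, `"case"` or `"control"`, per individual.
#' @return An object of class `phased_cohort`.
#' @export
phased_cohort <- function(haplotypes, map, samples, phenotype) {
  validate_marker_map(map)
  n <- length(samples)
  stopifnot(nrow(haplotypes) == 2L * n, ncol(haplotypes) == nrow(map),
            length(phenotype) == n)
  if (!all(phenotype %in% c("case", "control"))) {
    stop("phenotype labels must be 'case' or 'control'", call. = FALSE)
  }
  rownames(haplotypes) <- paste(rep(samples, each = 2L), 1:2, sep = "_h")
  structure(list(haplotypes = haplotypes, map = map, samples = samples,
                 phenotype = phenotype),
            class = "phased_cohort")
}

#' @export
print.phased_cohort <- function(x, ...) {
  cat(sprintf("phased_cohort: %d individuals (%d cases, %d controls), %d markers\n",
              length(x$samples), sum(x$phenotype == "case"),
              sum(x$phenotype == "control"), nrow(x$map)))
  invisible(x)
}

#' Diploid genotype matrix container
#'
#' Genotypes are coded as counts of the alternate (`1`) allele:
#' 0 = hom-ref, 1 = het, 2 = hom-alt, `NA` = missing.
#'
#' @param geno integer matrix, individuals x markers.
#' @param map a [marker_map] with one row per matrix column.
#' @param samples individual ids (rownames of `geno`).
#' @param phenotype optional case/control labels per individual.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, map, samples, phenotype = NULL) {
  validate_marker_map(map)
  stopifnot(nrow(geno) == length(samples), ncol(geno) == nrow(map))
  if (!is.null(phenotype)) stopifnot(length(phenotype) == length(samples))
  rownames(geno) <- samples
  colnames(geno) <- map$name
  structure(list(geno = geno, map = map, samples = samples,
                 phenotype = phenotype),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d markers (%.2f%% missing)\n",
              nrow(x$geno), ncol(x$geno), 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Collapse a phased cohort to a diploid genotype matrix
#'
#' @param cohort a [phased_cohort].
#' @return A [genotype_matrix] with the cohort's map and phenotypes.
#' @export
as_genotype_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "phased_cohort"))
  h <- cohort$haplotypes
  n <- length(cohort$samples)
  g <- h[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    h[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  genotype_matrix(g, cohort$map, cohort$samples, cohort$phenotype)
}

#' Multi-sample variant table container
#'
#' @param variants data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`.
#' @param geno character matrix (variants x samples) of diploid calls in
#'   `{"0/0", "0/1", "1/1", "./."}`.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(variants, geno) {
  stopifnot(all(c("chrom", "pos", "id", "ref", "alt") %in% names(variants)),
            nrow(variants) == nrow(geno))
  if (any(variants$ref == variants$alt)) {
    stop("ref and alt alleles must differ", call. = FALSE)
  }
  if (any(variants$pos < 1L)) stop("positions must be positive", call. = FALSE)
  bad <- !geno %in% c("0/0", "0/1", "1/1", "./.")
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid genotype token '%s' (variant %d, sample column %d)",
                 geno[bad][1L], i[1L], i[2L]), call. = FALSE)
  }
  rownames(geno) <- variants$id
  structure(list(variants = variants, geno = geno), class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d variants x %d samples (%s:%s-%s)\n",
              nrow(x$variants), ncol(x$geno), x$variants$chrom[1L],
              format(min(x$variants$pos), big.mark = ","),
              format(max(x$variants$pos), big.mark = ",")))
  invisible(x)
}

#' Strand-aware gene model bound to sequence
#'
#' Exons are stored in genomic order (ascending start) with a `rank` column
#' giving transcript (5'->3') order. The CDS is delimited by its genomic
#' bounds `cds_lo`/`cds_hi`; exon portions inside those bounds are coding.
#' `seq` holds the genomic sequence of the model's neighbourhood and
#' `seq_offset` the genomic position of its first base, so models living at
#' megabase coordinates can carry a local sequence slice.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome label.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `rank`, `start`, `end`
#'   (1-based inclusive genomic coordinates, non-overlapping).
#' @param cds_lo,cds_hi genomic bounds of the coding region.
#' @param seq genomic sequence (character) covering at least
#'   `[min(start), max(end)]`.
#' @param seq_offset genomic position of `substr(seq, 1, 1)`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds_lo, cds_hi,
                       seq, seq_offset = 1L) {
  stopifnot(strand %in% c("+", "-"),
            all(c("rank", "start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$end < exons$start)) stop("exon end < start", call. = FALSE)
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    stop("exons overlap", call. = FALSE)
  }
  ranks <- sort(exons$rank)
  stopifnot(identical(ranks, seq_len(nrow(exons))))
  span_lo <- min(exons$start); span_hi <- max(exons$end)
  if (seq_offset > span_lo || seq_offset + nchar(seq) - 1L < span_hi) {
    stop("bound sequence does not cover the exon span", call. = FALSE)
  }
  m <- structure(list(gene_id = gene_id, chrom = as.character(chrom),
                      strand = strand, exons = exons,
                      cds_lo = as.integer(cds_lo), cds_hi = as.integer(cds_hi),
                      seq = seq, seq_offset = as.integer(seq_offset)),
                 class = "gene_model")
  if (nchar(build_cds(m)) %% 3L != 0L) {
    stop("total CDS length is not a multiple of 3", call. = FALSE)
  }
  m
}

#' @export
print.gene_model <- function(x, ...) {
  n_cod <- sum(exon_coding_lengths(x) > 0L)
  cat(sprintf("gene_model %s (%s strand, %s): %d exons (%d coding), CDS %d nt\n",
              x$gene_id, x$strand, x$chrom, nrow(x$exons), n_cod,
              sum(exon_coding_lengths(x))))
  invisible(x)
}

#' Simulation ground truth record
#'
#' @param planted_segment list with `chrom`, `start_bp`, `end_bp` of the
#'   planted autozygous risk segment.
#' @param sire_risk_haplotype_id index of the risk haplotype in the founder
#'   pool.
#' @param planted_compatible_variant_ids ids of variants constructed to pass
#'   the recessive-compatibility filter.
#' @param causal_variant_id id of the planted splice-donor variant.
#' @param causal_exon_index transcript rank of the skippable exon.
#' @return An object of class `truth_record`.
#' @export
truth_record <- function(planted_segment, sire_risk_haplotype_id = 1L,
                         planted_compatible_variant_ids = character(),
                         causal_variant_id = NA_character_,
                         causal_exon_index = NA_integer_) {
  structure(list(planted_segment = planted_segment,
                 sire_risk_haplotype_id = sire_risk_haplotype_id,
                 planted_compatible_variant_ids = planted_compatible_variant_ids,
                 causal_variant_id = causal_variant_id,
                 causal_exon_index = causal_exon_index),
            class = "truth_record")
}
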