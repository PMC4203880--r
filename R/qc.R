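# Array QC cascade on diploid genotype matrices.
#
# All thresholds are strict: an individual failing "more than 10% missing"
# is removed, one at exactly 10% is kept; a marker with MAF exactly at the
# floor is kept ("less than 0.5%" removed).

#' QC thresholds
#'
#' @param excluded_chromosome_classes chromosome labels removed outright.
#' @param max_marker_missing markers with missing fraction strictly greater
#'   are removed.
#' @param max_individual_missing individuals with missing fraction strictly
#'   greater are removed.
#' @param min_maf markers with minor allele frequency strictly below are
#'   removed (monomorphic markers always are).
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(excluded_chromosome_classes = c("Y", "MT", "unknown"),
                          max_marker_missing = 0.10,
                          max_individual_missing = 0.10,
                          min_maf = 0.005) {
  assert_prob(max_marker_missing, "max_marker_missing")
  assert_prob(max_individual_missing, "max_individual_missing")
  assert_prob(min_maf, "min_maf")
  structure(list(excluded_chromosome_classes = excluded_chromosome_classes,
                 max_marker_missing = max_marker_missing,
                 max_individual_missing = max_individual_missing,
                 min_maf = min_maf),
            class = "qc_thresholds")
}

subset_markers <- function(gm, keep) {
  genotype_matrix(gm$geno[, keep, drop = FALSE],
                  marker_map(gm$map$name[keep], gm$map$chrom[keep],
                             gm$map$pos[keep]),
                  gm$samples, gm$phenotype)
}

#' Remove markers on excluded chromosome classes
#'
#' @param gm a [genotype_matrix].
#' @param classes chromosome labels to drop (e.g. `c("Y", "MT", "unknown")`).
#' @return list with `matrix` (filtered [genotype_matrix]), `removed`
#'   (named count per class) and `removed_markers`.
#' @export
filter_markers_by_chromosome <- function(gm, classes = c("Y", "MT", "unknown")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  drop <- gm$map$chrom %in% classes
  removed <- vapply(classes, function(cl) sum(gm$map$chrom == cl), integer(1))
  list(matrix = subset_markers(gm, !drop), removed = removed,
       removed_markers = gm$map$name[drop])
}

#' Remove individuals with excess missing genotypes
#'
#' @param gm a [genotype_matrix].
#' @param max_missing individuals whose missing fraction is strictly
#'   greater are removed.
#' @return list with `matrix`, `removed_ids`, `missing_fraction`.
#' @export
filter_individuals_by_callrate <- function(gm, max_missing = 0.10) {
  stopifnot(inherits(gm, "genotype_matrix"))
  assert_prob(max_missing, "max_missing")
  frac <- rowMeans(is.na(gm$geno))
  drop <- frac > max_missing
  if (all(drop)) warning("all individuals removed by call-rate filter",
                         call. = FALSE)
  keep <- !drop
  out <- genotype_matrix(gm$geno[keep, , drop = FALSE], gm$map,
                         gm$samples[keep],
                         if (is.null(gm$phenotype)) NULL else gm$phenotype[keep])
  list(matrix = out, removed_ids = gm$samples[drop],
       missing_fraction = stats::setNames(frac, gm$samples))
}

#' Remove markers with excess missing genotypes
#'
#' @inheritParams filter_individuals_by_callrate
#' @return list with `matrix`, `removed` (count), `removed_markers`.
#' @export
filter_markers_by_callrate <- function(gm, max_missing = 0.10) {
  stopifnot(inherits(gm, "genotype_matrix"))
  assert_prob(max_missing, "max_missing")
  frac <- colMeans(is.na(gm$geno))
  drop <- frac > max_missing
  list(matrix = subset_markers(gm, !drop), removed = sum(drop),
       removed_markers = gm$map$name[drop])
}

#' Minor allele frequencies of a genotype matrix
#'
#' Computed from alternate-allele counts over non-missing diploid calls of
#' the currently retained individuals (denominator 2 x non-missing calls).
#' Markers with no non-missing call get MAF 0.
#'
#' @param gm a [genotype_matrix].
#' @return numeric vector of per-marker MAF.
#' @export
marker_maf <- function(gm) {
  n_called <- colSums(!is.na(gm$geno))
  alt <- colSums(gm$geno, na.rm = TRUE)
  p <- ifelse(n_called > 0L, alt / (2 * n_called), 0)
  pmin(p, 1 - p)
}

#' Remove markers below a minor-allele-frequency floor
#'
#' @param gm a [genotype_matrix].
#' @param min_maf markers with MAF strictly below are removed; monomorphic
#'   and all-missing markers (MAF 0) always are.
#' @return list with `matrix`, `removed`, `removed_markers`, `maf`.
#' @export
filter_markers_by_maf <- function(gm, min_maf = 0.005) {
  stopifnot(inherits(gm, "genotype_matrix"))
  assert_prob(min_maf, "min_maf")
  maf <- marker_maf(gm)
  drop <- maf < min_maf | maf == 0
  list(matrix = subset_markers(gm, !drop), removed = sum(drop),
       removed_markers = gm$map$name[drop],
       maf = stats::setNames(maf, gm$map$name))
}

#' Run the full QC cascade
#'
#' Stages run in the fixed order: chromosome classes, individual call-rate,
#' marker call-rate, minor allele frequency. The report records the
#' executed order, the removal count per stage and the retained totals,
#' which reconcile exactly (`retained = initial - sum(removed)`).
#'
#' @param gm a [genotype_matrix].
#' @param thresholds a [qc_thresholds].
#' @return list of class `qc_result`: `matrix` (QC'd genotypes), `report`
#'   (data.frame: stage, unit, removed, retained), `removed_individuals`,
#'   `mean_call_rate` (per-individual mean over retained markers and
#'   individuals).
#' @export
qc_cascade <- function(gm, thresholds = qc_thresholds()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_markers0 <- ncol(gm$geno)
  n_ind0 <- nrow(gm$geno)
  s1 <- filter_markers_by_chromosome(gm, thresholds$excluded_chromosome_classes)
  s2 <- filter_individuals_by_callrate(s1$matrix,
                                       thresholds$max_individual_missing)
  s3 <- filter_markers_by_callrate(s2$matrix, thresholds$max_marker_missing)
  s4 <- filter_markers_by_maf(s3$matrix, thresholds$min_maf)
  report <- data.frame(
    stage = c("chromosome_class", "individual_callrate", "marker_callrate",
              "maf", "final"),
    unit = c("marker", "individual", "marker", "marker", ""),
    removed = c(sum(s1$removed), length(s2$removed_ids), s3$removed,
                s4$removed, NA_integer_),
    retained = c(ncol(s1$matrix$geno), nrow(s2$matrix$geno),
                 ncol(s3$matrix$geno), ncol(s4$matrix$geno),
                 ncol(s4$matrix$geno)),
    stringsAsFactors = FALSE)
  final <- s4$matrix
  structure(list(matrix = final, report = report,
                 initial = c(markers = n_markers0, individuals = n_ind0),
                 removed_individuals = s2$removed_ids,
                 removed_by_class = s1$removed,
                 mean_call_rate = mean(rowMeans(!is.na(final$geno)))),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("QC cascade (order: chromosome_class > individual_callrate > ",
      "marker_callrate > maf)\n", sep = "")
  print(x$report, row.names = FALSE)
  cat(sprintf("mean per-individual call-rate: %.2f%%\n",
              100 * x$mean_call_rate))
  invisible(x)
}
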