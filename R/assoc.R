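# Genome-wide sliding-window haplotype association with Fisher's exact test
# of allelic association. Each individual contributes two haplotype copies;
# within a window every haplotype above the frequency floor is tested
# one-vs-rest and the window is scored by the minimum p across its tested
# haplotypes.

#' Sliding-window specification
#'
#' @param window_size_snps window width in adjacent SNPs.
#' @param step_snps shift between window starts.
#' @param min_haplotype_freq strict frequency floor: only haplotypes with
#'   overall copy frequency strictly greater are tested.
#' @return list of class `window_spec`.
#' @export
window_spec <- function(window_size_snps = 80L, step_snps = 15L,
                        min_haplotype_freq = 0.05) {
  window_size_snps <- assert_count(window_size_snps, "window_size_snps", TRUE)
  step_snps <- assert_count(step_snps, "step_snps", TRUE)
  if (step_snps > window_size_snps) {
    stop("step must not exceed the window size", call. = FALSE)
  }
  stopifnot(min_haplotype_freq > 0, min_haplotype_freq < 1)
  structure(list(window_size_snps = window_size_snps, step_snps = step_snps,
                 min_haplotype_freq = min_haplotype_freq),
            class = "window_spec")
}

#' Enumerate sliding windows over one chromosome
#'
#' Only full-size windows are emitted: starts at marker indices
#' 1, 1+step, 1+2*step, ...; a chromosome shorter than the window yields no
#' window. The window count is `floor((L - size)/step) + 1` for `L >= size`.
#'
#' @param n_markers markers on the chromosome.
#' @param spec a [window_spec].
#' @return data.frame with columns `start_idx`, `end_idx` (1-based,
#'   inclusive, chromosome-local).
#' @export
enumerate_windows <- function(n_markers, spec = window_spec()) {
  size <- spec$window_size_snps
  if (n_markers < size) {
    return(data.frame(start_idx = integer(0), end_idx = integer(0)))
  }
  starts <- seq.int(1L, n_markers - size + 1L, by = spec$step_snps)
  data.frame(start_idx = starts, end_idx = starts + size - 1L)
}

# haplotype strings for a column range; copies with any missing allele are
# excluded (returned as NA)
window_hap_strings <- function(haplotypes, cols) {
  h <- haplotypes[, cols, drop = FALSE]
  bad <- rowSums(is.na(h)) > 0L
  s <- do.call(paste0, as.data.frame(h))
  s[bad] <- NA_character_
  s
}

#' Haplotype copy counts within a window
#'
#' Counts case and control copies of each distinct haplotype (exact
#' allele-string identity) in the given marker-index window. Copies
#' containing a missing allele are excluded from the counts and reported.
#'
#' @param cohort a [phased_cohort].
#' @param start_idx,end_idx marker column range (1-based inclusive).
#' @return list with `counts` (data.frame: `hap`, `case_copies`,
#'   `control_copies`) and `n_excluded` (copies dropped for missingness).
#' @export
window_haplotype_counts <- function(cohort, start_idx, end_idx) {
  stopifnot(inherits(cohort, "phased_cohort"),
            start_idx >= 1L, end_idx <= ncol(cohort$haplotypes),
            start_idx <= end_idx)
  s <- window_hap_strings(cohort$haplotypes, start_idx:end_idx)
  is_case <- rep(cohort$phenotype == "case", each = 2L)
  ok <- !is.na(s)
  haps <- sort(unique(s[ok]))
  case_copies <- vapply(haps, function(h) sum(s[ok & is_case] == h), integer(1))
  ctrl_copies <- vapply(haps, function(h) sum(s[ok & !is_case] == h), integer(1))
  list(counts = data.frame(hap = haps, case_copies = unname(case_copies),
                           control_copies = unname(ctrl_copies),
                           stringsAsFactors = FALSE),
       n_excluded = sum(!ok))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric enumeration: with margins fixed, the two-sided p is
#' the sum of point probabilities of all tables at most as probable as the
#' observed one (point probabilities compared within a relative tolerance
#' of 1e-7, the conventional guard against floating-point ties). A table
#' with a zero margin has a single attainable configuration and p = 1.
#'
#' @param a,b,c,d non-negative integer cell counts, rows = groups
#'   (case/control), columns = allele or haplotype classes:
#'   `rbind(c(a, b), c(c, d))`.
#' @return two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  a <- assert_count(a, "a"); b <- assert_count(b, "b")
  c <- assert_count(c, "c"); d <- assert_count(d, "d")
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  if (m == 0L || n == 0L || k == 0L || (b + d) == 0L) return(1)
  lo <- max(0L, k - n)
  hi <- min(k, m)
  x <- lo:hi
  dens <- stats::dhyper(x, m, n, k)
  p_obs <- dens[x == a]
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  min(1, max(p, .Machine$double.xmin))
}

#' Genome-wide sliding-window haplotype association scan
#'
#' Scores every full window on every ordinary chromosome (labels in
#' `exclude_chrom` are skipped). Within a window each haplotype whose
#' overall copy frequency exceeds the floor is tested one-vs-rest with
#' [fisher_exact_2x2]; the window's `best_p` is the minimum over tested
#' haplotypes, or 1 (flagged `no_haplotype_tested`) if none qualifies.
#' Raw p-values are reported; `bonferroni = TRUE` adds a column with
#' p adjusted for the number of haplotype tests performed.
#'
#' @param cohort a QC'd, phased [phased_cohort].
#' @param spec a [window_spec].
#' @param exclude_chrom chromosome labels not scanned.
#' @param bonferroni add a Bonferroni-adjusted column.
#' @return data.frame of class `scan_result`, one row per window: `chrom`,
#'   `start_bp`, `end_bp`, `start_idx`, `end_idx` (map-global indices),
#'   `best_hap`, `a`, `b`, `c`, `d` (case-with / case-without /
#'   control-with / control-without copies of the best haplotype), `p`,
#'   `neg_log10_p`, `n_tested`, `no_haplotype_tested`.
#' @export
scan_windows <- function(cohort, spec = window_spec(),
                         exclude_chrom = c("X", "Y", "MT", "unknown"),
                         bonferroni = FALSE) {
  stopifnot(inherits(cohort, "phased_cohort"))
  if (!any(cohort$phenotype == "case") || !any(cohort$phenotype == "control")) {
    stop("association scan needs at least one case and one control",
         call. = FALSE)
  }
  map <- cohort$map
  is_case <- rep(cohort$phenotype == "case", each = 2L)
  chroms <- setdiff(unique(map$chrom), exclude_chrom)
  rows <- list()
  for (ch in chroms) {
    cols <- which(map$chrom == ch)
    wins <- enumerate_windows(length(cols), spec)
    if (nrow(wins) == 0L) next
    for (w in seq_len(nrow(wins))) {
      idx <- cols[wins$start_idx[w]:wins$end_idx[w]]
      s <- window_hap_strings(cohort$haplotypes, idx)
      ok <- !is.na(s)
      tab <- table(s[ok])
      total <- sum(tab)
      qualifying <- names(tab)[tab / total > spec$min_haplotype_freq]
      best <- list(p = 1, hap = NA_character_,
                   a = NA_integer_, b = NA_integer_,
                   c = NA_integer_, d = NA_integer_)
      for (h in qualifying) {
        hit <- ok & s == h
        a <- sum(hit & is_case); b <- sum(ok & is_case) - a
        cc <- sum(hit & !is_case); d <- sum(ok & !is_case) - cc
        p <- fisher_exact_2x2(a, b, cc, d)
        if (is.na(best$hap) || p < best$p) {
          best <- list(p = p, hap = h, a = a, b = b, c = cc, d = d)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start_bp = map$pos[idx[1L]],
        end_bp = map$pos[idx[length(idx)]],
        start_idx = idx[1L], end_idx = idx[length(idx)],
        best_hap = best$hap, a = best$a, b = best$b, c = best$c, d = best$d,
        p = best$p, neg_log10_p = -log10(best$p),
        n_tested = length(qualifying),
        no_haplotype_tested = length(qualifying) == 0L,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    stop("no window could be formed: every chromosome is shorter than the window",
         call. = FALSE)
  }
  res <- res[order(res$chrom, res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  if (bonferroni) {
    res$p_bonferroni <- pmin(1, res$p * sum(res$n_tested))
  }
  class(res) <- c("scan_result", "data.frame")
  res
}

#' Merge the top association windows into a region
#'
#' Windows whose `best_p` ties the global minimum (exact equality on the
#' enumerated value) are grouped; consecutively emitted windows (same
#' chromosome, adjacent in scan order) merge into one bp interval, while
#' tied windows separated by a non-minimal window are reported as separate
#' intervals.
#'
#' @param results a [scan_windows] result.
#' @return data.frame: `chrom`, `start_bp`, `end_bp`, `n_windows`, `p`.
#' @export
top_region <- function(results) {
  if (is.null(results) || nrow(results) == 0L) {
    stop("empty scan result", call. = FALSE)
  }
  pmin_ <- min(results$p)
  hit <- which(results$p == pmin_)
  grp <- cumsum(c(1L, diff(hit) != 1L |
                    results$chrom[hit[-1L]] != results$chrom[hit[-length(hit)]]))
  out <- do.call(rbind, lapply(split(hit, grp), function(ix) {
    data.frame(chrom = results$chrom[ix[1L]],
               start_bp = min(results$start_bp[ix]),
               end_bp = max(results$end_bp[ix]),
               n_windows = length(ix), p = pmin_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
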