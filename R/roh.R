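# Runs-of-homozygosity detection and case/control autozygosity mapping.
#
# A run is a maximal stretch of homozygous calls tolerating a bounded
# number of heterozygous and missing calls; the shared autozygous candidate
# segment is the interval covered by a run in every case and in no control.

#' ROH detection parameters
#'
#' The defaults (>= 50 markers, <= 1 heterozygous call, <= 2 missing calls)
#' are sized so that a ~700 kb homozygous block on a ~3.4 kb-spaced
#' high-density map (~200 markers) is comfortably detected while array-scale
#' noise does not split it.
#'
#' @param min_markers minimum homozygous-run length in markers.
#' @param max_het heterozygous calls tolerated inside one run.
#' @param max_missing missing calls tolerated inside one run.
#' @param require_allele_match require all cases to carry the same
#'   homozygous allele at every informative segment marker
#'   (autozygosity = same ancestral haplotype).
#' @return list of class `roh_params`.
#' @export
roh_params <- function(min_markers = 50L, max_het = 1L, max_missing = 2L,
                       require_allele_match = TRUE) {
  structure(list(min_markers = assert_count(min_markers, "min_markers", TRUE),
                 max_het = assert_count(max_het, "max_het"),
                 max_missing = assert_count(max_missing, "max_missing"),
                 require_allele_match = isTRUE(require_allele_match)),
            class = "roh_params")
}

# non-overlapping maximal runs in one genotype vector (one chromosome),
# returned as local marker-index intervals trimmed to homozygous endpoints
roh_runs_one <- function(g, params) {
  m <- length(g)
  if (m < params$min_markers) {
    return(data.frame(start = integer(0), end = integer(0),
                      n_het = integer(0), n_missing = integer(0)))
  }
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  hom <- !het & !mis
  H <- cumsum(het)
  Mi <- cumsum(mis)
  # r[l] = furthest right end of a window starting at l within both budgets
  r_h <- findInterval(c(0, H)[seq_len(m)] + params$max_het, H)
  r_m <- findInterval(c(0, Mi)[seq_len(m)] + params$max_missing, Mi)
  r <- pmin(r_h, r_m)
  # candidate starts whose untrimmed window could reach min_markers
  cand <- which(r - seq_len(m) + 1L >= params$min_markers)
  runs <- list()
  l <- 1L
  while (length(cand) > 0L) {
    cand <- cand[cand >= l]
    if (length(cand) == 0L) break
    s <- cand[1L]
    e <- r[s]
    # trim to homozygous endpoints
    while (s <= e && !hom[s]) s <- s + 1L
    while (e >= s && !hom[e]) e <- e - 1L
    if (e - s + 1L >= params$min_markers) {
      runs[[length(runs) + 1L]] <- c(
        s, e, sum(het[s:e]), sum(mis[s:e]))
    }
    l <- r[cand[1L]] + 1L
  }
  if (length(runs) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      n_het = integer(0), n_missing = integer(0)))
  }
  out <- as.data.frame(do.call(rbind, runs))
  names(out) <- c("start", "end", "n_het", "n_missing")
  out
}

#' Detect runs of homozygosity
#'
#' Scans each individual chromosome by chromosome for maximal,
#' non-overlapping runs of homozygous genotypes tolerating at most
#' `max_het` heterozygous and `max_missing` missing calls, of at least
#' `min_markers` markers. Run boundaries are reported at the outermost
#' homozygous markers' positions.
#'
#' @param gm a [genotype_matrix].
#' @param params a [roh_params].
#' @param individuals ids to scan (default all).
#' @return data.frame: `individual`, `chrom`, `start_idx`, `end_idx`
#'   (map-global marker indices), `start_bp`, `end_bp`, `n_markers`,
#'   `n_het_used`, `n_missing_used`.
#' @export
detect_roh <- function(gm, params = roh_params(), individuals = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  individuals <- individuals %||% gm$samples
  map <- gm$map
  rows <- list()
  for (ind in individuals) {
    g_all <- gm$geno[match(ind, gm$samples), ]
    for (ch in unique(map$chrom)) {
      cols <- which(map$chrom == ch)
      runs <- roh_runs_one(g_all[cols], params)
      if (nrow(runs) == 0L) next
      gi_s <- cols[runs$start]
      gi_e <- cols[runs$end]
      rows[[length(rows) + 1L]] <- data.frame(
        individual = ind, chrom = ch,
        start_idx = gi_s, end_idx = gi_e,
        start_bp = map$pos[gi_s], end_bp = map$pos[gi_e],
        n_markers = gi_e - gi_s + 1L,
        n_het_used = runs$n_het, n_missing_used = runs$n_missing,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(individual = character(0), chrom = character(0),
                      start_idx = integer(0), end_idx = integer(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_markers = integer(0), n_het_used = integer(0),
                      n_missing_used = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# bp intervals of one individual's ROHs on one chromosome as an IRanges
roh_iranges <- function(roh, ind, ch) {
  r <- roh[roh$individual == ind & roh$chrom == ch, , drop = FALSE]
  IRanges::reduce(IRanges::IRanges(start = r$start_bp, end = r$end_bp))
}

#' Intersect case ROHs into candidate autozygous intervals
#'
#' @param roh a [detect_roh] table.
#' @param case_ids ids of the affected individuals (>= 1).
#' @return data.frame `chrom`, `start_bp`, `end_bp`: maximal intervals
#'   covered by at least one ROH of every case; zero rows if none.
#' @export
intersect_cases <- function(roh, case_ids) {
  if (length(case_ids) == 0L) stop("need at least one case", call. = FALSE)
  out <- list()
  for (ch in unique(roh$chrom[roh$individual %in% case_ids])) {
    acc <- roh_iranges(roh, case_ids[1L], ch)
    for (ind in case_ids[-1L]) {
      if (length(acc) == 0L) break
      acc <- IRanges::intersect(acc, roh_iranges(roh, ind, ch))
    }
    if (length(acc) > 0L) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_bp = IRanges::start(acc), end_bp = IRanges::end(acc),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), start_bp = integer(0),
                      end_bp = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# TRUE if, at every segment marker, the homozygous calls observed among the
# cases agree on one allele (heterozygous calls are covered by the ROH
# allowances; missing calls are ignored)
cases_allele_consistent <- function(gm, case_ids, chrom, start_bp, end_bp) {
  cols <- which(gm$map$chrom == chrom & gm$map$pos >= start_bp &
                  gm$map$pos <= end_bp)
  g <- gm$geno[match(case_ids, gm$samples), cols, drop = FALSE]
  any_ref <- colSums(g == 0L, na.rm = TRUE) > 0L
  any_alt <- colSums(g == 2L, na.rm = TRUE) > 0L
  !any(any_ref & any_alt)
}

#' Exclude candidate segments covered by control homozygosity
#'
#' A candidate interval is discarded if any control carries an ROH fully
#' covering it, and (with `require_allele_match`) if the cases' homozygous
#' genotypes disagree at any marker inside it.
#'
#' @param candidates an [intersect_cases] result.
#' @param roh a [detect_roh] table (controls included).
#' @param gm the [genotype_matrix] the ROHs were called from.
#' @param control_ids ids of unaffected individuals.
#' @param case_ids ids of affected individuals.
#' @param params a [roh_params] (for `require_allele_match`).
#' @return data.frame of class `shared_segment`: `chrom`, `start_bp`,
#'   `end_bp`, `length_kb`, `n_cases`, `n_controls_violating` (always 0 for
#'   retained segments). Zero rows (with a warning) if all candidates are
#'   excluded.
#' @export
exclude_controls <- function(candidates, roh, gm, control_ids, case_ids,
                             params = roh_params()) {
  keep <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    ch <- candidates$chrom[i]
    s <- candidates$start_bp[i]; e <- candidates$end_bp[i]
    covered <- vapply(control_ids, function(ind) {
      r <- roh[roh$individual == ind & roh$chrom == ch, , drop = FALSE]
      any(r$start_bp <= s & r$end_bp >= e)
    }, logical(1))
    ok <- !any(covered)
    if (ok && params$require_allele_match) {
      ok <- cases_allele_consistent(gm, case_ids, ch, s, e)
    }
    keep[i] <- ok
  }
  out <- candidates[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("all candidate segments excluded", call. = FALSE)
    out$length_kb <- integer(0)
    out$n_cases <- integer(0)
    out$n_controls_violating <- integer(0)
    class(out) <- c("shared_segment", "data.frame")
    return(out)
  }
  out$length_kb <- mapply(segment_length_kb, out$start_bp, out$end_bp)
  out$n_cases <- length(case_ids)
  out$n_controls_violating <- 0L
  rownames(out) <- NULL
  class(out) <- c("shared_segment", "data.frame")
  out
}

#' Segment length in kb
#'
#' Boundary-difference convention: `round((end - start)/1000)`, matching
#' marker-position interval reporting (not `end - start + 1`).
#'
#' @param start_bp,end_bp interval boundaries, `end_bp >= start_bp`.
#' @return integer kb.
#' @export
segment_length_kb <- function(start_bp, end_bp) {
  if (end_bp < start_bp) stop("negative span", call. = FALSE)
  as.integer(round((end_bp - start_bp) / 1000))
}

#' Map the shared autozygous segment in one call
#'
#' Convenience wrapper: detect ROHs in all individuals, intersect the
#' cases' runs, and exclude intervals covered by control homozygosity.
#'
#' @param gm a [genotype_matrix] with case/control phenotypes.
#' @param params a [roh_params].
#' @return list with `roh` (all runs), `candidates`, `segments`
#'   (shared segments).
#' @export
map_autozygosity <- function(gm, params = roh_params()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$phenotype)) {
    stop("genotype matrix carries no phenotype labels", call. = FALSE)
  }
  case_ids <- gm$samples[gm$phenotype == "case"]
  control_ids <- gm$samples[gm$phenotype == "control"]
  if (length(case_ids) == 0L) stop("no cases in cohort", call. = FALSE)
  roh <- detect_roh(gm, params)
  candidates <- intersect_cases(roh, case_ids)
  segments <- exclude_controls(candidates, roh, gm, control_ids, case_ids,
                               params)
  list(roh = roh, candidates = candidates, segments = segments)
}
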