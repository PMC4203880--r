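#' Construct a marker map
#'
#' A marker map is an ordered table of array markers: one row per marker with
#' a unique name, a chromosome label (autosome labels plus the special
#' classes `"Y"`, `"MT"` and `"unknown"`) and a 1-based physical position.
#' Positions must be strictly increasing within each chromosome.
#'
#' @param name character vector of unique marker names.
#' @param chrom chromosome label per marker.
#' @param pos 1-based physical position (bp) per marker.
#' @return A `data.frame` of class `marker_map` with columns
#'   `name`, `chrom`, `pos`.
#' @export
marker_map <- function(name, chrom, pos) {
  if (length(name) == 0L) stop("marker map is empty", call. = FALSE)
  map <- data.frame(name = as.character(name), chrom = as.character(chrom),
                    pos = as.integer(pos), stringsAsFactors = FALSE)
  validate_marker_map(map)
  class(map) <- c("marker_map", "data.frame")
  map
}

validate_marker_map <- function(map) {
  stopifnot(all(c("name", "chrom", "pos") %in% names(map)))
  if (anyDuplicated(map$name)) {
    stop("marker names must be unique", call. = FALSE)
  }
  if (any(map$pos < 1L)) stop("marker positions must be >= 1", call. = FALSE)
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0L)) {
      stop("positions must be strictly increasing within chromosome ", ch,
           call. = FALSE)
    }
  }
  invisible(map)
}

#' Simulate a SNP-array marker map
#'
#' Generates a high-density-array-like map: markers on one chromosome at
#' jittered regular spacing (default ~3.4 kb, the density of a 778k bovine
#' array), optionally anchoring markers at exact positions (e.g. the
#' boundaries of a planted risk segment) and appending markers on the
#' special chromosome classes Y / MT / unknown for QC exercises.
#'
#' @param n_markers number of markers on the main chromosome.
#' @param chrom chromosome label for the main chromosome.
#' @param start_bp position of the first marker.
#' @param spacing_bp mean inter-marker distance.
#' @param jitter_bp maximum uniform jitter applied to each grid position.
#' @param anchor_bp positions that must appear exactly as markers (each
#'   replaces the nearest grid marker).
#' @param special named integer vector of extra marker counts per special
#'   chromosome class, e.g. `c(Y = 12, MT = 3, unknown = 7)`.
#' @param seed RNG seed (`NULL` = use current stream).
#' @return A [marker_map].
#' @export
simulate_map <- function(n_markers = 5000, chrom = "17", start_bp = 60000000L,
                         spacing_bp = 3400L, jitter_bp = 1000L,
                         anchor_bp = NULL,
                         special = c(Y = 0L, MT = 0L, unknown = 0L),
                         seed = NULL) {
  n_markers <- assert_count(n_markers, "n_markers", positive = TRUE)
  with_seed(seed, {
    pos <- start_bp + (seq_len(n_markers) - 1L) * spacing_bp +
      as.integer(round(stats::runif(n_markers, -jitter_bp, jitter_bp)))
    pos <- sort(pos)
    # enforce strict monotonicity after jitter
    pos <- as.integer(Reduce(function(a, b) max(a + 1L, b), pos,
                             accumulate = TRUE))
    for (a in anchor_bp) {
      i <- which.min(abs(pos - a))
      pos[i] <- as.integer(a)
    }
    pos <- sort(unique(pos))
    n <- length(pos)
    name <- sprintf("snp%s_%06d", chrom, seq_len(n))
    chroms <- rep(chrom, n)
    for (cls in names(special)) {
      k <- special[[cls]]
      if (k > 0L) {
        name <- c(name, sprintf("snp%s_%06d", cls, seq_len(k)))
        chroms <- c(chroms, rep(cls, k))
        pos <- c(pos, seq_len(k) * 1000L)
      }
    }
    marker_map(name, chroms, pos)
  })
}
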