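# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. seed = NULL leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# length of the intersection of two 1-based inclusive integer intervals
interval_overlap_len <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2) + 1L)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, positive = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) &&
    x >= if (positive) 1 else 0
  if (!ok) {
    stop(sprintf("`%s` must be a %s integer", name,
                 if (positive) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(as.integer(x))
}

DNA_BASES_SIMPLE <- c("A", "C", "G", "T")

# sample() that never falls into the scalar-x trap
resample <- function(x, size = length(x), replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a coding sequence
#'
#' Standard nuclear genetic code, no initiator-codon special-casing (so a
#' subsequence translates the same way wherever it sits in a transcript).
#' An internal stop codon truncates the protein with a warning; a terminal
#' stop is dropped.
#'
#' @param cds coding nucleotide sequence; length must be a multiple of 3.
#' @return Amino-acid sequence (character).
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3L != 0L) {
    stop("coding sequence length is not a multiple of 3", call. = FALSE)
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X",
                                           no.init.codon = TRUE))
  star <- regexpr("*", aa, fixed = TRUE)
  if (star > 0L) {
    if (star < nchar(aa)) {
      warning("internal stop codon at residue ", star,
              "; translation truncated", call. = FALSE)
    }
    aa <- substr(aa, 1L, star - 1L)
  }
  aa
}
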