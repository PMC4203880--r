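# Single-exon skipping consequence prediction on gene models.

model_subseq <- function(model, start, end) {
  substr(model$seq, start - model$seq_offset + 1L, end - model$seq_offset + 1L)
}

#' Coding length of each exon
#'
#' The genomic clip of each exon to the CDS bounds, indexed by transcript
#' rank (element k is the coding length of the exon with rank k; 0 for
#' non-coding exons).
#'
#' @param model a [gene_model].
#' @return integer vector of per-exon coding lengths in transcript order.
#' @export
exon_coding_lengths <- function(model) {
  ex <- model$exons[order(model$exons$rank), , drop = FALSE]
  lo <- pmax(ex$start, model$cds_lo)
  hi <- pmin(ex$end, model$cds_hi)
  pmax(0L, hi - lo + 1L)
}

#' Extract the coding sequence of a gene model
#'
#' Concatenates the coding portions of all exons and reverse-complements
#' the result for minus-strand models.
#'
#' @param model a [gene_model].
#' @param skip_exon optional transcript rank of one exon to leave out
#'   (exon-skipping transcript).
#' @return Coding nucleotide sequence (character). Errors if the length is
#'   not a multiple of 3.
#' @export
build_cds <- function(model, skip_exon = NULL) {
  ex <- model$exons[order(model$exons$start), , drop = FALSE]
  if (!is.null(skip_exon)) {
    stopifnot(skip_exon %in% ex$rank)
    ex <- ex[ex$rank != skip_exon, , drop = FALSE]
  }
  lo <- pmax(ex$start, model$cds_lo)
  hi <- pmin(ex$end, model$cds_hi)
  keep <- hi >= lo
  pieces <- mapply(model_subseq, start = lo[keep], end = hi[keep],
                   MoreArgs = list(model = model))
  cds <- paste(pieces, collapse = "")
  if (model$strand == "-") cds <- revcomp(cds)
  if (nchar(cds) %% 3L != 0L) {
    stop("coding sequence length (", nchar(cds),
         ") is not a multiple of 3", call. = FALSE)
  }
  cds
}

#' Classify the consequence of skipping one exon
#'
#' @param model a [gene_model].
#' @param exon_index transcript rank of the exon.
#' @return `"non_coding"` if the exon contributes no CDS, `"in_frame"` if
#'   its coding length is a positive multiple of 3, `"frameshift"`
#'   otherwise.
#' @export
classify_skip <- function(model, exon_index) {
  len <- exon_coding_lengths(model)
  if (exon_index < 1L || exon_index > length(len)) {
    stop("exon_index out of range", call. = FALSE)
  }
  l <- len[exon_index]
  if (l == 0L) "non_coding" else if (l %% 3L == 0L) "in_frame" else "frameshift"
}

#' Diff a mutant protein against wild type as one contiguous deletion
#'
#' Reports the minimal contiguous block whose removal turns the wild-type
#' protein into the mutant; when flanking repeats make the placement
#' ambiguous the leftmost placement is reported (standard alignment
#' convention).
#'
#' @param wt,mut wild-type and mutant protein sequences (character).
#' @return A list of class `transcript_diff` with `in_frame`, `del_start`,
#'   `del_end` (1-based on the wild-type protein, `NA` if no deletion),
#'   `n_deleted`, `wt_len`, `mut_len`.
#' @export
protein_diff <- function(wt, mut) {
  nw <- nchar(wt); nm <- nchar(mut)
  if (nm > nw) stop("mutant is longer than wild type; not a deletion",
                    call. = FALSE)
  out <- list(in_frame = TRUE, del_start = NA_integer_, del_end = NA_integer_,
              n_deleted = nw - nm, wt_len = nw, mut_len = nm)
  class(out) <- "transcript_diff"
  if (nw == nm) {
    if (wt != mut) stop("equal-length sequences differ; not a deletion",
                        call. = FALSE)
    return(out)
  }
  wv <- strsplit(wt, "")[[1]]
  mv <- strsplit(mut, "")[[1]]
  pre <- 0L
  while (pre < nm && wv[pre + 1L] == mv[pre + 1L]) pre <- pre + 1L
  suf <- 0L
  while (suf < nm - 0L && suf < nm && wv[nw - suf] == mv[nm - suf]) suf <- suf + 1L
  if (pre + suf < nm) {
    stop("sequences are not reconcilable by one contiguous deletion",
         call. = FALSE)
  }
  k <- max(0L, nm - suf)  # leftmost placement
  out$del_start <- k + 1L
  out$del_end <- k + (nw - nm)
  out
}

#' @export
print.transcript_diff <- function(x, ...) {
  if (x$n_deleted == 0L) {
    cat("transcript_diff: identical proteins (", x$wt_len, " aa)\n", sep = "")
  } else {
    cat(sprintf(
      "transcript_diff: in-frame deletion of %d aa (residues %d-%d of %d)\n",
      x$n_deleted, x$del_start, x$del_end, x$wt_len))
  }
  invisible(x)
}

#' Residues removed from annotated protein domains
#'
#' @param diff a [protein_diff] result.
#' @param domains data.frame with columns `name`, `start`, `end` (1-based
#'   residue intervals on the wild-type protein).
#' @return `domains` with an added integer column `removed`.
#' @export
domain_overlap <- function(diff, domains) {
  stopifnot(all(c("name", "start", "end") %in% names(domains)))
  if (is.na(diff$del_start)) {
    domains$removed <- 0L
    return(domains)
  }
  domains$removed <- vapply(seq_len(nrow(domains)), function(i) {
    interval_overlap_len(diff$del_start, diff$del_end,
                         domains$start[i], domains$end[i])
  }, integer(1))
  domains
}

# genomic position -> transcript CDS coordinate (1-based), NA if not coding
cds_index_of <- function(model, genomic_pos) {
  ex <- model$exons[order(model$exons$rank), , drop = FALSE]
  lo <- pmax(ex$start, model$cds_lo)
  hi <- pmin(ex$end, model$cds_hi)
  clen <- pmax(0L, hi - lo + 1L)
  before <- cumsum(c(0L, clen[-length(clen)]))
  for (i in seq_len(nrow(ex))) {
    if (clen[i] > 0L && genomic_pos >= lo[i] && genomic_pos <= hi[i]) {
      off <- if (model$strand == "+") genomic_pos - lo[i] else hi[i] - genomic_pos
      return(before[i] + off + 1L)
    }
  }
  NA_integer_
}

#' Codon coordinates of a genomic position
#'
#' @param model a [gene_model].
#' @param genomic_pos 1-based genomic position; must fall in the CDS.
#' @return list with `codon` (1-based index along the spliced CDS),
#'   `pos_in_codon` (1..3) and `junction_dist` (distance in nt to the
#'   nearest exon/intron junction of the containing exon; 0 at a terminal
#'   exonic base).
#' @export
codon_of_position <- function(model, genomic_pos) {
  ex <- model$exons
  in_exon <- which(genomic_pos >= ex$start & genomic_pos <= ex$end)
  if (length(in_exon) == 0L) {
    span <- genomic_pos >= min(ex$start) & genomic_pos <= max(ex$end)
    stop(if (span) "position is intronic" else "position is outside the gene",
         call. = FALSE)
  }
  i <- cds_index_of(model, genomic_pos)
  if (is.na(i)) stop("position is exonic but untranslated (UTR)", call. = FALSE)
  e <- ex[in_exon, ]
  list(codon = (i - 1L) %/% 3L + 1L,
       pos_in_codon = (i - 1L) %% 3L + 1L,
       junction_dist = min(genomic_pos - e$start, e$end - genomic_pos))
}

#' Predict the protein consequence of skipping one exon
#'
#' Builds wild-type and exon-skipped coding sequences, translates both, and
#' reports the frame class, the deleted-residue interval and any domain
#' losses.
#'
#' @param model a [gene_model].
#' @param exon_index transcript rank of the skipped exon.
#' @param domains optional data.frame (`name`, `start`, `end`) of domain
#'   intervals on the wild-type protein.
#' @return list of class `skip_prediction` with `class`, `wt_protein`,
#'   `mut_protein`, `diff` (for in-frame skips) and `domains` (with a
#'   `removed` column).
#' @export
predict_exon_skip <- function(model, exon_index, domains = NULL) {
  cls <- classify_skip(model, exon_index)
  wt <- translate_cds(build_cds(model))
  out <- list(class = cls, wt_protein = wt, mut_protein = NULL,
              diff = NULL, domains = domains)
  if (cls == "in_frame") {
    mut <- translate_cds(build_cds(model, skip_exon = exon_index))
    out$mut_protein <- mut
    out$diff <- protein_diff(wt, mut)
    if (!is.null(domains)) out$domains <- domain_overlap(out$diff, domains)
  } else if (cls == "frameshift") {
    out$mut_protein <- suppressWarnings(
      translate_cds_frameshift(model, exon_index))
  }
  class(out) <- "skip_prediction"
  out
}

# frameshifted skip: translate the re-framed downstream sequence up to the
# first stop (frame is broken, the product is reported for inspection only)
translate_cds_frameshift <- function(model, exon_index) {
  ex <- model$exons[order(model$exons$start), , drop = FALSE]
  ex <- ex[ex$rank != exon_index, , drop = FALSE]
  lo <- pmax(ex$start, model$cds_lo)
  hi <- pmin(ex$end, model$cds_hi)
  keep <- hi >= lo
  cds <- paste(mapply(model_subseq, start = lo[keep], end = hi[keep],
                      MoreArgs = list(model = model)), collapse = "")
  if (model$strand == "-") cds <- revcomp(cds)
  cds <- substr(cds, 1L, nchar(cds) - nchar(cds) %% 3L)
  translate_cds(cds)
}

#' @export
print.skip_prediction <- function(x, ...) {
  cat("skip_prediction:", x$class, "\n")
  if (!is.null(x$diff)) print(x$diff)
  if (!is.null(x$domains) && "removed" %in% names(x$domains)) {
    for (i in seq_len(nrow(x$domains))) {
      cat(sprintf("  %s (%d-%d): %d residue(s) removed\n",
                  x$domains$name[i], x$domains$start[i], x$domains$end[i],
                  x$domains$removed[i]))
    }
  }
  invisible(x)
}
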