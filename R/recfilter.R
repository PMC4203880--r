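# Three-condition recessive-compatibility filtering of regional
# multi-sample variant tables, and variant classification against gene
# models.
#
# A variant is compatible with fully penetrant recessive inheritance when
# (i) every affected sample is homozygous for the alternate allele,
# (ii) every obligate-carrier sample is heterozygous, and
# (iii) every control-panel sample is homozygous for the reference allele.

#' Role assignment for recessive filtering
#'
#' @param affected sample ids of affected individuals (>= 1).
#' @param carriers sample ids of obligate heterozygous carriers (>= 1).
#' @param panel sample ids of the homozygous-reference control panel.
#' @param second_panel optional ids of a cross-breed exclusion panel used by
#'   [exclude_segregating_elsewhere].
#' @return list of class `role_assignment`.
#' @export
role_assignment <- function(affected, carriers, panel,
                            second_panel = character(0)) {
  roles <- list(affected = as.character(affected),
                carriers = as.character(carriers),
                panel = as.character(panel),
                second_panel = as.character(second_panel))
  if (length(roles$affected) == 0L || length(roles$carriers) == 0L) {
    stop("affected and carrier role sets must be non-empty", call. = FALSE)
  }
  main <- c(roles$affected, roles$carriers, roles$panel)
  if (anyDuplicated(main)) {
    stop("role sets must be disjoint", call. = FALSE)
  }
  structure(roles, class = "role_assignment")
}

#' Restrict a variant table to a genomic interval
#'
#' Boundaries are 1-based inclusive: a record at either boundary position is
#' retained.
#'
#' @param vt a [variant_table].
#' @param chrom chromosome label.
#' @param start_bp,end_bp interval boundaries.
#' @return the restricted [variant_table].
#' @export
restrict_region <- function(vt, chrom, start_bp, end_bp) {
  stopifnot(inherits(vt, "variant_table"))
  keep <- vt$variants$chrom == chrom & vt$variants$pos >= start_bp &
    vt$variants$pos <= end_bp
  variant_table(vt$variants[keep, , drop = FALSE],
                vt$geno[keep, , drop = FALSE])
}

# conditions checked in order (i) affected hom-alt, (ii) carrier het,
# (iii) panel hom-ref; returns "" when compatible, else the first violated
# condition
violated_condition <- function(calls, roles, missing_policy) {
  check <- function(ids, wanted, label) {
    g <- calls[ids]
    if (missing_policy == "strict" && any(g == "./.")) return(label)
    g <- g[g != "./."]
    if (any(g != wanted)) label else ""
  }
  v <- check(roles$affected, "1/1", "i_affected_not_hom_alt")
  if (v != "") return(v)
  v <- check(roles$carriers, "0/1", "ii_carrier_not_het")
  if (v != "") return(v)
  check(roles$panel, "0/0", "iii_panel_not_hom_ref")
}

#' Test one variant record for recessive compatibility
#'
#' @param vt a [variant_table].
#' @param id variant id in `vt`.
#' @param roles a [role_assignment]; every role sample must be a column of
#'   the table.
#' @param missing_policy `"strict"` (a missing call in any required sample
#'   makes the record incompatible — the default) or `"ignore"` (missing
#'   calls are skipped; appropriate for imputation-completed genotypes).
#' @return list with `compatible` (logical) and `violated` (first violated
#'   condition label, `""` when compatible).
#' @export
recessive_compatible <- function(vt, id, roles,
                                 missing_policy = c("strict", "ignore")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(vt, "variant_table"))
  i <- match(id, vt$variants$id)
  if (is.na(i)) stop("unknown variant id: ", id, call. = FALSE)
  need <- c(roles$affected, roles$carriers, roles$panel)
  absent <- setdiff(need, colnames(vt$geno))
  if (length(absent) > 0L) {
    stop("role sample(s) absent from table: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  v <- violated_condition(vt$geno[i, ], roles, missing_policy)
  list(compatible = v == "", violated = v)
}

#' Apply the recessive-compatibility filter to a whole table
#'
#' @inheritParams recessive_compatible
#' @return data.frame, one row per record: `id`, `compatible`, `violated`.
#' @export
filter_recessive <- function(vt, roles,
                             missing_policy = c("strict", "ignore")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(vt, "variant_table"))
  need <- c(roles$affected, roles$carriers, roles$panel)
  absent <- setdiff(need, colnames(vt$geno))
  if (length(absent) > 0L) {
    stop("role sample(s) absent from table: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  violated <- vapply(seq_len(nrow(vt$variants)), function(i) {
    violated_condition(vt$geno[i, ], roles, missing_policy)
  }, character(1))
  data.frame(id = vt$variants$id, compatible = violated == "",
             violated = violated, stringsAsFactors = FALSE)
}

#' Exclude variants segregating in a second panel
#'
#' Variants carrying any non-reference call (`0/1` or `1/1`) in the second
#' (e.g. cross-breed) panel cannot be the breed-specific recessive mutation
#' and are removed. Missing calls are not evidence. With no second panel
#' the input ids are returned unchanged.
#'
#' @param vt a [variant_table].
#' @param ids candidate variant ids (typically the filter survivors).
#' @param second_panel_geno character matrix (variants x samples) of calls
#'   for the second panel, rownames = variant ids; or `NULL`.
#' @return list with `retained` (ids), `excluded` (data.frame `id`,
#'   `n_het`, `n_hom_alt`).
#' @export
exclude_segregating_elsewhere <- function(vt, ids, second_panel_geno = NULL) {
  if (is.null(second_panel_geno) || length(ids) == 0L) {
    return(list(retained = ids,
                excluded = data.frame(id = character(0), n_het = integer(0),
                                      n_hom_alt = integer(0))))
  }
  stopifnot(all(ids %in% rownames(second_panel_geno)))
  g <- second_panel_geno[ids, , drop = FALSE]
  n_het <- rowSums(g == "0/1")
  n_hom <- rowSums(g == "1/1")
  drop <- n_het + n_hom > 0L
  list(retained = ids[!drop],
       excluded = data.frame(id = ids[drop], n_het = unname(n_het[drop]),
                             n_hom_alt = unname(n_hom[drop]),
                             stringsAsFactors = FALSE))
}

#' Classify a variant against gene models
#'
#' A position outside every gene span is `intergenic`; inside a gene but in
#' no exon, `intronic`; in an exon outside the CDS, `utr`; otherwise
#' `coding`, with codon index, position in codon and amino-acid change
#' (substituting the alternate allele, strand-aware). Exonic positions
#' within `splice_window` nt of an exon/intron junction are additionally
#' flagged `splice_region` (the flag, not the class). A position inside
#' several overlapping genes yields one annotation per gene.
#'
#' @param vt a [variant_table].
#' @param id variant id.
#' @param models list of [gene_model]s.
#' @param splice_window exonic distance (nt) from a junction that earns the
#'   splice-region flag.
#' @return data.frame with one row per overlapping gene (or a single
#'   `intergenic` row): `id`, `gene`, `class`, `splice_region`,
#'   `junction_dist`, `codon`, `pos_in_codon`, `aa_ref`, `aa_alt`,
#'   `consequence` (`synonymous`/`missense`, `NA` outside the CDS), and
#'   `effect` — the compact label (`intergenic`, `intronic`, `utr`,
#'   `synonymous`, `missense`, with `,splicing site` appended when the
#'   splice-region flag is set).
#' @export
annotate_variant <- function(vt, id, models, splice_window = 3L) {
  stopifnot(inherits(vt, "variant_table"))
  i <- match(id, vt$variants$id)
  if (is.na(i)) stop("unknown variant id: ", id, call. = FALSE)
  rec <- vt$variants[i, ]
  if (inherits(models, "gene_model")) models <- list(models)
  blank <- data.frame(id = id, gene = NA_character_, class = "intergenic",
                      splice_region = FALSE, junction_dist = NA_integer_,
                      codon = NA_integer_, pos_in_codon = NA_integer_,
                      aa_ref = NA_character_, aa_alt = NA_character_,
                      consequence = NA_character_, effect = "intergenic",
                      stringsAsFactors = FALSE)
  rows <- list()
  for (m in models) {
    span_lo <- min(m$exons$start); span_hi <- max(m$exons$end)
    if (rec$chrom != m$chrom || rec$pos < span_lo || rec$pos > span_hi) next
    r <- blank
    r$gene <- m$gene_id
    in_exon <- which(rec$pos >= m$exons$start & rec$pos <= m$exons$end)
    if (length(in_exon) == 0L) {
      r$class <- "intronic"; r$effect <- "intronic"
    } else {
      e <- m$exons[in_exon, ]
      r$junction_dist <- min(rec$pos - e$start, e$end - rec$pos)
      r$splice_region <- r$junction_dist <= splice_window
      ci <- cds_index_of(m, rec$pos)
      if (is.na(ci)) {
        r$class <- "utr"; r$effect <- "utr"
      } else {
        r$class <- "coding"
        r$codon <- (ci - 1L) %/% 3L + 1L
        r$pos_in_codon <- (ci - 1L) %% 3L + 1L
        if (nchar(rec$ref) == 1L && nchar(rec$alt) == 1L) {
          cds <- build_cds(m)
          alt_sense <- if (m$strand == "+") rec$alt else
            chartr("ACGT", "TGCA", rec$alt)
          mut_cds <- cds
          substr(mut_cds, ci, ci) <- alt_sense
          cstart <- (r$codon - 1L) * 3L + 1L
          r$aa_ref <- unname(Biostrings::GENETIC_CODE[substr(cds, cstart, cstart + 2L)])
          r$aa_alt <- unname(Biostrings::GENETIC_CODE[substr(mut_cds, cstart, cstart + 2L)])
          r$consequence <- if (r$aa_ref == r$aa_alt) "synonymous" else "missense"
          r$effect <- r$consequence
        } else {
          r$effect <- "coding_indel"
        }
      }
      if (r$splice_region) r$effect <- paste0(r$effect, ",splicing site")
    }
    rows[[length(rows) + 1L]] <- r
  }
  if (length(rows) == 0L) return(blank)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotate every variant in a table
#'
#' @inheritParams annotate_variant
#' @param ids variant ids to annotate (default: all).
#' @return row-bound [annotate_variant] output.
#' @export
annotate_variants <- function(vt, models, ids = NULL, splice_window = 3L) {
  ids <- ids %||% vt$variants$id
  out <- do.call(rbind, lapply(ids, annotate_variant, vt = vt,
                               models = models, splice_window = splice_window))
  rownames(out) <- NULL
  out
}
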