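# Readers and writers: PLINK PED/MAP text, phased-haplotype TSV, minimal
# VCF v4.2 (GT only), GFF3 + FASTA gene models, BED, truth JSON.
#
# Coordinates are 1-based inclusive everywhere except BED output, which is
# converted to 0-based half-open at the writer boundary.

provenance_line <- function(prefix = "##", seed = NULL, params = NULL) {
  bits <- c(sprintf("recmapr=%s", as.character(utils::packageVersion("recmapr"))),
            if (!is.null(seed)) sprintf("seed=%s", seed),
            if (!is.null(params)) sprintf("params=%s", params))
  paste0(prefix, "source: ", paste(bits, collapse = " "))
}

# ---- PLINK PED/MAP -------------------------------------------------------

#' Write a genotype matrix as PLINK PED/MAP text
#'
#' Alleles are coded 1 (reference) / 2 (alternate), missing `0 0`;
#' phenotype column is 2 for cases, 1 for controls, -9 when unknown.
#'
#' @param gm a [genotype_matrix].
#' @param ped_path,map_path output paths.
#' @return invisibly, the two paths.
#' @export
write_ped_map <- function(gm, ped_path, map_path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$geno
  a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, "2", "1"))
  a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, "2", "1"))
  n <- nrow(g); m <- ncol(g)
  alle <- matrix("", n, 2L * m)
  alle[, seq(1L, 2L * m, by = 2L)] <- a1
  alle[, seq(2L, 2L * m, by = 2L)] <- a2
  pheno <- if (is.null(gm$phenotype)) rep("-9", n) else
    ifelse(gm$phenotype == "case", "2", "1")
  ped <- data.table::data.table(FID = "FAM1", IID = gm$samples, PAT = "0",
                                MAT = "0", SEX = "0", PHENO = pheno)
  ped <- cbind(ped, data.table::as.data.table(alle))
  data.table::fwrite(ped, ped_path, sep = " ", col.names = FALSE,
                     quote = FALSE)
  write_map(gm$map, map_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Write a marker map as PLINK MAP text
#' @param map a [marker_map].
#' @param path output path.
#' @export
write_map <- function(map, path) {
  data.table::fwrite(data.table::data.table(map$chrom, map$name, 0L, map$pos),
                     path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a PLINK MAP file
#' @param path MAP path (chrom, name, cM, pos).
#' @return a [marker_map].
#' @export
read_map <- function(path) {
  m <- data.table::fread(path, header = FALSE, colClasses = "character")
  if (ncol(m) != 4L) stop("MAP file must have 4 columns", call. = FALSE)
  marker_map(m[[2L]], m[[1L]], as.integer(m[[4L]]))
}

#' Read PLINK PED/MAP text into a genotype matrix
#'
#' Expects biallelic 1/2 allele coding (`0` = missing). Genotypes are
#' returned as alternate-allele counts.
#'
#' @param ped_path,map_path input paths.
#' @return a [genotype_matrix] (phenotype labels recovered from column 6
#'   when coded 1/2).
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- read_map(map_path)
  ped <- data.table::fread(ped_path, header = FALSE, colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6L + 2L * m) {
    k <- ncol(ped) - 6L
    stop(sprintf(
      "PED has %d allele columns for %d markers (expected %d); near marker %d",
      k, m, 2L * m, (min(k, 2L * m) + 1L) %/% 2L), call. = FALSE)
  }
  alle <- as.matrix(ped[, -(1:6), with = FALSE])
  bad <- !alle %in% c("0", "1", "2")
  if (any(bad)) {
    stop("PED allele coding must be 1/2 with 0 for missing; offending value '",
         alle[bad][1L], "'", call. = FALSE)
  }
  a1 <- alle[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  a2 <- alle[, seq(2L, 2L * m, by = 2L), drop = FALSE]
  g <- (a1 == "2") + (a2 == "2")
  g[a1 == "0" | a2 == "0"] <- NA_integer_
  pheno <- ped[[6L]]
  phenotype <- if (all(pheno %in% c("1", "2"))) {
    ifelse(pheno == "2", "case", "control")
  } else NULL
  genotype_matrix(matrix(as.integer(g), nrow(ped), m), map, ped[[2L]],
                  phenotype)
}

# ---- phased haplotype TSV ------------------------------------------------

#' Write a phased cohort as a haplotype TSV
#'
#' One row per haplotype copy: `sample`, `phenotype`, `hap_index` (1/2),
#' `alleles` (0/1 string, `.` for missing). A provenance comment line
#' records the package version and seed.
#'
#' @param cohort a [phased_cohort].
#' @param path output path.
#' @param seed seed recorded in the header comment.
#' @export
write_hap_tsv <- function(cohort, path, seed = NULL) {
  stopifnot(inherits(cohort, "phased_cohort"))
  h <- cohort$haplotypes
  ch <- matrix(as.character(h), nrow(h), ncol(h))
  ch[is.na(ch)] <- "."
  alleles <- do.call(paste0, as.data.frame(ch))
  n <- length(cohort$samples)
  out <- data.frame(sample = rep(cohort$samples, each = 2L),
                    phenotype = rep(cohort$phenotype, each = 2L),
                    hap_index = rep(1:2, n), alleles = alleles,
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line("#", seed = seed), con)
  writeLines(paste(names(out), collapse = "\t"), con)
  writeLines(do.call(paste, c(out, sep = "\t")), con)
  invisible(path)
}

#' Read a haplotype TSV written by [write_hap_tsv]
#'
#' @param path input path.
#' @param map the [marker_map] the haplotypes are defined over.
#' @return a [phased_cohort].
#' @export
read_hap_tsv <- function(path, map) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character")
  stopifnot(all(c("sample", "phenotype", "hap_index", "alleles") %in% names(d)))
  d <- d[order(match(d$sample, unique(d$sample)), d$hap_index), ]
  if (any(nchar(d$alleles) != nrow(map))) {
    stop("allele string length does not match the marker map", call. = FALSE)
  }
  h <- do.call(rbind, strsplit(d$alleles, ""))
  h[h == "."] <- NA
  mode(h) <- "integer"
  samples <- unique(d$sample)
  phenotype <- d$phenotype[match(samples, d$sample)]
  phased_cohort(h, map, samples, phenotype)
}

# ---- minimal VCF v4.2 ----------------------------------------------------

#' Write a variant table as minimal VCF v4.2
#'
#' Emits CHROM POS ID REF ALT QUAL FILTER INFO FORMAT + GT sample columns.
#'
#' @param vt a [variant_table].
#' @param path output path (`.vcf`, plain text).
#' @param seed seed recorded in the header.
#' @export
write_vcf <- function(vt, path, seed = NULL) {
  stopifnot(inherits(vt, "variant_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               provenance_line("##", seed = seed),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(vt$geno)), collapse = "\t")),
             con)
  v <- vt$variants
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", ".", ".", "GT",
                sep = "\t")
  gt <- apply(vt$geno, 1L, paste, collapse = "\t")
  writeLines(paste(body, gt, sep = "\t"), con)
  invisible(path)
}

normalize_gt <- function(g, where) {
  g <- sub("^([0-9.])\\|([0-9.])$", "\\1/\\2", g)
  g[g %in% c(".", "./.")] <- "./."
  g[g == "1/0"] <- "0/1"
  bad <- !g %in% c("0/0", "0/1", "1/1", "./.")
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("malformed genotype token '%s' at %s entry %d",
                 g[i], where, i), call. = FALSE)
  }
  g
}

#' Read a minimal VCF into a variant table
#'
#' Accepts the VCF v4.2 subset CHROM POS ID REF ALT ... FORMAT(GT) samples;
#' phased separators are normalized to unphased (`0|1` -> `0/1`). Only the
#' GT subfield is kept.
#'
#' @param path VCF path (plain or gzipped text).
#' @return a [variant_table].
#' @export
read_vcf_minimal <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(v@gt) == 0L || !all(grepl("GT", v@gt[, "FORMAT"]))) {
    stop("VCF lacks GT genotypes", call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt[is.na(gt)] <- "./."
  geno <- matrix(normalize_gt(as.character(gt), basename(path)),
                 nrow(gt), ncol(gt), dimnames = dimnames(gt))
  ids <- fix[, "ID"]
  miss_id <- is.na(ids) | ids == "."
  ids[miss_id] <- sprintf("%s_%s", fix[miss_id, "CHROM"], fix[miss_id, "POS"])
  variant_table(data.frame(chrom = fix[, "CHROM"],
                           pos = as.integer(fix[, "POS"]),
                           id = ids, ref = fix[, "REF"], alt = fix[, "ALT"],
                           stringsAsFactors = FALSE),
                geno)
}

#' Read a multi-sample variant genotype table
#'
#' `dialect = "vcf"` delegates to [read_vcf_minimal]; `dialect =
#' "s1_table"` reads a TSV with columns `chrom`, `pos`, `id`, `ref`, `alt`
#' followed by one genotype column per sample.
#'
#' @param path input path.
#' @param dialect `"vcf"` or `"s1_table"`.
#' @return a [variant_table].
#' @export
read_variant_table <- function(path, dialect = c("vcf", "s1_table")) {
  dialect <- match.arg(dialect)
  if (dialect == "vcf") return(read_vcf_minimal(path))
  d <- data.table::fread(path, header = TRUE, colClasses = "character")
  fixed <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(fixed %in% names(d))) {
    stop("s1_table needs columns: ", paste(fixed, collapse = ", "),
         call. = FALSE)
  }
  samples <- setdiff(names(d), fixed)
  if (length(samples) == 0L) stop("no sample columns found", call. = FALSE)
  geno <- as.matrix(d[, samples, with = FALSE])
  for (j in seq_along(samples)) {
    geno[, j] <- normalize_gt(geno[, j],
                              sprintf("column '%s'", samples[j]))
  }
  variant_table(data.frame(chrom = d$chrom, pos = as.integer(d$pos),
                           id = d$id, ref = d$ref, alt = d$alt,
                           stringsAsFactors = FALSE),
                geno)
}

#' Write a variant table in the tabular (S1-style) dialect
#' @param vt a [variant_table].
#' @param path output TSV path.
#' @export
write_variant_tsv <- function(vt, path) {
  d <- cbind(vt$variants, as.data.frame(vt$geno, stringsAsFactors = FALSE))
  data.table::fwrite(d, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# ---- gene models: GFF3 + FASTA -------------------------------------------

#' Write a gene model as GFF3
#'
#' Emits gene, mRNA, exon and CDS features with ID/Parent attributes,
#' 1-based inclusive coordinates.
#'
#' @param model a [gene_model].
#' @param path output path.
#' @param seed seed recorded in the header comment.
#' @export
write_gff3 <- function(model, path, seed = NULL) {
  stopifnot(inherits(model, "gene_model"))
  ex <- model$exons[order(model$exons$start), , drop = FALSE]
  gid <- model$gene_id
  tid <- paste0(gid, ".t1")
  lines <- c("##gff-version 3",
             provenance_line("#", seed = seed),
             sprintf("%s\trecmapr\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     model$chrom, min(ex$start), max(ex$end), model$strand, gid),
             sprintf("%s\trecmapr\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                     model$chrom, min(ex$start), max(ex$end), model$strand,
                     tid, gid))
  lines <- c(lines, sprintf(
    "%s\trecmapr\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s;rank=%d",
    model$chrom, ex$start, ex$end, model$strand, tid, ex$rank, tid, ex$rank))
  lo <- pmax(ex$start, model$cds_lo)
  hi <- pmin(ex$end, model$cds_hi)
  keep <- hi >= lo
  # CDS phase: bases to discard before the first full codon, transcript order
  cl <- hi[keep] - lo[keep] + 1L
  ord <- if (model$strand == "+") seq_along(cl) else rev(seq_along(cl))
  before <- cumsum(c(0L, cl[ord][-length(cl)]))
  phase <- (3L - before %% 3L) %% 3L
  phase_genomic <- phase[order(ord)]
  lines <- c(lines, sprintf(
    "%s\trecmapr\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
    model$chrom, lo[keep], hi[keep], model$strand, phase_genomic, tid, tid))
  writeLines(lines, path)
  invisible(path)
}

#' Write a gene model's bound sequence as FASTA
#'
#' The record is named `chrom:offset-end` so that a genomic slice carries
#' its own placement; [read_gene_model] recovers the offset from the name.
#'
#' @param model a [gene_model].
#' @param path output path.
#' @export
write_model_fasta <- function(model, path) {
  s <- Biostrings::DNAStringSet(model$seq)
  names(s) <- sprintf("%s:%d-%d", model$chrom, model$seq_offset,
                      model$seq_offset + nchar(model$seq) - 1L)
  Biostrings::writeXStringSet(s, path, width = 70L)
  invisible(path)
}

parse_fasta_region <- function(nm) {
  m <- regmatches(nm, regexec("^(\\S+?):(\\d+)-(\\d+)$", nm))[[1]]
  if (length(m) == 4L) {
    list(chrom = m[2L], offset = as.integer(m[3L]))
  } else {
    list(chrom = sub("\\s.*$", "", nm), offset = 1L)
  }
}

#' Read a gene model from GFF3 + FASTA
#'
#' Understands the subset written by [write_gff3]: one gene with exon
#' features (transcript order taken from a `rank` attribute when present,
#' otherwise from strand-aware genomic order) and CDS features delimiting
#' the coding bounds. The FASTA record may be named `chrom:start-end` to
#' place a genomic slice (see [write_model_fasta]).
#'
#' @param gff_path GFF3 path.
#' @param fasta_path FASTA path with the covering sequence.
#' @param gene_id gene to extract (default: the first gene feature).
#' @return a [gene_model].
#' @export
read_gene_model <- function(gff_path, fasta_path, gene_id = NULL) {
  g <- data.table::fread(gff_path, header = FALSE, sep = "\t", skip = "\t",
                         col.names = c("seqid", "source", "type", "start",
                                       "end", "score", "strand", "phase",
                                       "attributes"))
  attr_val <- function(attrs, key) {
    v <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
    vapply(v, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
  }
  genes <- g[g$type == "gene", ]
  if (nrow(genes) == 0L) stop("no gene feature in GFF3", call. = FALSE)
  gid <- gene_id %||% attr_val(genes$attributes, "ID")[1L]
  gene <- genes[attr_val(genes$attributes, "ID") == gid, ]
  if (nrow(gene) == 0L) stop("gene not found: ", gid, call. = FALSE)
  strand <- gene$strand[1L]
  mrna <- g[g$type == "mRNA" &
              attr_val(g$attributes, "Parent") == gid, ]
  tid <- if (nrow(mrna) > 0L) attr_val(mrna$attributes, "ID")[1L] else gid
  ex <- g[g$type == "exon" & attr_val(g$attributes, "Parent") == tid, ]
  if (nrow(ex) == 0L) stop("no exon features for ", gid, call. = FALSE)
  rank <- suppressWarnings(as.integer(attr_val(ex$attributes, "rank")))
  if (anyNA(rank)) {
    o <- order(ex$start)
    rank <- integer(nrow(ex))
    rank[o] <- if (strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  }
  cds <- g[g$type == "CDS" & attr_val(g$attributes, "Parent") == tid, ]
  if (nrow(cds) == 0L) stop("no CDS features for ", gid, call. = FALSE)
  fa <- Biostrings::readDNAStringSet(fasta_path)
  reg <- parse_fasta_region(names(fa)[1L])
  gene_model(gene_id = gid, chrom = gene$seqid[1L], strand = strand,
             exons = data.frame(rank = rank, start = ex$start, end = ex$end),
             cds_lo = min(cds$start), cds_hi = max(cds$end),
             seq = as.character(fa[[1L]]), seq_offset = reg$offset)
}

# ---- BED + truth JSON ----------------------------------------------------

#' Write segments as BED (0-based half-open)
#'
#' Internal coordinates are 1-based inclusive; the writer converts to BED's
#' 0-based half-open convention (`chromStart = start_bp - 1`,
#' `chromEnd = end_bp`).
#'
#' @param segments data.frame with `chrom`, `start_bp`, `end_bp` and
#'   optionally `length_kb`.
#' @param path output path.
#' @export
write_bed <- function(segments, path) {
  name <- if ("length_kb" %in% names(segments)) {
    sprintf("segment_%dkb", segments$length_kb)
  } else rep(".", nrow(segments))
  data.table::fwrite(data.table::data.table(segments$chrom,
                                            segments$start_bp - 1L,
                                            segments$end_bp, name),
                     path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED file back to 1-based inclusive segments
#' @param path BED path.
#' @return data.frame `chrom`, `start_bp`, `end_bp`.
#' @export
read_bed <- function(path) {
  d <- data.table::fread(path, header = FALSE)
  data.frame(chrom = as.character(d[[1L]]), start_bp = d[[2L]] + 1L,
             end_bp = d[[3L]], stringsAsFactors = FALSE)
}

#' Write a truth record as JSON
#' @param truth a [truth_record].
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a truth record written by [write_truth_json]
#' @param path JSON path.
#' @return a [truth_record].
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "truth_record")
}
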