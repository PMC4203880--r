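# End-to-end pipeline on synthetic cohorts: simulate -> qc -> assoc -> roh
# -> recessive filter -> splice consequence -> incidence statistics.

#' Default pipeline configuration
#'
#' Nested parameter list for [simulate_study] and [run_pipeline]. Stage
#' seeds are derived deterministically from the master seed. Overrides are
#' merged recursively, e.g.
#' `pipeline_config(seed = 7, cohort = list(n_cases = 4))`.
#'
#' @param seed master RNG seed.
#' @param ... named overrides of config sections (`map`, `pool`, `cohort`,
#'   `variants`, `gene`, `qc`, `window`, `roh`, `domains`, `survey`,
#'   `out_dir`).
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  seed <- assert_count(seed, "seed")
  cfg <- list(
    seed = seed,
    map = list(n_markers = 5000L, chrom = "17", start_bp = 60000000L,
               spacing_bp = 3400L, jitter_bp = 1000L,
               special = c(Y = 0L, MT = 0L, unknown = 0L)),
    pool = list(n_haplotypes = 20L, maf_params = c(0.1, 0.5)),
    risk_segment = list(chrom = "17", start_bp = 65645831L,
                        end_bp = 66358629L),
    cohort = list(n_cases = 9L, n_controls = 37L, dam_carrier_freq = 0.25,
                  recombination_rate_per_bp = 1e-8,
                  genotyping_error_rate = 0, missing_rate = 0),
    variants = list(n_variants = 1825L, n_compatible = 4L,
                    n_panel_samples = 43L, fraction_indels = 141 / 1825),
    gene = list(n_exons = 32L, noncoding_prefix_exons = 6L,
                skippable_exon = 23L, strand = "+",
                target_causal_pos = 65921497L),
    qc = qc_thresholds(),
    window = window_spec(),
    roh = roh_params(),
    domains = data.frame(name = c("HECT", "E2_binding_subdomain"),
                         start = c(673L, 673L), end = c(1052L, 800L),
                         stringsAsFactors = FALSE),
    survey = list(n_genotyped = 129L, n_het = 22L),
    out_dir = NULL)
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]) &&
                       !is.data.frame(cfg[[nm]])) {
      utils::modifyList(cfg[[nm]], over[[nm]])
    } else {
      over[[nm]]
    }
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

stage_seed <- function(seed, k) (seed * 7L + k) %% 2147483647L

#' Simulate a complete synthetic study
#'
#' Generates the coordinated inputs of one mapping study: a marker map
#' anchored at the planted-segment boundaries, a founder haplotype pool with
#' a risk signature, an ascertained half-sib cohort, a gene model placed
#' inside the segment whose planted donor-junction variant sits at
#' `gene$target_causal_pos`, and a regional variant table in which the
#' planted recessive-compatible set includes that causal variant.
#'
#' @param config a [pipeline_config].
#' @return list with `map`, `pool`, `cohort`, `sire`, `gene` (the
#'   [simulate_gene_model] result), `variants` ([variant_table]) and
#'   `truth` ([truth_record]).
#' @export
simulate_study <- function(config = pipeline_config()) {
  seg <- config$risk_segment
  map <- do.call(simulate_map, c(config$map,
                                 list(anchor_bp = c(seg$start_bp, seg$end_bp),
                                      seed = stage_seed(config$seed, 101L))))
  pool <- do.call(simulate_pool,
                  c(list(map = map, risk_segment = seg,
                         seed = stage_seed(config$seed, 202L)),
                    config$pool))
  cspec <- do.call(cohort_spec,
                   c(config$cohort,
                     list(risk_segment = seg,
                          seed = stage_seed(config$seed, 303L))))
  sim <- simulate_half_sib_cohort(pool, cspec)
  # place the gene so the planted donor-junction variant lands on target
  gene_args <- config$gene
  target <- gene_args$target_causal_pos
  gene_args$target_causal_pos <- NULL
  gene_args$chrom <- seg$chrom
  gene_args$seed <- stage_seed(config$seed, 505L)
  gene <- do.call(simulate_gene_model, gene_args)
  if (!is.null(target)) {
    shift <- as.integer(target) - gene$causal_pos
    gene_args$gene_start <- min(gene$model$exons$start) + shift
    gene <- do.call(simulate_gene_model, gene_args)
    stopifnot(gene$causal_pos == target)
  }
  span <- range(gene$model$exons$start, gene$model$exons$end)
  if (span[1L] < seg$start_bp || span[2L] > seg$end_bp) {
    stop("gene model does not fit inside the risk segment", call. = FALSE)
  }
  truth <- sim$truth
  truth$causal_pos <- gene$causal_pos
  truth$causal_ref <- gene$causal_ref
  truth$causal_alt <- gene$causal_alt
  truth$causal_exon_index <- gene$causal_exon_index
  vspec <- do.call(variant_spec,
                   c(list(region = seg, seed = stage_seed(config$seed, 404L)),
                     config$variants))
  vsim <- simulate_variant_table(truth, vspec)
  list(map = map, pool = pool, cohort = sim$cohort, sire = sim$sire,
       gene = gene, variants = vsim$table, truth = vsim$truth,
       config = config)
}

#' Subset a phased cohort by markers and/or individuals
#'
#' @param cohort a [phased_cohort].
#' @param markers marker names to keep (default all).
#' @param samples individual ids to keep (default all).
#' @return the subset [phased_cohort].
#' @export
subset_cohort <- function(cohort, markers = NULL, samples = NULL) {
  stopifnot(inherits(cohort, "phased_cohort"))
  mk <- if (is.null(markers)) seq_len(nrow(cohort$map)) else
    match(markers, cohort$map$name)
  sk <- if (is.null(samples)) seq_along(cohort$samples) else
    match(samples, cohort$samples)
  stopifnot(!anyNA(mk), !anyNA(sk))
  rows <- as.vector(rbind(2L * sk - 1L, 2L * sk))
  phased_cohort(cohort$haplotypes[rows, mk, drop = FALSE],
                marker_map(cohort$map$name[mk], cohort$map$chrom[mk],
                           cohort$map$pos[mk]),
                cohort$samples[sk], cohort$phenotype[sk])
}

#' Run the full mapping pipeline on a synthetic study
#'
#' Executes simulate -> qc -> association scan -> autozygosity mapping ->
#' recessive filter -> variant annotation -> exon-skip prediction ->
#' incidence statistics, and (optionally) writes every artifact with a
#' provenance header to `config$out_dir`.
#'
#' @param config a [pipeline_config].
#' @return list of class `pipeline_result`: `sim`, `qc`, `scan`,
#'   `assoc_region`, `autozygosity`, `segment` (the shared segment used for
#'   filtering), `recfilter` (per-variant verdicts), `compatible_ids`,
#'   `annotation`, `candidate` (annotated causal candidate row),
#'   `skip` ([predict_exon_skip] result), `incidence`, `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$cohort$n_cases < 1L || config$cohort$n_controls < 1L) {
    stop("association and autozygosity stages need at least one case ",
         "and one control", call. = FALSE)
  }
  log_stage <- function(...) message("[recmapr] ", sprintf(...))
  log_stage("simulate: seed %d", config$seed)
  sim <- simulate_study(config)

  gm <- as_genotype_matrix(sim$cohort)
  qc <- qc_cascade(gm, config$qc)
  log_stage("qc: %d -> %d markers, %d -> %d individuals",
            ncol(gm$geno), ncol(qc$matrix$geno), nrow(gm$geno),
            nrow(qc$matrix$geno))
  cohort_qc <- subset_cohort(sim$cohort, markers = qc$matrix$map$name,
                             samples = qc$matrix$samples)

  scan <- scan_windows(cohort_qc, config$window)
  assoc_region <- top_region(scan)
  log_stage("assoc: best p = %.3g over %s:%d-%d", assoc_region$p[1L],
            assoc_region$chrom[1L], assoc_region$start_bp[1L],
            assoc_region$end_bp[1L])

  az <- map_autozygosity(qc$matrix, config$roh)
  if (nrow(az$segments) == 0L) {
    stop("autozygosity stage produced no shared segment", call. = FALSE)
  }
  seg <- az$segments[which.max(az$segments$end_bp - az$segments$start_bp), ]
  log_stage("roh: shared segment %s:%d-%d (%d kb)", seg$chrom, seg$start_bp,
            seg$end_bp, seg$length_kb)

  vt <- restrict_region(sim$variants, seg$chrom, seg$start_bp, seg$end_bp)
  roles <- role_assignment(affected = "affected", carriers = "carrier",
                           panel = grep("^FV", colnames(vt$geno),
                                        value = TRUE))
  verdicts <- filter_recessive(vt, roles)
  compatible_ids <- verdicts$id[verdicts$compatible]
  log_stage("recfilter: %d of %d variants compatible",
            length(compatible_ids), nrow(verdicts))

  annotation <- annotate_variants(vt, sim$gene$model, ids = compatible_ids)
  cand_rows <- annotation[annotation$class == "coding" &
                            annotation$splice_region, , drop = FALSE]
  candidate <- if (nrow(cand_rows) > 0L) cand_rows[1L, ] else NULL

  skip <- NULL
  if (!is.null(candidate)) {
    pos <- vt$variants$pos[match(candidate$id, vt$variants$id)]
    ex <- sim$gene$model$exons
    exon_index <- ex$rank[pos >= ex$start & pos <= ex$end]
    skip <- predict_exon_skip(sim$gene$model, exon_index, config$domains)
    log_stage("splice: exon %d skip is %s", exon_index, skip$class)
  }

  incidence <- incidence_report(carrier_survey(config$survey$n_genotyped,
                                               config$survey$n_het))
  res <- structure(list(
    sim = sim, qc = qc, scan = scan, assoc_region = assoc_region,
    autozygosity = az, segment = seg, recfilter = verdicts,
    compatible_ids = compatible_ids, annotation = annotation,
    candidate = candidate, skip = skip, incidence = incidence,
    provenance = list(package = "recmapr",
                      version = as.character(utils::packageVersion("recmapr")),
                      seed = config$seed, date = format(Sys.Date()))),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_bundle(res, config$out_dir)
  res
}

#' Write a pipeline result bundle to disk
#'
#' Emits the cohort (PED/MAP + phased TSV), variant table (VCF + TSV), gene
#' model (GFF3 + FASTA), truth JSON, QC report, window scan TSV, ROH TSV,
#' shared segments (BED + TSV), annotation TSV and a machine-readable JSON
#' summary. Every text artifact carries the seed in a comment header where
#' the format allows one.
#'
#' @param res a [run_pipeline] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_bundle <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- res$provenance$seed
  p <- function(...) file.path(dir, ...)
  write_ped_map(as_genotype_matrix(res$sim$cohort), p("cohort.ped"),
                p("cohort.map"))
  write_hap_tsv(res$sim$cohort, p("cohort_haplotypes.tsv"), seed = seed)
  write_vcf(res$sim$variants, p("variants.vcf"), seed = seed)
  write_variant_tsv(res$sim$variants, p("variants.tsv"))
  write_gff3(res$sim$gene$model, p("gene.gff3"), seed = seed)
  write_model_fasta(res$sim$gene$model, p("gene.fa"))
  write_truth_json(res$sim$truth, p("truth.json"))
  data.table::fwrite(res$qc$report, p("qc_report.tsv"), sep = "\t")
  data.table::fwrite(as.data.frame(res$scan), p("scan.tsv"), sep = "\t")
  data.table::fwrite(res$autozygosity$roh, p("roh.tsv"), sep = "\t")
  write_bed(res$autozygosity$segments, p("shared_segments.bed"))
  data.table::fwrite(as.data.frame(res$autozygosity$segments),
                     p("shared_segments.tsv"), sep = "\t")
  data.table::fwrite(res$annotation, p("compatible_annotated.tsv"),
                     sep = "\t")
  summary <- list(
    provenance = res$provenance,
    qc = list(report = res$qc$report,
              mean_call_rate = res$qc$mean_call_rate),
    assoc = list(best_p = res$assoc_region$p[1L],
                 region = res$assoc_region[1L, c("chrom", "start_bp",
                                                 "end_bp")]),
    segment = res$segment[, c("chrom", "start_bp", "end_bp", "length_kb")],
    n_compatible = length(res$compatible_ids),
    compatible_ids = res$compatible_ids,
    candidate_id = if (is.null(res$candidate)) NULL else res$candidate$id,
    skip_class = if (is.null(res$skip)) NULL else res$skip$class,
    incidence = res$incidence)
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       dataframe = "rows")
  invisible(dir)
}

#' Read a pipeline configuration from YAML
#'
#' Flat key-tree YAML mirroring [pipeline_config] sections; unknown keys
#' are rejected. Values given override the defaults.
#'
#' @param path YAML path.
#' @param seed optional seed overriding the file's value.
#' @return a [pipeline_config].
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  known <- c("seed", "map", "pool", "risk_segment", "cohort", "variants",
             "gene", "qc", "window", "roh", "domains", "survey", "out_dir")
  bad <- setdiff(names(y), known)
  if (length(bad) > 0L) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) y$seed <- seed
  if (!is.null(y$domains)) y$domains <- as.data.frame(y$domains)
  if (!is.null(y$qc)) y$qc <- do.call(qc_thresholds, y$qc)
  if (!is.null(y$window)) y$window <- do.call(window_spec, y$window)
  if (!is.null(y$roh)) y$roh <- do.call(roh_params, y$roh)
  do.call(pipeline_config, y)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("recmapr pipeline result (seed ", x$provenance$seed, ")\n", sep = "")
  cat(sprintf("  assoc: best p %.3g at %s:%d-%d\n", x$assoc_region$p[1L],
              x$assoc_region$chrom[1L], x$assoc_region$start_bp[1L],
              x$assoc_region$end_bp[1L]))
  cat(sprintf("  shared segment: %s:%d-%d (%d kb)\n", x$segment$chrom,
              x$segment$start_bp, x$segment$end_bp, x$segment$length_kb))
  cat(sprintf("  compatible variants: %d (%s)\n", length(x$compatible_ids),
              paste(x$compatible_ids, collapse = ", ")))
  if (!is.null(x$candidate)) {
    cat(sprintf("  candidate: %s (%s)\n", x$candidate$id, x$candidate$effect))
  }
  if (!is.null(x$skip)) {
    cat(sprintf("  exon skip: %s, %d residues deleted\n", x$skip$class,
                x$skip$diff$n_deleted))
  }
  cat(sprintf("  expected incidence: 1 affected per %d offspring\n",
              x$incidence$one_in_n))
  invisible(x)
}
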