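test_that("founder pool is seed-deterministic and rejects empty maps", {
  map <- tiny_map(10)
  p1 <- simulate_pool(2, map, seed = 11)
  p2 <- simulate_pool(2, map, seed = 11)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_equal(dim(p1$haplotypes), c(2L, 10L))
  expect_true(all(p1$haplotypes %in% 0:1))
  expect_error(simulate_pool(2, NULL), "empty")
  expect_error(simulate_pool(1, map), "at least 2")
})

test_that("pool allele frequencies follow the sampling model", {
  map <- tiny_map(40)
  pool <- simulate_pool(1000, map, maf_params = c(0.5, 0.5), seed = 3)
  freq <- colMeans(pool$haplotypes)
  se3 <- 3 * sqrt(0.25 / 1000)
  expect_true(all(abs(freq - 0.5) <= se3))
})

test_that("risk haplotype carries an exclusive signature across the segment", {
  map <- tiny_map(60)
  seg <- list(chrom = "1", start_bp = map$pos[20], end_bp = map$pos[39])
  pool <- simulate_pool(50, map, risk_segment = seg, seed = 5)
  expect_length(pool$risk_idx, 20L)
  expect_identical(pool$haplotypes[1, pool$risk_idx], pool$signature)
  others <- pool$haplotypes[-1, pool$risk_idx, drop = FALSE]
  expect_true(all(apply(others, 1, function(h) any(h != pool$signature))))
})

test_that("without recombination every sire gamete is a parental haplotype", {
  map <- tiny_map(80)
  seg <- list(chrom = "1", start_bp = map$pos[30], end_bp = map$pos[50])
  pool <- simulate_pool(10, map, risk_segment = seg, seed = 7)
  sim <- simulate_half_sib_cohort(pool, cohort_spec(
    n_cases = 3, n_controls = 5, risk_segment = seg,
    recombination_rate_per_bp = 0, dam_carrier_freq = 0.5, seed = 8))
  n <- length(sim$cohort$samples)
  gametes <- sim$cohort$haplotypes[seq(1, 2 * n, by = 2), , drop = FALSE]
  for (i in seq_len(n)) {
    expect_true(identical(gametes[i, ], sim$sire[1, ]) ||
                  identical(gametes[i, ], sim$sire[2, ]))
  }
})

test_that("recessive phenotype needs two copies: no carrier dams, no cases", {
  map <- tiny_map(80)
  seg <- list(chrom = "1", start_bp = map$pos[30], end_bp = map$pos[50])
  pool <- simulate_pool(10, map, risk_segment = seg, seed = 7)
  sim <- simulate_half_sib_cohort(pool, cohort_spec(
    n_cases = 0, n_controls = 20, risk_segment = seg,
    dam_carrier_freq = 0, seed = 9))
  expect_true(all(sim$cohort$phenotype == "control"))
  seg_idx <- pool$risk_idx
  n <- length(sim$cohort$samples)
  hom_risk <- vapply(seq_len(n), function(i) {
    h <- sim$cohort$haplotypes[(2 * i - 1):(2 * i), seg_idx, drop = FALSE]
    all(h[1, ] == pool$signature) && all(h[2, ] == pool$signature)
  }, logical(1))
  expect_false(any(hom_risk))
  # unreachable quota errors out after a bounded number of draws
  expect_error(
    simulate_half_sib_cohort(pool, cohort_spec(
      n_cases = 1, n_controls = 0, risk_segment = seg,
      dam_carrier_freq = 0, max_draws = 500, seed = 10)),
    "unreachable")
})

test_that("sire transmits the risk segment to half the offspring", {
  map <- tiny_map(60)
  seg <- list(chrom = "1", start_bp = map$pos[20], end_bp = map$pos[45])
  pool <- simulate_pool(10, map, risk_segment = seg, seed = 21)
  # with every dam a carrier, an offspring is a case iff the sire gamete
  # carries the risk segment, so draws-to-quota measure Mendelian 1/2
  sim <- simulate_half_sib_cohort(pool, cohort_spec(
    n_cases = 1000, n_controls = 0, risk_segment = seg,
    dam_carrier_freq = 1, seed = 22))
  p_hat <- 1000 / sim$n_draws
  se3 <- 3 * sqrt(0.25 / sim$n_draws)
  expect_lt(abs(p_hat - 0.5), se3)
})

test_that("affected individuals are homozygous across the planted segment", {
  for (s in c(2, 12, 22)) {
    cfg <- pipeline_config(seed = s, map = list(n_markers = 1500L,
                                                start_bp = 65000000L))
    sim <- simulate_study(cfg)
    seg_idx <- sim$pool$risk_idx
    sig <- sim$pool$signature
    cases <- which(sim$cohort$phenotype == "case")
    for (i in cases) {
      h <- sim$cohort$haplotypes[(2 * i - 1):(2 * i), seg_idx, drop = FALSE]
      expect_identical(unname(h[1, ]), sig)
      expect_identical(unname(h[2, ]), sig)
    }
  }
})

test_that("variant table plants exactly the compatible set", {
  spec <- variant_spec(n_variants = 300, n_compatible = 4, seed = 31)
  vsim <- simulate_variant_table(spec = spec)
  roles <- role_assignment("affected", "carrier",
                           grep("^FV", colnames(vsim$table$geno), value = TRUE))
  verdicts <- filter_recessive(vsim$table, roles)
  expect_identical(sort(verdicts$id[verdicts$compatible]),
                   sort(vsim$truth$planted_compatible_variant_ids))
  expect_length(vsim$truth$planted_compatible_variant_ids, 4L)
  # planted-truth closure: every planted id resolves in the table
  expect_true(all(vsim$truth$planted_compatible_variant_ids %in%
                    vsim$table$variants$id))
})

test_that("variant table honours n_compatible = 0 and fraction_indels = 0", {
  v0 <- simulate_variant_table(spec = variant_spec(
    n_variants = 200, n_compatible = 0, fraction_indels = 0, seed = 32))
  roles <- role_assignment("affected", "carrier",
                           grep("^FV", colnames(v0$table$geno), value = TRUE))
  verdicts <- filter_recessive(v0$table, roles)
  expect_identical(verdicts$id[verdicts$compatible], character(0))
  expect_true(all(nchar(v0$table$variants$ref) == 1L))
  expect_true(all(nchar(v0$table$variants$alt) == 1L))
  expect_error(variant_spec(n_variants = 3, n_compatible = 4), "exceeds")
})

test_that("indel records have ref/alt of unequal length", {
  v <- simulate_variant_table(spec = variant_spec(
    n_variants = 400, n_compatible = 2, fraction_indels = 0.2, seed = 33))
  len_diff <- nchar(v$table$variants$ref) != nchar(v$table$variants$alt)
  expect_equal(sum(len_diff), round(0.2 * 400))
})

test_that("gene model generator is deterministic and frame-checked", {
  g1 <- simulate_gene_model(seed = 41)
  g2 <- simulate_gene_model(seed = 41)
  expect_identical(g1$model$seq, g2$model$seq)
  expect_identical(g1$model$exons, g2$model$exons)
  d1 <- tempfile(fileext = ".fa"); d2 <- tempfile(fileext = ".fa")
  write_model_fasta(g1$model, d1); write_model_fasta(g2$model, d2)
  expect_identical(readLines(d1), readLines(d2))
  f1 <- tempfile(fileext = ".gff3"); f2 <- tempfile(fileext = ".gff3")
  write_gff3(g1$model, f1, seed = 41); write_gff3(g2$model, f2, seed = 41)
  expect_identical(readLines(f1), readLines(f2))
  # a skippable exon whose coding length breaks the frame is rejected
  lens <- c(rep(150L, 6L), rep(120L, 15L), 156L, 119L, rep(120L, 8L), 121L)
  expect_error(
    simulate_gene_model(n_exons = 32, exon_lengths = lens,
                        noncoding_prefix_exons = 6, skippable_exon = 23,
                        seed = 42),
    "frame")
})

test_that("study-level simulation is seed-deterministic", {
  cfg <- pipeline_config(seed = 17, map = list(n_markers = 800L,
                                               start_bp = 65000000L))
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$cohort$haplotypes, s2$cohort$haplotypes)
  expect_identical(s1$variants$geno, s2$variants$geno)
  expect_identical(s1$truth, s2$truth)
})
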