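toy_table <- function() {
  variants <- data.frame(
    chrom = "17", pos = c(100L, 200L, 300L, 400L, 500L),
    id = sprintf("v%d", 1:5), ref = c("G", "A", "C", "T", "G"),
    alt = c("A", "G", "T", "C", "C"), stringsAsFactors = FALSE)
  g <- matrix("0/0", 5, 5,
              dimnames = list(variants$id,
                              c("FV01", "FV02", "FV03", "carrier", "affected")))
  g["v1", ] <- c("0/0", "0/0", "0/0", "0/1", "1/1")  # compatible
  g["v2", ] <- c("0/0", "0/0", "0/0", "1/1", "1/1")  # carrier hom-alt (ii)
  g["v3", ] <- c("0/0", "0/0", "0/0", "0/1", "0/1")  # affected het (i)
  g["v4", ] <- c("0/1", "0/0", "0/0", "0/1", "1/1")  # panel carrier (iii)
  g["v5", ] <- c("0/0", "0/0", "./.", "0/1", "1/1")  # missing panel call
  variant_table(variants, g)
}

toy_roles <- function() {
  role_assignment("affected", "carrier", c("FV01", "FV02", "FV03"))
}

test_that("region restriction is 1-based inclusive on both boundaries", {
  vt <- toy_table()
  r <- restrict_region(vt, "17", 200, 400)
  expect_identical(r$variants$id, c("v2", "v3", "v4"))
  expect_identical(restrict_region(vt, "17", 200, 399)$variants$id,
                   c("v2", "v3"))
  expect_equal(nrow(restrict_region(vt, "18", 1, 1000)$variants), 0L)
})

test_that("the three conditions are checked in order with named violations", {
  vt <- toy_table(); roles <- toy_roles()
  expect_true(recessive_compatible(vt, "v1", roles)$compatible)
  expect_identical(recessive_compatible(vt, "v2", roles)$violated,
                   "ii_carrier_not_het")
  expect_identical(recessive_compatible(vt, "v3", roles)$violated,
                   "i_affected_not_hom_alt")
  expect_identical(recessive_compatible(vt, "v4", roles)$violated,
                   "iii_panel_not_hom_ref")
  # strict policy fails on a missing required call; ignore-missing passes
  expect_false(recessive_compatible(vt, "v5", roles, "strict")$compatible)
  expect_true(recessive_compatible(vt, "v5", roles, "ignore")$compatible)
  # absent role sample errors
  bad <- role_assignment("affected", "carrier", c("FV01", "FV99"))
  expect_error(recessive_compatible(vt, "v1", bad), "FV99")
  expect_error(role_assignment(character(0), "carrier", "FV01"), "non-empty")
  expect_error(role_assignment("x", "x", "FV01"), "disjoint")
})

test_that("compatibility partitions records: verdict XOR one violation", {
  vt <- toy_table()
  verdicts <- filter_recessive(vt, toy_roles())
  expect_identical(verdicts$id[verdicts$compatible], "v1")
  expect_true(all(xor(verdicts$compatible, verdicts$violated != "")))
})

test_that("the filter is order-free in records and sample columns", {
  vsim <- simulate_variant_table(spec = variant_spec(
    n_variants = 150, n_compatible = 3, seed = 61))
  vt <- vsim$table
  roles <- role_assignment("affected", "carrier",
                           grep("^FV", colnames(vt$geno), value = TRUE))
  base <- filter_recessive(vt, roles)
  perm_r <- withr::with_seed(62, sample(nrow(vt$variants)))
  perm_c <- withr::with_seed(63, sample(ncol(vt$geno)))
  vt2 <- variant_table(vt$variants[perm_r, ], vt$geno[perm_r, perm_c])
  shuffled <- filter_recessive(vt2, roles)
  expect_setequal(base$id[base$compatible], shuffled$id[shuffled$compatible])
})

test_that("planted compatibles are recovered exactly on simulated tables", {
  for (s in c(71, 72, 73)) {
    vsim <- simulate_variant_table(spec = variant_spec(seed = s))
    roles <- role_assignment("affected", "carrier",
                             grep("^FV", colnames(vsim$table$geno),
                                  value = TRUE))
    verdicts <- filter_recessive(vsim$table, roles)
    expect_identical(sort(verdicts$id[verdicts$compatible]),
                     sort(vsim$truth$planted_compatible_variant_ids))
  }
})

test_that("second-panel segregation narrows the survivor set", {
  ids <- c("v1", "v2", "v3", "v4")
  vt <- variant_table(
    data.frame(chrom = "17", pos = 1:4 * 100L, id = ids, ref = "G",
               alt = "A", stringsAsFactors = FALSE),
    matrix("0/0", 4, 2, dimnames = list(ids, c("s1", "s2"))))
  # no second panel: identity
  none <- exclude_segregating_elsewhere(vt, ids, NULL)
  expect_identical(none$retained, ids)
  # two of four segregate in the second panel: 4 -> 2
  second <- matrix("0/0", 4, 191, dimnames = list(ids, NULL))
  second["v2", 10] <- "0/1"
  second["v4", c(3, 50)] <- c("0/1", "1/1")
  out <- exclude_segregating_elsewhere(vt, ids, second)
  expect_identical(out$retained, c("v1", "v3"))
  expect_identical(out$excluded$id, c("v2", "v4"))
  expect_equal(out$excluded$n_het, c(1L, 1L))
  expect_equal(out$excluded$n_hom_alt, c(0L, 1L))
  # missing second-panel calls are not evidence
  second2 <- matrix("./.", 4, 10, dimnames = list(ids, NULL))
  expect_identical(exclude_segregating_elsewhere(vt, ids, second2)$retained,
                   ids)
})

test_that("variants classify against the gene model like the worked example", {
  g <- simulate_gene_model(seed = 81)
  m <- g$model
  span <- range(m$exons$start, m$exons$end)
  ids <- c("splice", "intergenic", "intronic")
  pos <- c(g$causal_pos, span[2] + 10000L, m$exons$end[1] + 10L)
  vt <- variant_table(
    data.frame(chrom = "17", pos = pos, id = ids,
               ref = c(g$causal_ref, "A", "A"),
               alt = c(g$causal_alt, "G", "G"), stringsAsFactors = FALSE),
    matrix("0/1", 3, 1, dimnames = list(ids, "s1")))
  ann <- annotate_variants(vt, m)
  sp <- ann[ann$id == "splice", ]
  expect_identical(sp$class, "coding")
  expect_true(sp$splice_region)
  expect_equal(sp$junction_dist, 0L)
  expect_equal(sp$codon, 692L)
  expect_equal(sp$pos_in_codon, 3L)
  expect_identical(sp$consequence, "synonymous")
  expect_identical(sp$effect, "synonymous,splicing site")
  expect_identical(ann$class[ann$id == "intergenic"], "intergenic")
  expect_identical(ann$class[ann$id == "intronic"], "intronic")
})

test_that("coding annotation agrees with a translate-and-compare oracle", {
  g <- simulate_gene_model(seed = 82)
  m <- g$model
  cds <- build_cds(m)
  wt_protein <- translate_oracle(m)
  lo <- pmax(m$exons$start, m$cds_lo)
  hi <- pmin(m$exons$end, m$cds_hi)
  coding_pos <- unlist(mapply(seq, lo[hi >= lo], hi[hi >= lo]))
  withr::with_seed(83, picks <- sample(coding_pos, 25))
  for (pos in picks) {
    i <- match(pos, coding_pos)  # CDS index on the plus strand model
    ref <- substr(cds, i, i)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[sample.int(3, 1)]
    vt <- variant_table(
      data.frame(chrom = "17", pos = pos, id = "x", ref = ref, alt = alt,
                 stringsAsFactors = FALSE),
      matrix("0/1", 1, 1, dimnames = list("x", "s1")))
    ann <- annotate_variant(vt, "x", m)
    mut_cds <- cds
    substr(mut_cds, i, i) <- alt
    mut_model <- m
    mut_protein <- translate_oracle(within_seq_replace(m, pos, alt))
    expect_identical(ann$class, "coding")
    expect_identical(ann$consequence,
                     if (wt_protein == mut_protein) "synonymous"
                     else "missense")
  }
})
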