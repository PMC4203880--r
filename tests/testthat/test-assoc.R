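test_that("window enumeration emits only full windows on the step grid", {
  spec <- window_spec(80, 15)
  expect_equal(nrow(enumerate_windows(80, spec)), 1L)
  expect_equal(nrow(enumerate_windows(95, spec)), 2L)
  expect_equal(nrow(enumerate_windows(79, spec)), 0L)
  w <- enumerate_windows(200, spec)
  expect_equal(w$start_idx, c(1L, 16L, 31L, 46L, 61L, 76L, 91L, 106L, 121L))
  expect_true(all(w$end_idx - w$start_idx + 1L == 80L))
  expect_error(window_spec(10, 11), "step")
})

test_that("haplotype copies are counted by exact string identity", {
  co <- cohort_from_strings(c("0101", "0101", "0101", "0101"),
                            c("case", "control"))
  out <- window_haplotype_counts(co, 1, 4)
  expect_equal(nrow(out$counts), 1L)
  expect_equal(out$counts$case_copies + out$counts$control_copies, 4L)
  co2 <- cohort_from_strings(c("0000", "0001", "0011", "0111"),
                             c("case", "control"))
  out2 <- window_haplotype_counts(co2, 1, 4)
  expect_equal(nrow(out2$counts), 4L)
  expect_true(all(out2$counts$case_copies + out2$counts$control_copies == 1L))
  # a copy with a missing allele is excluded and logged
  co3 <- cohort_from_strings(c("0.01", "0101", "0101", "0101"),
                             c("case", "control"))
  out3 <- window_haplotype_counts(co3, 1, 4)
  expect_equal(out3$n_excluded, 1L)
  expect_equal(sum(out3$counts$case_copies), 1L)
})

test_that("fisher_exact_2x2 matches hand-enumerated tables", {
  expect_equal(fisher_exact_2x2(1, 1, 1, 1), 1)
  expect_equal(fisher_exact_2x2(2, 0, 0, 2), 1 / 3, tolerance = 1e-12)
  # zero margin: only one attainable table
  expect_equal(fisher_exact_2x2(0, 0, 3, 5), 1)
  expect_equal(fisher_exact_2x2(3, 0, 5, 0), 1)
  # the full-segregation table of 18 case alleles vs 23 carrier controls
  expect_equal(fisher_exact_2x2(18, 0, 23, 51),
               fisher_oracle(18, 0, 23, 51), tolerance = 1e-12)
})

test_that("fisher_exact_2x2 agrees with enumeration and fisher.test broadly", {
  withr::with_seed(14, {
    for (i in 1:200) {
      tab <- sample(0:25, 4, replace = TRUE)
      p <- fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4])
      expect_equal(p, fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                   tolerance = 1e-12)
      p_ref <- stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
      expect_equal(p, min(p_ref, 1), tolerance = 1e-9)
    }
  })
})

test_that("fisher p is invariant under row and column swaps", {
  withr::with_seed(15, {
    for (i in 1:50) {
      t4 <- sample(0:20, 4, replace = TRUE)
      p <- fisher_exact_2x2(t4[1], t4[2], t4[3], t4[4])
      expect_equal(fisher_exact_2x2(t4[3], t4[4], t4[1], t4[2]), p,
                   tolerance = 1e-12)
      expect_equal(fisher_exact_2x2(t4[2], t4[1], t4[4], t4[3]), p,
                   tolerance = 1e-12)
    }
  })
})

test_that("concentrating case copies on the risk haplotype never weakens p", {
  # nested family on the risk-enriched side: moving one copy from
  # (case, other) to (case, risk) keeps the case risk fraction above the
  # control fraction (8/38), so the two-sided p can only get more extreme
  for (b in 1:7) {
    p_before <- fisher_exact_2x2(10 - b, b, 8, 30)
    p_after <- fisher_exact_2x2(10 - b + 1, b - 1, 8, 30)
    expect_lte(p_after, p_before + 1e-12)
  }
})

test_that("scan recovers a planted fully penetrant segment", {
  cfg <- pipeline_config(seed = 77, map = list(n_markers = 1200L,
                                               start_bp = 65200000L))
  sim <- simulate_study(cfg)
  sc <- scan_windows(sim$cohort)
  expect_s3_class(sc, "scan_result")
  expect_true(all(diff(sc$start_bp) > 0))
  best <- sc[which.min(sc$p), ]
  expect_lt(best$start_bp, cfg$risk_segment$end_bp)
  expect_gt(best$end_bp, cfg$risk_segment$start_bp)
  expect_equal(best$a + best$b + best$c + best$d,
               2L * length(sim$cohort$samples))
})

test_that("permuting phenotypes destroys the planted signal", {
  cfg <- pipeline_config(seed = 78, map = list(n_markers = 600L,
                                               start_bp = 65200000L))
  sim <- simulate_study(cfg)
  co <- sim$cohort
  sc0 <- scan_windows(co)
  p_obs <- min(sc0$p)
  n_perm <- 60L
  pmins <- withr::with_seed(79, replicate(n_perm, {
    perm <- co
    perm$phenotype <- sample(co$phenotype)
    min(scan_windows(perm)$p)
  }))
  # no permutation comes within three orders of magnitude of the observed
  # association, i.e. the planted signal is label-driven, not structural
  expect_lt(p_obs, 1e-6)
  expect_true(all(pmins > 1000 * p_obs))
})

test_that("a cohort of identical haplotypes scores p = 1 everywhere", {
  hap <- paste(rep("0", 90), collapse = "")
  co <- cohort_from_strings(rep(hap, 12), rep(c("case", "control"), each = 3),
                            map = tiny_map(90))
  sc <- scan_windows(co)
  expect_true(all(sc$p == 1))
})

test_that("top_region merges only adjacent windows tied at the minimum", {
  mk <- function(start, p) {
    data.frame(chrom = "1", start_bp = start, end_bp = start + 79L,
               start_idx = start, end_idx = start + 79L,
               best_hap = "h", a = 1L, b = 1L, c = 1L, d = 1L, p = p,
               neg_log10_p = -log10(p), n_tested = 1L,
               no_haplotype_tested = FALSE, stringsAsFactors = FALSE)
  }
  one <- mk(1, 1e-8)
  expect_equal(nrow(top_region(rbind(one, mk(100, 1e-3)))), 1L)
  # four adjacent tied windows merge into one interval
  four <- do.call(rbind, lapply(c(1, 16, 31, 46), mk, p = 1e-9))
  merged <- top_region(rbind(four, mk(200, 1e-3)))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start_bp, 1L)
  expect_equal(merged$end_bp, 46L + 79L)
  expect_equal(merged$n_windows, 4L)
  # two tied windows separated by a weaker one stay separate intervals
  split2 <- rbind(mk(1, 1e-9), mk(16, 1e-3), mk(31, 1e-9))
  expect_equal(nrow(top_region(split2)), 2L)
})
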