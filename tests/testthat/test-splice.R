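# hand-rolled toy: two exons, fully coding, on a 60 nt contig
toy_model <- function(strand = "+") {
  seq <- paste(rep(c("GCT", "AAA", "CCC", "GGG", "TTT"), 4), collapse = "")
  # exons 5..13 (9 nt) and 20..25 (6 nt), CDS = both in full
  gene_model("toy", "1", strand,
             exons = data.frame(rank = if (strand == "+") 1:2 else 2:1,
                                start = c(5L, 20L), end = c(13L, 25L)),
             cds_lo = 5L, cds_hi = 25L, seq = seq, seq_offset = 1L)
}

test_that("build_cds concatenates coding exon portions strand-aware", {
  m <- toy_model("+")
  cds <- build_cds(m)
  expect_equal(nchar(cds), 15L)
  expect_identical(cds, paste0(substr(m$seq, 5, 13), substr(m$seq, 20, 25)))
  # minus strand equals the reverse complement of the plus-strand extraction
  mm <- toy_model("-")
  expect_identical(build_cds(mm), rc(build_cds(m)))
  # single-exon CDS of 9 nt -> 3 codons
  one <- gene_model("one", "1", "+", data.frame(rank = 1L, start = 3L,
                                                end = 11L),
                    cds_lo = 3L, cds_hi = 11L,
                    seq = "AAGCTGCTGCTAA", seq_offset = 1L)
  expect_equal(nchar(build_cds(one)), 9L)
  expect_equal(nchar(translate_cds(build_cds(one))), 3L)
})

test_that("synthetic models translate like the codon-walk oracle", {
  for (s in c(1, 2)) {
    g <- simulate_gene_model(seed = s,
                             strand = if (s %% 2 == 0) "-" else "+")
    expect_identical(translate_cds(build_cds(g$model)),
                     translate_oracle(g$model))
  }
})

test_that("skip classification follows the coding length mod 3", {
  # coding lengths 121 / 121 / 118 over three exons, plus a non-coding one
  seqs <- withr::with_seed(6, paste(sample(c("A", "C", "G", "T"), 2000,
                                           replace = TRUE), collapse = ""))
  m <- gene_model("t", "1", "+",
                  exons = data.frame(rank = 1:4,
                                     start = c(10L, 200L, 500L, 800L),
                                     end = c(69L, 320L, 620L, 917L)),
                  cds_lo = 200L, cds_hi = 917L, seq = seqs, seq_offset = 1L)
  expect_identical(classify_skip(m, 1L), "non_coding")
  expect_equal((121L + 121L + 118L) %% 3L, 0L)  # model itself is in frame
  expect_identical(classify_skip(m, 2L), "frameshift")
  expect_identical(classify_skip(m, 4L), "frameshift")
  expect_error(classify_skip(m, 9L), "range")
  # the canonical 120-nt coding exon is an in-frame skip
  g <- simulate_gene_model(seed = 3)
  expect_identical(classify_skip(g$model, 23L), "in_frame")
  expect_identical(classify_skip(g$model, 3L), "non_coding")
})

test_that("protein_diff finds the minimal leftmost contiguous deletion", {
  d0 <- protein_diff("MKLAVR", "MKLAVR")
  expect_equal(d0$n_deleted, 0L)
  expect_true(is.na(d0$del_start))
  d1 <- protein_diff("MKLAVR", "MKR")
  expect_equal(c(d1$del_start, d1$del_end), c(3L, 5L))
  # repeat ambiguity resolved leftmost
  d2 <- protein_diff("MAAAK", "MAAK")
  expect_equal(c(d2$del_start, d2$del_end), c(2L, 2L))
  expect_error(protein_diff("MKL", "MAL"), "not a deletion|deletion")
  expect_error(protein_diff("MKLAVR", "MRK"), "contiguous")
  expect_error(protein_diff("MK", "MKL"), "longer")
})

test_that("domain overlap counts removed residues by interval arithmetic", {
  diff <- list(del_start = 653L, del_end = 692L, n_deleted = 40L)
  doms <- data.frame(name = c("E2", "far"), start = c(673L, 800L),
                     end = c(1000L, 900L))
  out <- domain_overlap(diff, doms)
  expect_equal(out$removed, c(20L, 0L))
  # random intervals match per-residue enumeration
  withr::with_seed(5, {
    for (i in 1:30) {
      del <- sort(sample(1:300, 2))
      dom <- sort(sample(1:300, 2))
      got <- domain_overlap(list(del_start = del[1], del_end = del[2]),
                            data.frame(name = "d", start = dom[1],
                                       end = dom[2]))$removed
      brute <- length(intersect(seq(del[1], del[2]), seq(dom[1], dom[2])))
      expect_equal(got, brute)
    }
  })
})

test_that("codon coordinates and junction distances are exact", {
  g <- simulate_gene_model(seed = 7)
  m <- g$model
  first_cds <- min(m$exons$start[m$exons$rank == 7])
  expect_equal(codon_of_position(m, m$cds_lo),
               list(codon = 1L, pos_in_codon = 1L, junction_dist = 0L))
  at_causal <- codon_of_position(m, g$causal_pos)
  expect_equal(at_causal$codon, 692L)
  expect_equal(at_causal$pos_in_codon, 3L)
  expect_equal(at_causal$junction_dist, 0L)
  # intronic and UTR positions produce distinguishable errors
  intron_pos <- m$exons$end[1] + 3L
  expect_error(codon_of_position(m, intron_pos), "intronic")
  utr_pos <- m$exons$start[1] + 1L
  expect_error(codon_of_position(m, utr_pos), "UTR")
  expect_error(codon_of_position(m, max(m$exons$end) + 999L), "outside")
  # random CDS positions agree with a codon-walk oracle
  cds_len <- sum(exon_coding_lengths(m))
  lo <- pmax(m$exons$start, m$cds_lo); hi <- pmin(m$exons$end, m$cds_hi)
  coding_pos <- unlist(mapply(seq, lo[hi >= lo], hi[hi >= lo]))
  withr::with_seed(8, picks <- sample(coding_pos, 20))
  for (pos in picks) {
    i <- match(pos, coding_pos)
    got <- codon_of_position(m, pos)
    expect_equal(got$codon, (i - 1) %/% 3 + 1)
    expect_equal(got$pos_in_codon, (i - 1) %% 3 + 1)
  }
})

test_that("translate-after-skip equals delete-after-translate", {
  for (s in 11:20) {
    g <- random_gene_model(s)
    m <- g$model
    wt <- translate_cds(build_cds(m))
    len <- exon_coding_lengths(m)
    for (k in which(len > 0L & len %% 3L == 0L)) {
      mut <- translate_cds(build_cds(m, skip_exon = k))
      d <- protein_diff(wt, mut)
      expect_equal(d$n_deleted, len[k] / 3L)
      manual <- paste0(substr(wt, 1, d$del_start - 1),
                       substr(wt, d$del_end + 1, nchar(wt)))
      expect_identical(mut, manual)
    }
  }
})

test_that("a model and its reverse-complement mirror translate identically", {
  g <- simulate_gene_model(seed = 9)
  m <- g$model
  L <- nchar(m$seq)
  span_lo <- m$seq_offset; span_hi <- m$seq_offset + L - 1L
  flip <- function(p) span_hi - (p - span_lo)
  mirror <- gene_model(m$gene_id, m$chrom, "-",
                       exons = data.frame(rank = m$exons$rank,
                                          start = flip(m$exons$end),
                                          end = flip(m$exons$start)),
                       cds_lo = flip(m$cds_hi), cds_hi = flip(m$cds_lo),
                       seq = rc(m$seq), seq_offset = span_lo)
  expect_identical(translate_cds(build_cds(mirror)),
                   translate_cds(build_cds(m)))
  expect_identical(classify_skip(mirror, 23L), classify_skip(m, 23L))
})

test_that("skip prediction bundles class, diff and domain loss", {
  g <- simulate_gene_model(seed = 10)
  doms <- data.frame(name = "E2", start = 673L, end = 800L)
  p <- predict_exon_skip(g$model, 23L, domains = doms)
  expect_identical(p$class, "in_frame")
  expect_equal(p$diff$n_deleted, 40L)
  expect_equal(c(p$diff$del_start, p$diff$del_end), c(653L, 692L))
  expect_equal(p$domains$removed, 20L)
  expect_equal(nchar(p$mut_protein), nchar(p$wt_protein) - 40L)
  # skipping a non-coding exon changes nothing downstream
  p2 <- predict_exon_skip(g$model, 2L)
  expect_identical(p2$class, "non_coding")
  expect_null(p2$diff)
})
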