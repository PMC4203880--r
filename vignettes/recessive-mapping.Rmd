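---
title: "Mapping a recessive defect in a half-sib cohort: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive defect in a half-sib cohort: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recmapr)
```

## The problem

Intensive artificial insemination concentrates a handful of sires over a
whole dairy population, so a single heterozygous carrier bull can spread a
recessive defect quickly. The resulting study design is characteristic: a
*half-sib cohort* of affected and unaffected offspring of one carrier sire,
genotyped on a dense SNP array. `recmapr` implements the complete analysis
such a cohort supports:

1. **Array QC** — marker and individual filtering (chromosome classes,
   call rates, minor allele frequency).
2. **Haplotype association** — a sliding window of phased SNP alleles is
   treated as a multi-allelic marker and each frequent haplotype is tested
   case vs. control with Fisher's exact test of allelic association.
3. **Autozygosity mapping** — affected individuals must be identical by
   descent across the causal region, so runs of homozygosity (ROH) shared
   by all cases and absent in all controls delimit the candidate segment.
4. **Recessive-compatibility filtering** — within the segment, a
   multi-sample variant table is reduced to variants where every affected
   animal is homozygous for the alternate allele, the obligate carrier is
   heterozygous, and a reference panel of unrelated animals is homozygous
   reference.
5. **Splice-consequence prediction** — a candidate at an exon's last base
   suggests loss of the splice donor; the package models single-exon
   skipping on a gene model: frame test, mutant protein, deleted-residue
   interval and domain losses.
6. **Incidence statistics** — surveyed carrier frequencies are turned into
   expected affected-offspring rates under random mating.

A synthetic-data generator produces cohorts, variant tables and gene models
with planted ground truth, so every stage can be tested by recovery rather
than by fixture inspection.

## The association statistic

Within a window of `window_size_snps` consecutive SNPs (default 80, stepped
by 15), each individual contributes two haplotype copies. A haplotype with
overall copy frequency strictly above `min_haplotype_freq` (default 5%) is
tested one-vs-rest in the 2×2 table

|            | this haplotype | other haplotypes |
|------------|----------------|------------------|
| case copies    | a | b |
| control copies | c | d |

scored by the two-sided Fisher exact probability: the sum of hypergeometric
point probabilities (margins fixed) of all tables at most as probable as
the observed one, with the conventional `1e-7` relative guard on
floating-point ties. `fisher_exact_2x2()` computes this by direct
enumeration; the test suite checks it against an independent
binomial-coefficient enumeration and against `stats::fisher.test`. A
window's score is the minimum p over its tested haplotypes; raw p-values
are reported (an optional Bonferroni column is available) because the
published analyses of this design report raw minima. Windows are
fixed-size: trailing markers shorter than one window are unscored.

`top_region()` merges adjacently emitted windows whose best p ties the
global minimum *exactly*; ties broken by one haplotype copy are real
differences, not noise, because the statistic is discrete.

## ROH detection and the shared segment

`detect_roh()` reports maximal non-overlapping runs of homozygous
genotypes per individual, tolerating at most `max_het` heterozygous
(default 1) and `max_missing` missing calls (default 2) per run, at least
`min_markers` (default 50) long, with boundaries at the outermost
homozygous markers. These parameters are this package's own defaults,
sized so that a ~700 kb block on a ~3.4 kb-spaced map (~200 markers) is
detected comfortably; no published values exist for this step.

The candidate segment is the interval covered by at least one ROH of
*every* case (`intersect_cases()`, interval arithmetic via IRanges) minus
any candidate fully covered by a control's ROH (`exclude_controls()`).
With `require_allele_match` (default on), all cases must agree on the
homozygous allele at every informative marker in the segment — autozygosity
means the *same* ancestral haplotype, and a marker where two cases are
homozygous for opposite alleles refutes that. Heterozygous calls inside
the segment are tolerated up to the ROH allowances and missing calls are
ignored in this check.

Segment lengths use the boundary-difference convention
`round((end - start)/1000)` kb, matching how marker-delimited intervals
are reported in this literature (the worked boundary pair
65,645,831/66,358,629 gives 713 kb).

## The recessive filter

`recessive_compatible()` checks, in order: (i) every affected sample is
`1/1`, (ii) every obligate carrier is `0/1`, (iii) every panel sample is
`0/0`. The first violated condition is reported, so verdicts partition
records exactly. Published descriptions of this filter sometimes state
condition (i) with the reference allele; the genotype tables and worked
examples make clear the affected animal is homozygous for the *alternate*
allele, which is what this package implements. Under the default `strict`
missing policy a missing call in any required sample makes a record
incompatible; `ignore` skips missing calls and suits
imputation-completed tables. Multi-allelic sites should be decomposed to
ref/alt pairs before filtering (the simulator only emits biallelic
records). A second, cross-population panel can further exclude variants
that segregate outside the affected breed
(`exclude_segregating_elsewhere()`): any non-reference call there
disqualifies a candidate; missing calls are not evidence.

`annotate_variant()` classifies candidates against gene models by pure
overlap (no distance threshold is applied for "intergenic"): intergenic /
intronic / UTR / coding, with codon index, position in codon and
amino-acid change for coding SNVs, and a `splice_region` flag for exonic
positions within 3 nt of an exon/intron junction (the donor-site worked
example sits at distance 0, the exon's final base).

## Exon skipping

`build_cds()` concatenates the coding exon portions (reverse-complemented
on the minus strand); `classify_skip()` calls a skip in-frame iff the
exon's coding length is a positive multiple of 3; `protein_diff()`
reconciles mutant against wild type as one contiguous deletion, resolving
repeat ambiguity to the leftmost placement (the standard alignment
convention); `domain_overlap()` intersects the deleted interval with
domain intervals supplied as configuration (domain coordinates are inputs,
not computed). Translation uses the standard nuclear code; an internal
stop codon truncates the protein with a warning.

The deletion interval is reported as *first..last removed residue*: a
40-residue skip of the worked 32-exon model removes residues 653–692.
Descriptions phrased "between residues 652–692" denote the same event with
flanking-inclusive wording; only the count (40) is unambiguous.

## Incidence model

With sire-side carrier frequency $c_s$ and dam-side $c_d$, the expected
affected fraction under random mating is $c_s c_d / 4$. The two
frequencies are separate arguments because the dam-side frequency is
usually an assumption, not a measurement; `incidence_report()` defaults it
to the surveyed value. With the worked survey (22 heterozygotes of 129
bulls, i.e. 17.1%) this yields one affected calf per
`r one_in_n(expected_affected_rate(22/129, 22/129))` offspring.
Homozygous-affected animals in a survey are counted separately, never as
carriers. Percentages are rounded to one decimal and "one in N" to the
nearest integer, matching the reporting conventions of carrier surveys.

## What the simulator emulates — and what it does not

`simulate_study()` coordinates one synthetic study: a jittered ~3.4 kb
marker grid on one chromosome (anchored so the planted segment's
boundaries are themselves markers), a founder haplotype pool whose first
haplotype carries the risk signature, an ascertained half-sib cohort, a
32-exon gene model inside the segment, and a regional variant table whose
planted compatible set contains the gene's donor-junction variant.

Key design choices, each a deliberate model of the study conditions:

* **Ascertained quotas.** Offspring are drawn by rejection until exactly
  `n_cases` (9) and `n_controls` (37) accumulate, mirroring the
  case/control design; a draw cap (default 10^6) turns impossible quotas
  (e.g. `dam_carrier_freq = 0` with cases requested) into an error.
* **Recombination** is a Poisson crossover process along the map at
  `recombination_rate_per_bp` (default 1e-8, i.e. ~1 cM/Mb) — the
  simplest adequate model at segment scale.
* **Dams are unrelated carriers.** A transmitting dam contributes the
  ancestral risk haplotype over the planted segment (optionally with
  exponentially decaying flanks, `dam_flank_mean_bp`, default 0 — the
  planted object is the sharp segment), spliced into her own background
  haplotype, and dams never carry the sire's own haplotypes. Without
  this, a small founder pool would make controls coincidentally
  autozygous across the region, something a diverse dam population
  precludes.
* **The cohort is the phased product.** Phasing and imputation are
  external to this package's scope, and phasing software emits complete,
  internally consistent haplotypes in which shared ancestral copies stay
  identical. The defaults therefore inject no missingness and no
  independent allele flips (`genotyping_error_rate = 0`,
  `missing_rate = 0`); both knobs exist to emulate *raw* array data for
  QC exercises, where the strict thresholds ("more than 10%", "less than
  0.5%") actually bite.
* **Full penetrance.** An offspring is affected iff both haplotypes carry
  the full signature; truth is recorded before noise injection.
* **Codon-aligned exons.** Synthetic coding exons each have length a
  multiple of 3, so the exon-skip round-trip invariant
  (translate-after-skip = delete-after-translate) holds exactly. The
  worked 32-exon model's skipped exon is codon-aligned at both ends (its
  last base is the third base of codon 692), as is the case for many real
  in-frame skip events; genes with junction-spanning codons would
  additionally substitute one residue at the fusion junction, which this
  generator deliberately does not model.

What passing recovery tests therefore shows: the pipeline's logic —
window scoring, ROH intersection, the three-condition filter, the splice
arithmetic — recovers planted truth under an idealized but structurally
faithful cohort. What it does not show: robustness to phasing switch
errors, genotyping artefacts correlated along the array, population
structure among dams, reduced penetrance, or LD patterns of a real
population (founders are drawn independently per site; no coalescent
simulation).

## Problem sizes and numerical choices

The default synthetic map holds 5,000 markers (~17 Mb at ~3.4 kb spacing)
with a 713 kb planted segment (~210 markers); the default variant table
holds 1,825 sites across 45 samples with 4 planted compatibles. Recovery
properties are evaluated over 100 seeded cohorts. At these sizes the whole
test suite and the acceptance script each run in a few minutes on one CPU.

One recovery property deserves a caveat. Over 100 cohorts the shared ROH
segment contains the planted midpoint essentially always, but the
merged top-association region does so in only ~94–95: when a control's
sire gamete recombines *inside* the segment (expected ~0.3 crossovers per
cohort), one edge window sheds a control haplotype copy, its discrete
Fisher p drops below the interior windows' tie, and the reported region
hugs that segment edge. This is the method's genuine behaviour, not an
implementation artefact: in empirical studies of this design the top
haplotype windows likewise tend to flank the homozygosity segment rather
than centre on it. We kept the physical recombination rate rather than
tuning it down to force the property; the final region in this pipeline
comes from the ROH stage, which is unaffected.

Numerical conventions: coordinates are 1-based inclusive everywhere except
BED output (converted at the writer); Fisher ties are compared within
`1e-7` relative; kb lengths and "one in N" use `round()`; the haplotype
frequency floor and both QC thresholds are strict inequalities; a window
with no haplotype above the floor scores p = 1 and is flagged rather than
dropped.
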