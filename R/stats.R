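# Cohort-level statistics: carrier frequency, Hardy-Weinberg expected
# incidence of affected offspring, and marker/haplotype concordance.

#' Carrier survey container
#'
#' @param n_genotyped animals genotyped.
#' @param n_het heterozygous carriers found.
#' @param n_hom_alt homozygous-alternate animals (counted separately from
#'   carriers, never pooled with them).
#' @return list of class `carrier_survey`; `n_hom_ref` is derived.
#' @export
carrier_survey <- function(n_genotyped, n_het, n_hom_alt = 0L) {
  n_genotyped <- assert_count(n_genotyped, "n_genotyped", positive = TRUE)
  n_het <- assert_count(n_het, "n_het")
  n_hom_alt <- assert_count(n_hom_alt, "n_hom_alt")
  if (n_het + n_hom_alt > n_genotyped) {
    stop("counts exceed the number genotyped", call. = FALSE)
  }
  structure(list(n_genotyped = n_genotyped, n_het = n_het,
                 n_hom_alt = n_hom_alt,
                 n_hom_ref = n_genotyped - n_het - n_hom_alt),
            class = "carrier_survey")
}

#' Carrier frequency of a survey
#'
#' @param survey a [carrier_survey].
#' @return list with `fraction` (`n_het / n_genotyped`), `percent` (rounded
#'   to 1 decimal), and `hom_alt_fraction` reported separately.
#' @export
carrier_frequency <- function(survey) {
  stopifnot(inherits(survey, "carrier_survey"))
  f <- survey$n_het / survey$n_genotyped
  list(fraction = f, percent = round(100 * f, 1),
       hom_alt_fraction = survey$n_hom_alt / survey$n_genotyped)
}

#' Expected affected-offspring rate under random mating
#'
#' Both parents must be carriers and transmit the recessive allele:
#' `c_sire * c_dam / 4`. The two frequencies are separate arguments so a
#' surveyed sire-side frequency can be combined with an assumed dam-side
#' one.
#'
#' @param c_sire,c_dam carrier frequencies in `[0, 1]`.
#' @return probability that a random offspring is affected.
#' @export
expected_affected_rate <- function(c_sire, c_dam = c_sire) {
  assert_prob(c_sire, "c_sire")
  assert_prob(c_dam, "c_dam")
  c_sire * c_dam / 4
}

#' Express a rate as "one in N"
#'
#' @param rate positive probability.
#' @return `round(1/rate)` as integer.
#' @export
one_in_n <- function(rate) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate <= 0) {
    stop("rate must be positive: no affected offspring expected", call. = FALSE)
  }
  as.integer(round(1 / rate))
}

#' Concordance between a marker genotype and a haplotype status
#'
#' Cross-tabulates paired carrier/wild-type marker calls against
#' haplotype presence/absence, flags perfect concordance (both
#' off-diagonal cells zero) and attaches the exact allelic-test p-value.
#'
#' @param marker_calls character vector, `"carrier"` or `"wildtype"`.
#' @param status_calls character vector, `"present"` or `"absent"`
#'   (haplotype status), same length, no missing values.
#' @return list with `table` (2x2 matrix), `perfect` (logical), `p`
#'   ([fisher_exact_2x2]).
#' @export
concordance <- function(marker_calls, status_calls) {
  if (length(marker_calls) != length(status_calls)) {
    stop("paired observations required: length mismatch", call. = FALSE)
  }
  stopifnot(all(marker_calls %in% c("carrier", "wildtype")),
            all(status_calls %in% c("present", "absent")))
  tab <- matrix(c(sum(marker_calls == "carrier" & status_calls == "present"),
                  sum(marker_calls == "carrier" & status_calls == "absent"),
                  sum(marker_calls == "wildtype" & status_calls == "present"),
                  sum(marker_calls == "wildtype" & status_calls == "absent")),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("carrier", "wildtype"),
                                c("haplotype+", "haplotype-")))
  list(table = tab,
       perfect = tab["carrier", "haplotype-"] == 0L &&
         tab["wildtype", "haplotype+"] == 0L,
       p = fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
}

#' Incidence report for a carrier survey
#'
#' @param survey a [carrier_survey] (sire-side).
#' @param c_dam assumed dam-side carrier frequency; defaults to the
#'   surveyed frequency (random mating within one population).
#' @return list with `carrier` ([carrier_frequency] output),
#'   `expected_affected_rate` and `one_in_n`.
#' @export
incidence_report <- function(survey, c_dam = NULL) {
  cf <- carrier_frequency(survey)
  rate <- expected_affected_rate(cf$fraction, c_dam %||% cf$fraction)
  list(carrier = cf, expected_affected_rate = rate,
       one_in_n = if (rate > 0) one_in_n(rate) else NA_integer_)
}
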