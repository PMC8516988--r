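#' Bundled reference top-tables from an HbH-CS cohort
#'
#' Two small example result tables shipped with the package, transcribed from
#' a published screen of immature red blood cells in Hemoglobin H-Constant
#' Spring (HbH-CS) patients versus healthy controls: the top 20
#' hypo-methylated mRNAs (regulation class plus log2 fold changes of m6A
#' quantity and gene expression) and the top 20 hypo-methylated non-coding
#' RNAs (linear methylation-ratio fold change plus unpaired t-test p-value).
#' They serve as worked examples for [classify_regulation()] and
#' [top_table()] and as ready-made fixtures.
#'
#' @param which `"mrna"` or `"noncoding"`.
#' @return A data.frame; loci are printed-style strings parseable with
#'   [parse_locus()].
#' @export
hbhcs_reference_table <- function(which = c("mrna", "noncoding")) {
  which <- match.arg(which)
  file <- switch(which,
                 mrna = "hbhcs_top20_hypo_mrna.tsv",
                 noncoding = "hbhcs_top20_hypo_noncoding.tsv")
  path <- system.file("extdata", file, package = "meriparray", mustWork = TRUE)
  read_tsv(path)
}

#' Bundled cohort characteristics from an HbH-CS study
#'
#' Group summary statistics of the same published cohort: age (mean, SD, n)
#' and sex counts for 15 HbH-CS patients (T) and 16 healthy volunteers (N).
#' Input for [t_test_from_summary()], [chi_square_2x2()] and
#' [cohort_tests()].
#'
#' @return A list with `age_T`, `age_N` (each `mean`, `sd`, `n`) and
#'   `sex_counts` (`female_N`, `female_T`, `male_N`, `male_T`).
#' @export
hbhcs_cohort_summary <- function() {
  list(age_N = list(mean = 17.8, sd = 14.29, n = 16),
       age_T = list(mean = 22.44, sd = 14.16, n = 15),
       sex_counts = c(female_N = 7, female_T = 9, male_N = 9, male_T = 6))
}
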