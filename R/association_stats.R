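#' Pearson correlation with exact small-sample p-value
#'
#' Sample Pearson correlation between two vectors with the two-sided p-value
#' from the exact t-transform `t = r * sqrt((n-2)/(1-r^2))` on `n - 2`
#' degrees of freedom (not a normal approximation — the correlations this
#' pipeline reports are computed on cohorts as small as 10 + 10).
#'
#' @param x,y numeric vectors of equal length >= 3, finite, each with
#'   nonzero variance.
#' @return A list with `r`, the two-sided `p`, and `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    stop("pearson_correlation: x and y must have equal length", call. = FALSE)
  }
  if (length(x) < 3) {
    stop("pearson_correlation: need at least 3 paired observations",
         call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("pearson_correlation: values must be finite", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("pearson_correlation: zero variance; correlation undefined",
         call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Unpaired t-test from group summary statistics
#'
#' Two-sided unpaired t-test computed from per-group mean, SD and n alone —
#' the form needed to re-test published cohort tables that print only
#' `mean +/- SD`. Pooled-variance (Student) by default; Welch with
#' Satterthwaite degrees of freedom optionally. Equivalent to
#' [unpaired_t_test()] on any raw data having exactly these moments.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @param variant `"student"` (default) or `"welch"`.
#' @return A list with `t`, `df` and the two-sided `p`. Both SDs zero gives
#'   the documented limits `p = 1` (equal means) or `p = 0`.
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                variant = c("student", "welch")) {
  variant <- match.arg(variant)
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2)
  if (sd1 == 0 && sd2 == 0) {
    df <- n1 + n2 - 2
    if (mean1 == mean2) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(mean1 - mean2) * Inf, df = df, p = 0))
  }
  if (variant == "student") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Chi-square test of independence with 1 degree of freedom on the table
#' `rbind(c(a, b), c(c, d))`, without continuity correction by default (with
#' group sizes around 15 per arm the uncorrected statistic is what published
#' cohort sex-ratio p-values reproduce); Yates correction optional.
#'
#' @param a,b,c,d non-negative cell counts (row 1: `a`, `b`; row 2: `c`,
#'   `d`). All row and column margins must be positive.
#' @param continuity apply the Yates continuity correction.
#' @return A list with `chi2`, `df` (= 1) and `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d, continuity = FALSE) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("chi_square_2x2: counts must be finite and non-negative",
         call. = FALSE)
  }
  m <- rbind(c(a, b), c(c, d))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("chi_square_2x2: all margins must be positive", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = continuity))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Summarize a cohort table and test group differences
#'
#' Convenience wrapper reproducing clinical-characteristics tables: an
#' age-style continuous variable tested with [t_test_from_summary()] and a
#' sex-style 2x2 count table tested with [chi_square_2x2()].
#'
#' @param age_T,age_N lists with `mean`, `sd`, `n` per group.
#' @param sex_counts 2x2 counts `c(female_N, female_T, male_N, male_T)`.
#' @param variant t-test variant.
#' @param continuity continuity correction for the chi-square test.
#' @return data.frame with one row per characteristic: test statistic and p.
#' @export
cohort_tests <- function(age_T, age_N, sex_counts,
                         variant = c("student", "welch"), continuity = FALSE) {
  variant <- match.arg(variant)
  tt <- t_test_from_summary(age_N$mean, age_N$sd, age_N$n,
                            age_T$mean, age_T$sd, age_T$n, variant = variant)
  cs <- chi_square_2x2(sex_counts[1], sex_counts[2], sex_counts[3],
                       sex_counts[4], continuity = continuity)
  data.frame(
    characteristic = c("age", "sex"),
    test = c(paste0(variant, " t-test"), "pearson chi-square"),
    statistic = c(tt$t, cs$chi2),
    df = c(tt$df, cs$df),
    p = c(tt$p, cs$p),
    stringsAsFactors = FALSE
  )
}
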