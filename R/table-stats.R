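#' Welch's t-test from printed summary statistics
#'
#' Reconstructs the two-sample unequal-variance t-test from group means,
#' standard deviations and sizes, as needed to check the continuous rows of
#' a published baseline-characteristics table:
#' t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2) with the Welch-Satterthwaite
#' degrees of freedom. The pooled-variance Student test is available for
#' comparison.
#'
#' @param mean1,sd1,n1 first group's summary.
#' @param mean2,sd2,n2 second group's summary.
#' @param pooled use the pooled-variance Student test instead (default
#'   FALSE).
#' @return list: `t`, `df`, `p_value` (two-sided).
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                 pooled = FALSE) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be non-negative")
  if (sd1 == 0 && sd2 == 0) stop("at least one group needs positive variance")
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Yates continuity-corrected chi-square test on a 2x2 table
#'
#' chi^2 = N (|ad - bc| - N/2)^2 / (R1 R2 C1 C2), clamped to 0 when
#' |ad - bc| <= N/2; p from the chi-square distribution with 1 df. This is
#' the standard test for a gender-by-group contingency row of a baseline
#' table.
#'
#' @param a,b first row cell counts; @param c,d second row cell counts
#'   (rows = groups, columns = category levels).
#' @return list: `chi2`, `df` (= 1), `p_value`.
#' @export
yates_chi2_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  N <- sum(cells)
  R1 <- a + b; R2 <- c + d; C1 <- a + c; C2 <- b + d
  if (any(c(R1, R2, C1, C2) == 0)) stop("zero margin in 2x2 table")
  delta <- abs(a * d - b * c)
  chi2 <- if (delta <= N / 2) 0 else N * (delta - N / 2)^2 / (R1 * R2 * C1 * C2)
  list(chi2 = chi2, df = 1L, p_value = stats::pchisq(chi2, 1, lower.tail = FALSE))
}
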