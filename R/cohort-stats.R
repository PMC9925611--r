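# Descriptive group-comparison statistics of the baseline-characteristics
# table: Welch t-tests recomputable from printed summary statistics, a 2x2
# chi-square on sex, and Pearson correlations.

#' Welch t-test from summary statistics
#'
#' Unequal-variance (Welch) two-sample t statistic and Welch-Satterthwaite
#' degrees of freedom computed directly from per-group means, SDs and counts,
#' as needed to recompute a published baseline table:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)`.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return A tibble with columns `t`, `df` and `p` (two-sided).
#' @examples
#' welch_t_from_summary(122.97, 27.76, 65, 122.46, 26.55, 39)
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0) stop("group SDs must be positive")
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble::tibble(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square on a 2x2 table
#'
#' Pearson chi-square without continuity correction,
#' `sum((O - E)^2 / E)` with expected counts from the margins, on the table
#' `rbind(c(a, b), c(c, d))` (1 degree of freedom).
#'
#' @param a,b,c,d Cell counts (row-wise).
#' @return A tibble with columns `stat`, `df` (= 1) and `p` (upper tail).
#' @examples
#' chi_square_2x2(33, 32, 17, 22)
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative")
  tab <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all margins of the 2x2 table must be positive")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  tibble::tibble(stat = stat, df = 1L,
                 p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Pearson correlation with its degrees of freedom
#'
#' Sample Pearson correlation of two paired vectors, reported with the
#' `r(df)` convention `df = n - 2` used in baseline tables.
#'
#' @param x,y Paired numeric vectors.
#' @return A tibble with columns `r`, `df` and `p` (two-sided, t reference).
#' @examples
#' pearson_r(c(1, 2, 3), c(6, 4, 2))
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  n <- length(x)
  if (n < 3) stop("at least 3 pairs required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined")
  }
  r <- stats::cor(x, y)
  df <- n - 2L
  t <- r * sqrt(df / (1 - r^2))
  p <- if (is.finite(t)) 2 * stats::pt(-abs(t), df) else 0
  tibble::tibble(r = r, df = df, p = p)
}

#' Baseline characteristics table of a cohort
#'
#' Builds a Table-1-style group comparison between the VPT and FT groups:
#' Welch t-tests on birth weight, gestational age, age at assessment and (when
#' present) socio-economic score, and an uncorrected chi-square on sex.
#'
#' @param clinical A validated clinical table.
#' @return A tibble with one row per characteristic: group means (SDs) or
#'   counts and the comparison statistic.
#' @export
cohort_summary <- function(clinical) {
  clinical <- validate_clinical(clinical)
  vpt <- clinical[clinical$group == "VPT", ]
  ft <- clinical[clinical$group == "FT", ]
  if (!nrow(vpt) || !nrow(ft)) stop("both groups must be non-empty")
  cont_row <- function(label, col) {
    if (!col %in% names(clinical) || anyNA(clinical[[col]])) return(NULL)
    w <- welch_t_from_summary(
      mean(vpt[[col]]), stats::sd(vpt[[col]]), nrow(vpt),
      mean(ft[[col]]), stats::sd(ft[[col]]), nrow(ft))
    tibble::tibble(
      characteristic = label,
      vpt = sprintf("%.2f (%.2f)", mean(vpt[[col]]), stats::sd(vpt[[col]])),
      ft = sprintf("%.2f (%.2f)", mean(ft[[col]]), stats::sd(ft[[col]])),
      statistic = sprintf("t(%.2f) = %.2f", w$df, w$t), p = w$p)
  }
  sex <- chi_square_2x2(sum(vpt$sex == "F"), sum(vpt$sex == "M"),
                        sum(ft$sex == "F"), sum(ft$sex == "M"))
  dplyr::bind_rows(
    cont_row("birth_weight_g", "birth_weight_g"),
    cont_row("ga_weeks", "ga_weeks"),
    cont_row("age_months", "age_months"),
    tibble::tibble(
      characteristic = "sex",
      vpt = sprintf("%dF/%dM", sum(vpt$sex == "F"), sum(vpt$sex == "M")),
      ft = sprintf("%dF/%dM", sum(ft$sex == "F"), sum(ft$sex == "M")),
      statistic = sprintf("X2(1, N = %d) = %.2f", nrow(clinical), sex$stat),
      p = sex$p),
    cont_row("ses", "ses"))
}
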