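#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by the minimum-likelihood rule: the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' whose probability does not exceed that of the observed table.
#'
#' @param tab a 2x2 matrix of non-negative integer counts, rows = groups,
#'   columns = outcome; or a length-4 vector `c(a, b, c, d)` filled by row.
#' @return The two-sided p-value.
#' @examples
#' # pediatric vs adult onset, male vs female
#' fisher_exact_2x2(c(53, 91, 24, 88))
#' @export
fisher_exact_2x2 <- function(tab) {
  if (is.vector(tab) && length(tab) == 4)
    tab <- matrix(tab, nrow = 2, byrow = TRUE)
  if (!is.matrix(tab) || !all(dim(tab) == c(2, 2)))
    stop("need a 2x2 table or a length-4 count vector")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate margins: every row and column sum must be positive")
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Female-to-male ratio string
#'
#' @param n_female,n_male subject counts.
#' @return The ratio formatted as `"x:1"` with one decimal, or `"inf"` when
#'   there are no males.
#' @examples
#' ratio_summary(91, 53)  # "1.7:1"
#' ratio_summary(88, 24)  # "3.7:1"
#' @export
ratio_summary <- function(n_female, n_male) {
  stopifnot(n_female >= 0, n_male >= 0)
  if (n_male == 0) return("inf")
  sprintf("%.1f:1", n_female / n_male)
}

#' Cohort summary from a phenotype table
#'
#' Tabulates sex by onset group (pediatric: onset before 18 years) and runs
#' the exact test for a difference in female-to-male ratio between the two
#' onset groups.
#'
#' @param pheno `data.frame` with columns `subject`, `sex` (`"F"`/`"M"`) and
#'   `onset_age` (years).
#' @param pediatric_cutoff onset age below which a case is pediatric;
#'   default 18.
#' @return A list: `counts` (2x2 matrix onset x sex), `ratios` (named
#'   character vector of female-to-male ratio strings), `fisher_p`.
#' @export
cohort_summary <- function(pheno, pediatric_cutoff = 18) {
  stopifnot(all(c("sex", "onset_age") %in% names(pheno)))
  grp <- ifelse(pheno$onset_age < pediatric_cutoff, "pediatric", "adult")
  counts <- table(factor(grp, levels = c("pediatric", "adult")),
                  factor(pheno$sex, levels = c("M", "F")))
  ratios <- c(
    pediatric = ratio_summary(counts["pediatric", "F"],
                              counts["pediatric", "M"]),
    adult = ratio_summary(counts["adult", "F"], counts["adult", "M"]))
  list(counts = unclass(counts), ratios = ratios,
       fisher_p = fisher_exact_2x2(unclass(counts)))
}
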