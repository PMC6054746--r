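#' One-sided binomial burden test for a single gene or gene set
#'
#' Under the null hypothesis of no association, the number of qualifying
#' variants observed in cases follows a binomial distribution given the total
#' number of such variants in cases and controls combined, with success
#' probability equal to the fraction of cases among all subjects,
#' `n_case / (n_case + n_control)`. The p-value is the one-sided upper tail
#' `P(X >= x_case)` of that binomial; enrichment is reported as the ratio of
#' per-subject variant frequencies `(x_case/n_case) / (x_control/n_control)`,
#' infinite when controls carry no qualifying variant.
#'
#' The unit counted is a qualifying variant observation, not a distinct
#' carrier: a subject carrying two qualifying variants in one gene
#' contributes two.
#'
#' @param x_case,x_control non-negative integer vectors of qualifying-variant
#'   counts in cases and controls.
#' @param n_case,n_control cohort sizes (scalars).
#' @return A `data.frame` with columns `x_case`, `x_control`,
#'   `enrichment`, `p_value`.
#' @examples
#' # 5 case variants in 144 subjects vs 5 control variants in 7509
#' burden_test(5, 5, 144, 7509)
#' @export
burden_test <- function(x_case, x_control, n_case, n_control) {
  stopifnot(length(n_case) == 1, length(n_control) == 1,
            n_case > 0, n_control > 0)
  if (any(x_case < 0) || any(x_control < 0))
    stop("variant counts must be non-negative")
  if (any(x_case != round(x_case)) || any(x_control != round(x_control)))
    stop("variant counts must be integers")
  n <- max(length(x_case), length(x_control))
  x_case <- rep_len(x_case, n)
  x_control <- rep_len(x_control, n)

  p0 <- n_case / (n_case + n_control)
  total <- x_case + x_control
  # upper tail P(X >= x_case); x_case = 0 gives 1 by convention
  p <- stats::pbinom(x_case - 1, total, p0, lower.tail = FALSE)
  p[x_case == 0] <- 1
  enr <- (x_case / n_case) / (x_control / n_control)
  enr[x_case == 0 & x_control == 0] <- NaN
  data.frame(x_case = x_case, x_control = x_control,
             enrichment = enr, p_value = p)
}

#' Bonferroni genome-wide significance threshold
#'
#' @param n_tests number of genes tested (e.g. 17701 for an exome-wide scan).
#' @param alpha family-wise error rate; default 0.05.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(17701)  # 2.8e-6
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (length(n_tests) != 1 || n_tests < 1)
    stop("n_tests must be a single integer >= 1")
  stopifnot(alpha > 0, alpha < 1)
  alpha / n_tests
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH adjustment (via [stats::p.adjust()]), order-preserving with the
#' input vector.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Genome-wide burden scan
#'
#' Runs [burden_test()] on every gene of a per-gene count table and applies
#' Bonferroni and Benjamini-Hochberg correction across all tested genes.
#' Genes with zero qualifying variants in both cohorts get p = 1. Genes with
#' case variants but none in controls have infinite enrichment; they keep a
#' valid p-value and are flagged in the `no_control_variants` column.
#'
#' @param counts `data.frame` with columns `gene`, `x_case`, `x_control`.
#' @param n_case,n_control cohort sizes.
#' @param n_tests number of tests for the corrections; defaults to
#'   `nrow(counts)`. Set explicitly (e.g. 17701) when the table is a subset
#'   of the genes actually scanned.
#' @param alpha significance level used for the reported Bonferroni
#'   threshold attribute.
#' @return A `data.frame` sorted by `p_value` with columns `gene`, `x_case`,
#'   `x_control`, `enrichment`, `p_value`, `p_bonferroni`, `q_bh`,
#'   `no_control_variants`, plus attributes `n_tests` and
#'   `bonferroni_threshold`.
#' @export
burden_scan <- function(counts, n_case, n_control, n_tests = nrow(counts),
                        alpha = 0.05) {
  stopifnot(all(c("gene", "x_case", "x_control") %in% names(counts)))
  res <- burden_test(counts$x_case, counts$x_control, n_case, n_control)
  res <- cbind(gene = counts$gene, res)
  res$p_bonferroni <- pmin(res$p_value * n_tests, 1)
  res$q_bh <- bh_fdr(res$p_value)
  res$no_control_variants <- res$x_case > 0 & res$x_control == 0
  res <- res[order(res$p_value, -res$x_case), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_tests") <- n_tests
  attr(res, "bonferroni_threshold") <- bonferroni_threshold(n_tests, alpha)
  res
}

#' Pooled burden test over a gene set
#'
#' Sums qualifying-variant counts over the member genes of a set and applies
#' the binomial burden test to the pooled counts. Set members absent from
#' the count table contribute zero counts and are reported with a message.
#'
#' @param counts per-gene count table as in [burden_scan()].
#' @param genes character vector of member gene symbols (the gene set).
#' @param n_case,n_control cohort sizes.
#' @param set_name label for the result row.
#' @return A one-row `data.frame` with `unit`, `n_genes`, `x_case`,
#'   `x_control`, `enrichment`, `p_value`.
#' @export
gene_set_burden <- function(counts, genes, n_case, n_control,
                            set_name = "gene_set") {
  genes <- unique(genes)
  if (!length(genes)) stop("empty gene set")
  present <- genes %in% counts$gene
  if (!any(present))
    stop("no gene-set member is present in the count table")
  if (any(!present))
    message(sum(!present), " gene-set member(s) absent from the count table ",
            "contribute zero counts")
  sub <- counts[counts$gene %in% genes, , drop = FALSE]
  res <- burden_test(sum(sub$x_case), sum(sub$x_control), n_case, n_control)
  cbind(unit = set_name, n_genes = length(genes), res)
}

#' Synonymous-variant batch-effect calibration
#'
#' Cases and population controls are typically sequenced and processed on
#' different platforms. Rare synonymous variants are largely neutral with
#' respect to disease, so their exome-wide pooled burden should be identical
#' in cases and controls; a pooled enrichment away from 1 indicates a batch
#' effect rather than biology. This runs the pooled binomial burden test on
#' rare synonymous counts and flags enrichment outside a calibration band.
#'
#' @param x_case,x_control pooled (or per-gene, they are summed) rare
#'   synonymous counts.
#' @param n_case,n_control cohort sizes.
#' @param band numeric length-2: acceptable enrichment range,
#'   default `c(0.9, 1.1)`.
#' @return A list of class `rv_calibration`: `x_case`, `x_control`,
#'   `enrichment`, `p_value`, `band`, `flag` (TRUE when outside the band),
#'   `status` (`"ok"`, `"flagged"` or `"insufficient data"`).
#' @export
synonymous_calibration <- function(x_case, x_control, n_case, n_control,
                                   band = c(0.9, 1.1)) {
  stopifnot(length(band) == 2, band[1] < band[2])
  xc <- sum(x_case); xk <- sum(x_control)
  if (xc + xk == 0) {
    out <- list(x_case = 0L, x_control = 0L, enrichment = NaN, p_value = 1,
                band = band, flag = FALSE, status = "insufficient data")
    class(out) <- "rv_calibration"
    return(out)
  }
  bt <- burden_test(xc, xk, n_case, n_control)
  flag <- !is.finite(bt$enrichment) ||
    bt$enrichment < band[1] || bt$enrichment > band[2]
  out <- list(x_case = xc, x_control = xk, enrichment = bt$enrichment,
              p_value = bt$p_value, band = band, flag = flag,
              status = if (flag) "flagged" else "ok")
  class(out) <- "rv_calibration"
  out
}

#' @export
print.rv_calibration <- function(x, ...) {
  cat("Synonymous burden calibration\n")
  cat(sprintf("  pooled counts: %d case / %d control\n", x$x_case, x$x_control))
  cat(sprintf("  enrichment = %.3f, p = %.3g [band %.2f-%.2f] -> %s\n",
              x$enrichment, x$p_value, x$band[1], x$band[2], x$status))
  invisible(x)
}

#' Carrier frequency as a percentage
#'
#' @param n_carriers number of subjects carrying at least one qualifying
#'   variant.
#' @param n_subjects cohort size.
#' @return `100 * n_carriers / n_subjects`.
#' @examples
#' carrier_frequency(3, 413)   # 0.73% of PAH cases without CHD
#' carrier_frequency(5, 7509)  # 0.067% of population controls
#' @export
carrier_frequency <- function(n_carriers, n_subjects) {
  if (any(n_subjects == 0)) stop("n_subjects must be positive")
  if (any(n_carriers < 0 | n_carriers > n_subjects))
    stop("n_carriers must lie in [0, n_subjects]")
  100 * n_carriers / n_subjects
}

#' Attributable fraction of cases
#'
#' Fraction of cases attributable to qualifying variants in a gene,
#' estimated as the difference of per-subject carrier frequencies between
#' cases and controls (in percent). The estimator used is recorded in the
#' `method` attribute of the result.
#'
#' @param x_case,n_case,x_control,n_control counts and cohort sizes.
#' @return Percentage with attribute `method = "frequency_difference"`.
#' @export
attributable_fraction <- function(x_case, n_case, x_control, n_control) {
  stopifnot(n_case > 0, n_control > 0, x_case >= 0, x_control >= 0)
  out <- 100 * (x_case / n_case - x_control / n_control)
  attr(out, "method") <- "frequency_difference"
  out
}

#' Quantile-quantile data for a burden scan
#'
#' Sorted observed -log10 p-values paired with uniform order-statistic
#' expectations -log10(i / (n + 1)).
#'
#' @param p numeric vector of p-values (e.g. `scan$p_value`).
#' @return `data.frame` with columns `expected`, `observed` (both -log10
#'   scale, ascending in significance).
#' @export
qq_burden <- function(p) {
  if (!length(p)) stop("need at least one p-value")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p <- sort(p[!is.na(p)], decreasing = TRUE)
  n <- length(p)
  data.frame(expected = -log10(seq(n, 1) / (n + 1)),
             observed = -log10(p))
}
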