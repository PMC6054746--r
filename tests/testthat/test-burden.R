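test_that("binomial burden test matches pmf-summation on hand cases", {
  # 2 case / 1 control variants in 10 vs 90 subjects: P(X >= 2), X~B(3, 0.1)
  bt <- burden_test(2, 1, 10, 90)
  expect_equal(bt$p_value, sum(dbinom(2:3, 3, 0.1)))
  expect_equal(bt$p_value, 0.028)
  # upper tail from zero is 1 regardless of control count
  expect_equal(burden_test(0, 7, 144, 7509)$p_value, 1)
  expect_equal(burden_test(0, 0, 144, 7509)$p_value, 1)
  expect_error(burden_test(-1, 0, 10, 10), "non-negative")
  expect_error(burden_test(1.5, 0, 10, 10), "integers")
})

test_that("binomial tail equals the brute-force oracle on all small totals", {
  cohorts <- list(c(144, 7509), c(100, 900), c(500, 500))
  for (nn in cohorts) {
    p0 <- nn[1] / sum(nn)
    for (total in 0:50) {
      for (x in 0:total) {
        got <- burden_test(x, total - x, nn[1], nn[2])$p_value
        expect_equal(got, binom_tail_oracle(x, total, p0), tolerance = 1e-12)
      }
    }
  }
})

test_that("enrichment is the per-subject frequency ratio", {
  bt <- burden_test(5, 5, 144, 7509)
  expect_equal(bt$enrichment, (5 / 144) / (5 / 7509))
  # equal per-subject frequencies give enrichment 1
  expect_equal(burden_test(10, 100, 100, 1000)$enrichment, 1)
  expect_true(is.infinite(burden_test(3, 0, 144, 7509)$enrichment))
  # binomial proportion identity: odds of p0-scaled proportion equal the
  # frequency ratio: (x_case/total) / (x_control/total) scaled by cohorts
  prop <- 5 / 10
  odds_form <- (prop / (1 - prop)) * (7509 / 144)
  expect_equal(odds_form, bt$enrichment)
})

test_that("swapping cohort labels maps to the complementary tail", {
  x_case <- 7; x_control <- 12; n_case <- 100; n_control <- 900
  p_fwd <- burden_test(x_case, x_control, n_case, n_control)$p_value
  p_swp <- burden_test(x_control, x_case, n_control, n_case)$p_value
  total <- x_case + x_control
  p0 <- n_case / (n_case + n_control)
  # P(Y >= x_control) at swapped rate equals P(X <= x_case) at original
  expect_equal(p_swp, pbinom(x_case, total, p0))
  # and the two one-sided tails overlap at the observed outcome only
  expect_equal(p_fwd + p_swp - dbinom(x_case, total, p0), 1)
})

test_that("Bonferroni threshold and correction behave as defined", {
  expect_equal(bonferroni_threshold(17701), 0.05 / 17701)
  expect_equal(signif(bonferroni_threshold(17701), 2), 2.8e-6)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(10), 0.005)
  expect_error(bonferroni_threshold(0), "n_tests")
})

test_that("BH q-values equal an independent step-up reimplementation", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in sorted order
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("genome-wide scan corrects across genes and flags edge cases", {
  zero <- data.frame(gene = sprintf("G%02d", 1:5), x_case = 0, x_control = 0)
  sc0 <- burden_scan(zero, 144, 7509)
  expect_true(all(sc0$p_value == 1))
  expect_true(all(sc0$q_bh == 1))

  one <- data.frame(gene = "SOX17", x_case = 5, x_control = 5)
  sc1 <- burden_scan(one, 144, 7509, n_tests = 17701)
  expect_lt(sc1$p_bonferroni, 0.05)
  expect_equal(sc1$p_bonferroni, sc1$p_value * 17701)
  expect_equal(attr(sc1, "bonferroni_threshold"), 0.05 / 17701)

  inf <- data.frame(gene = c("A", "B"), x_case = c(3, 1),
                    x_control = c(0, 10))
  sci <- burden_scan(inf, 144, 7509)
  expect_equal(sci$no_control_variants, c(TRUE, FALSE))
  expect_true(all(sci$p_value >= 0 & sci$p_value <= 1))
})

test_that("a planted risk gene dominates a null scan", {
  spec <- cohort_spec(n_genes = 1000, planted_genes = c(RISK1 = 52),
                      seed = 101)
  sim <- generate_cohort(spec)
  sc <- burden_scan(sim$counts[, c("gene", "x_case", "x_control")],
                    spec$n_case, spec$n_control)
  expect_equal(sc$gene[1], "RISK1")
})

test_that("risk-gene recovery holds in the majority of cohorts, exactly", {
  # exact enumeration over the count distribution of a gene planted at the
  # observed risk-gene regime: control variants ~ Poisson(5), case variants
  # ~ Poisson(144 * 52 * 5 / 7509); the probability that a single cohort
  # clears the exome-wide threshold must exceed 1/2
  threshold <- bonferroni_threshold(17701, 0.05)
  lam_case <- 144 * 52 * 5 / 7509
  lam_ctrl <- 5
  p_pass <- 0
  for (xc in 1:60) {
    for (xk in 0:60) {
      p <- burden_test(xc, xk, 144, 7509)$p_value
      if (p < threshold)
        p_pass <- p_pass + dpois(xc, lam_case) * dpois(xk, lam_ctrl)
    }
  }
  expect_gt(p_pass, 0.5)
})

test_that("gene-set burden pools member counts", {
  counts <- data.frame(gene = c("A", "B", "C"),
                       x_case = c(2, 3, 0), x_control = c(10, 5, 0))
  single <- gene_set_burden(counts, "A", 144, 7509)
  expect_equal(single$p_value, burden_test(2, 10, 144, 7509)$p_value)
  expect_equal(single$enrichment, burden_test(2, 10, 144, 7509)$enrichment)

  # pooled counts constructed to a 5.7-fold case/control frequency ratio
  counts2 <- data.frame(gene = c("PAH1", "PAH2"),
                        x_case = c(20, 21), x_control = c(200, 175))
  gs <- gene_set_burden(counts2, c("PAH1", "PAH2"), 144, 7509, "PAH_set")
  expect_equal(gs$enrichment, (41 / 144) / (375 / 7509))
  expect_equal(round(gs$enrichment, 1), 5.7)

  expect_message(gene_set_burden(counts, c("A", "ZZZ"), 144, 7509),
                 "absent from the count table")
  zero <- gene_set_burden(counts, "C", 144, 7509)
  expect_equal(zero$p_value, 1)
  expect_error(gene_set_burden(counts, character(0), 144, 7509), "empty")
  expect_error(gene_set_burden(counts, "NOPE", 144, 7509), "no gene-set")
})

test_that("synonymous calibration stays in band without a batch effect", {
  n_case <- 144; n_control <- 7509
  n_in_band <- 0
  for (seed in 1:50) {
    set.seed(seed)
    # identical per-subject rates, pooled counts in the 5e4 regime
    rate <- 50000 / (n_case + n_control)
    xc <- rpois(1, n_case * rate)
    xk <- rpois(1, n_control * rate)
    cal <- synonymous_calibration(xc, xk, n_case, n_control)
    if (!cal$flag) n_in_band <- n_in_band + 1
  }
  expect_gte(n_in_band, 45)  # >= 95% of seeds expected in [0.9, 1.1]
})

test_that("synonymous calibration flags a shifted batch and starved input", {
  set.seed(7)
  n_case <- 144; n_control <- 7509
  rate <- 50000 / (n_case + n_control)
  # cases enriched 1.3-fold relative to controls: batch artifact
  xc <- rpois(1, n_case * rate * 1.3)
  xk <- rpois(1, n_control * rate)
  expect_true(synonymous_calibration(xc, xk, n_case, n_control)$flag)

  empty <- synonymous_calibration(0, 0, n_case, n_control)
  expect_equal(empty$status, "insufficient data")
  expect_false(empty$flag)
})

test_that("carrier frequencies and attributable fraction are percentages", {
  expect_equal(round(carrier_frequency(3, 413), 1), 0.7)
  expect_equal(round(carrier_frequency(5, 7509), 2), 0.07)
  expect_equal(round(carrier_frequency(16, 250), 1), 6.4)
  expect_error(carrier_frequency(1, 0), "positive")
  expect_error(carrier_frequency(5, 3), "n_subjects")

  af <- attributable_fraction(5, 144, 5, 7509)
  expect_equal(round(as.numeric(af), 2), 3.41)
  expect_equal(attr(af, "method"), "frequency_difference")
  expect_equal(as.numeric(attributable_fraction(0, 10, 0, 20)), 0)
  expect_equal(as.numeric(attributable_fraction(4, 100, 0, 500)),
               carrier_frequency(4, 100))
})

test_that("QQ data pairs sorted observations with uniform expectations", {
  single <- qq_burden(0.5)
  expect_equal(single$expected, -log10(0.5))
  expect_equal(single$observed, -log10(0.5))

  set.seed(3)
  p <- runif(5000)
  qq <- qq_burden(p)
  expect_equal(nrow(qq), 5000)
  expect_true(all(diff(qq$observed) >= 0))
  # uniform p-values hug the diagonal except at the extreme tail
  expect_lt(max(abs(qq$observed - qq$expected)[qq$expected < 2]), 0.35)

  # strong planted signal (~20 expected variants in each cohort) so the
  # tail deviation is unambiguous for any seed
  spec <- cohort_spec(n_genes = 2000, planted_genes = c(RISK1 = 52),
                      baseline_rate = 20 / 7509, seed = 5)
  sim <- generate_cohort(spec)
  sc <- burden_scan(sim$counts[, c("gene", "x_case", "x_control")],
                    spec$n_case, spec$n_control)
  qq2 <- qq_burden(sc$p_value)
  top <- qq2[nrow(qq2), ]
  expect_gt(top$observed - top$expected, 1)  # planted signal lifts the tail
})
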