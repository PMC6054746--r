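test_that("rate tables are validated structurally", {
  tab <- toy_rate_table(seed = 2)
  expect_s3_class(tab, "rv_rate_table")
  expect_equal(nrow(tab), 192)
  expect_identical(tab$rate, toy_rate_table(seed = 2)$rate)
  expect_false(identical(tab$rate, toy_rate_table(seed = 3)$rate))

  expect_error(trinuc_rate_table(tab[-1, 1:5]), "192")
  bad <- as.data.frame(tab)[, 1:5]
  bad$before[1] <- "N"
  expect_error(trinuc_rate_table(bad), "A/C/G/T")
  bad2 <- as.data.frame(tab)[, 1:5]
  bad2$rate[5] <- -1
  expect_error(trinuc_rate_table(bad2), "non-negative")

  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(as.data.frame(tab)[, 1:5], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_equal(read_rate_table(path)$rate, tab$rate)
})

test_that("CDS annotation classifies every substitution by codon change", {
  ann <- annotate_cds("ATGGCATAA")  # Met-Ala-Stop
  expect_equal(nrow(ann), 27)
  # position 4: GCA codon; G>A gives ACA (Thr) = missense
  expect_equal(ann$consequence[ann$pos == 4 & ann$alt == "A"], "missense")
  # position 6: GCA>GCC etc are synonymous (all code Ala)
  expect_equal(unique(ann$consequence[ann$pos == 6]), "synonymous")
  # stop codon position: losing the stop (TAA>TCA, Ser) is classed "other",
  # while a stop-retaining change (TAA>TGA) is synonymous
  expect_equal(ann$consequence[ann$pos == 8 & ann$alt == "C"], "other")
  expect_equal(ann$consequence[ann$pos == 8 & ann$alt == "G"], "synonymous")
  expect_error(annotate_cds("ATGX"), "A/C/G/T|multiple of 3")
  expect_error(annotate_cds("ATGA"), "multiple of 3")
})

test_that("expected counts follow the closed form for a uniform table", {
  grid <- expand.grid(before = c("A", "C", "G", "T"),
                      ref = c("A", "C", "G", "T"),
                      after = c("A", "C", "G", "T"),
                      alt = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  r <- 2e-8
  grid$rate <- r
  uni <- trinuc_rate_table(grid)
  seq <- paste(rep("ACGTGA", 20), collapse = "")  # 120 bases
  L_internal <- nchar(seq) - 2                    # edges lack context
  n_trios <- 60
  m0 <- suppressMessages(expected_denovo(uni, seq, n_trios, "all"))
  expect_equal(m0, 2 * n_trios * 3 * L_internal * r)
})

test_that("class expectations partition the total and add over blocks", {
  rates <- toy_rate_table(seed = 4, mean_rate = 1e-5)
  cds <- list(g1 = "ATGGCATGCTTAGACTAA", g2 = "ATGCCCGGGAAATTTTGA")
  m0 <- vapply(c("synonymous", "missense", "LGD", "other", "all"),
               function(k) suppressMessages(
                 expected_denovo(rates, cds, 60, k)), numeric(1))
  expect_equal(sum(m0[c("synonymous", "missense", "LGD", "other")]),
               m0[["all"]])
  # linear in n_trios
  expect_equal(suppressMessages(expected_denovo(rates, cds, 120, "all")),
               2 * m0[["all"]])
  # additive over disjoint sequence blocks
  m0_g1 <- suppressMessages(expected_denovo(rates, cds["g1"], 60, "all"))
  m0_g2 <- suppressMessages(expected_denovo(rates, cds["g2"], 60, "all"))
  expect_equal(m0_g1 + m0_g2, m0[["all"]])
})

test_that("a 9 bp toy CDS matches exhaustive hand enumeration", {
  rates <- toy_rate_table(seed = 9, mean_rate = 1e-4)
  seq <- "ATGGCATAA"
  n_trios <- 10
  # oracle: walk all 27 substitutions, translate mutated codons directly
  bases <- strsplit(seq, "")[[1]]
  code <- Biostrings::GENETIC_CODE
  lookup <- setNames(rates$rate, rates$context)
  translate3 <- function(s) {
    paste(code[substring(s, c(1, 4, 7), c(3, 6, 9))], collapse = "")
  }
  aa_ref <- translate3(seq)
  total <- list(all = 0, synonymous = 0, missense = 0, LGD = 0)
  for (pos in 2:8) {
    for (alt in setdiff(c("A", "C", "G", "T"), bases[pos])) {
      mut <- bases; mut[pos] <- alt
      aa_alt <- translate3(paste(mut, collapse = ""))
      d <- which(strsplit(aa_alt, "")[[1]] != strsplit(aa_ref, "")[[1]])
      cls <- if (!length(d)) "synonymous"
             else if (substring(aa_alt, d, d) == "*") "LGD"
             else if (substring(aa_ref, d, d) == "*") "other"
             else "missense"
      rate <- lookup[paste0(bases[pos - 1], bases[pos], bases[pos + 1], alt)]
      total$all <- total$all + rate
      if (cls %in% names(total)) total[[cls]] <- total[[cls]] + rate
    }
  }
  for (k in c("all", "synonymous", "missense", "LGD")) {
    expect_equal(suppressMessages(expected_denovo(rates, seq, n_trios, k)),
                 2 * n_trios * unname(total[[k]]), tolerance = 1e-12,
                 label = k)
  }
})

test_that("Poisson tail equals pmf summation on all small instances", {
  res <- poisson_enrichment(5, 1)
  expect_equal(res$p_value, 1 - sum(exp(-1) / factorial(0:4)))
  expect_equal(res$enrichment, 5)
  expect_equal(poisson_enrichment(0, 3)$p_value, 1)
  expect_error(poisson_enrichment(2, 0), "positive")
  expect_error(poisson_enrichment(-1, 2), "non-negative")

  for (m0 in c(0.25, 1, 5, 12, 20)) {
    for (m1 in 0:40) {
      expect_equal(poisson_enrichment(m1, m0)$p_value,
                   pois_tail_oracle(m1, m0), tolerance = 1e-12)
    }
  }
})

test_that("trio inheritance classification follows the trio genotypes", {
  res <- classify_inheritance(
    child  = c("het", "het", "het", "het", "hom_ref", "hom_alt", "hom_alt"),
    mother = c("hom_ref", "hom_ref", "missing", "het", "het", "hom_ref",
               "het"),
    father = c("hom_ref", "het", "hom_ref", "het", "hom_ref", "hom_ref",
               "hom_ref"))
  expect_equal(res$status,
               c("de_novo", "inherited", "unknown", "inherited",
                 "not_carried", "de_novo", "inherited"))
  expect_equal(res$origin[2], "paternal")
  expect_equal(res$origin[4], "both")
  expect_equal(res$origin[7], "maternal")
  # hom_alt child with a carrying mother but hom_ref father: inconsistent
  expect_true(res$mendelian_flag[7])
  expect_false(any(res$mendelian_flag[1:6]))
})

test_that("cohorts simulated from the rate model are not enriched", {
  rates <- toy_rate_table(seed = 6, mean_rate = 2e-4)
  cds <- list(g = paste(rep("ACGTCA", 100), collapse = ""))
  m0 <- suppressMessages(expected_denovo(rates, cds, 60, "all"))
  expect_gt(m0, 5)  # enough expected events for the z-check to be meaningful
  ok <- 0
  for (seed in 1:20) {
    trios <- generate_trios(60, rates, cds, seed = seed)
    m1 <- nrow(trios)
    if (abs(m1 - m0) <= 2 * sqrt(m0)) ok <- ok + 1
  }
  expect_gte(ok, 17)  # ~95% coverage of the 2-SE interval
  # and the per-seed test p-values are well away from significance on average
  p <- vapply(1:10, function(s)
    poisson_enrichment(nrow(generate_trios(60, rates, cds, seed = s)),
                       m0)$p_value, numeric(1))
  expect_gt(mean(p), 0.2)
})
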