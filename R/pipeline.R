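#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis in one validated
#' object. Defaults are the study-standard values: rarity cutoff
#' AF < 1e-4 (0.01%), D-mis cutoff REVEL > 0.5, family-wise alpha 0.05,
#' top-quartile cutoff 0.75.
#'
#' @param af_cutoff rarity allele-frequency cutoff.
#' @param revel_cutoff damaging-missense REVEL cutoff.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param quartile top-quartile expression cutoff.
#' @param n_tests override for the number of tests in multiple-testing
#'   correction; `NULL` uses the number of genes scanned.
#' @param seed integer seed governing every stochastic stage.
#' @param n_perm permutations for the expression-overlap stage.
#' @param stages named logical list toggling stages `qc`, `classify`,
#'   `burden`, `denovo`, `expression`, `report`.
#' @param cohort an [cohort_spec()] for the synthetic cohort (used when no
#'   external inputs are supplied).
#' @param calibration_band enrichment band for [synonymous_calibration()].
#' @return A list of class `rv_config`.
#' @export
pipeline_config <- function(af_cutoff = 1e-4, revel_cutoff = 0.5,
                            alpha = 0.05, quartile = 0.75, n_tests = NULL,
                            seed = 1L, n_perm = 10000,
                            stages = list(), cohort = NULL,
                            calibration_band = c(0.9, 1.1)) {
  stopifnot(af_cutoff > 0, af_cutoff < 1,
            revel_cutoff >= 0, revel_cutoff <= 1,
            alpha > 0, alpha < 1,
            quartile > 0, quartile < 1,
            is.null(n_tests) || n_tests >= 1,
            n_perm >= 1)
  def <- list(qc = FALSE, classify = TRUE, burden = TRUE, denovo = TRUE,
              expression = TRUE, report = TRUE)
  bad <- setdiff(names(stages), names(def))
  if (length(bad)) stop("unknown stage toggle(s): ",
                        paste(bad, collapse = ", "))
  def[names(stages)] <- stages
  if (is.null(cohort)) cohort <- cohort_spec(seed = seed)
  structure(list(af_cutoff = af_cutoff, revel_cutoff = revel_cutoff,
                 alpha = alpha, quartile = quartile, n_tests = n_tests,
                 seed = as.integer(seed), n_perm = n_perm, stages = def,
                 cohort = cohort, calibration_band = calibration_band),
            class = "rv_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipeline_config()] arguments; a `cohort` mapping
#' maps to [cohort_spec()] arguments (with `planted_genes` given as a
#' `gene: multiplier` mapping).
#'
#' @param path YAML file path.
#' @return An `rv_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cohort)) {
    ca <- y$cohort
    if (!is.null(ca$planted_genes))
      ca$planted_genes <- unlist(ca$planted_genes)
    y$cohort <- do.call(cohort_spec, ca)
  }
  do.call(pipeline_config, y)
}

#' Run the full burden-analysis pipeline on synthetic data
#'
#' Executes the stages in order: cohort generation, classification of case
#' variants, genome-wide burden scan with synonymous batch-effect
#' calibration and QQ data, trio de novo enrichment against a synthetic
#' trinucleotide rate model, and the expression-overlap permutation test for
#' a focal set of variant-carrying genes. Every threshold used is echoed
#' into the report. When `out_dir` is given, result tables are written as
#' TSV with a JSON metadata sidecar; re-running with an identical
#' configuration reproduces byte-identical outputs.
#'
#' @param config an [pipeline_config()] object.
#' @param out_dir optional output directory (created if needed).
#' @return A list of class `rv_report` with elements `top_genes`, `qq`,
#'   `calibration`, `denovo`, `expression`, `thresholds`, plus `paths` when
#'   written to disk. Stages toggled off are absent from the report.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "rv_config"))
  st <- config$stages
  report <- list()
  thresholds <- list(af_cutoff = config$af_cutoff,
                     revel_cutoff = config$revel_cutoff,
                     alpha = config$alpha, quartile = config$quartile,
                     seed = config$seed)

  cohort <- NULL
  if (st$classify || st$burden || st$expression)
    cohort <- generate_cohort(config$cohort)

  counts <- NULL
  if (st$classify) {
    counts <- case_burden_counts(cohort$case_variants, cohort$control_counts,
                                 af_cutoff = config$af_cutoff,
                                 revel_cutoff = config$revel_cutoff)
  }

  if (st$burden) {
    if (is.null(counts))
      counts <- data.frame(gene = cohort$counts$gene,
                           x_case = cohort$counts$x_case,
                           x_control = cohort$counts$x_control)
    n_tests <- if (is.null(config$n_tests)) nrow(counts) else config$n_tests
    scan <- burden_scan(counts, config$cohort$n_case, config$cohort$n_control,
                        n_tests = n_tests, alpha = config$alpha)
    report$top_genes <- utils::head(scan, 20)
    report$qq <- qq_burden(scan$p_value)
    report$calibration <- synonymous_calibration(
      cohort$counts$x_case_syn, cohort$counts$x_control_syn,
      config$cohort$n_case, config$cohort$n_control,
      band = config$calibration_band)
    thresholds$n_tests <- n_tests
    thresholds$bonferroni_threshold <- bonferroni_threshold(n_tests,
                                                            config$alpha)
  }

  if (st$denovo) {
    # a scaled-down exome: few short genes, with per-site rates raised so the
    # aggregate mutability matches roughly one coding de novo per trio
    cds <- .toy_cds(n_genes = 5, length_codons = 120, seed = config$seed)
    n_sub <- sum(vapply(cds, nchar, numeric(1)) - 2) * 3
    rates <- toy_rate_table(seed = config$seed, mean_rate = 1 / (2 * n_sub))
    trios <- generate_trios(60, rates, cds, seed = config$seed)
    report$denovo <- denovo_enrichment(trios, rates, cds, n_trios = 60)
  }

  if (st$expression) {
    if (is.null(counts))
      counts <- data.frame(gene = cohort$counts$gene,
                           x_case = cohort$counts$x_case)
    background <- counts$gene[counts$x_case > 0]
    n_focal <- min(149, length(background))
    if (n_focal >= 2) {
      old <- .Random.seed_save()
      set.seed(config$seed)
      focal <- sample(background, n_focal)
      .Random.seed_restore(old)
      expr <- generate_expression(
        n_genes = max(2000, length(background) + 500),
        signal_set = background,
        signal_strength = 0, seed = config$seed)
      ranks <- expression_ranks(expr$expr_a, expr$expr_b)
      report$expression <- overlap_permutation_test(
        focal, background, ranks, n_perm = config$n_perm,
        seed = config$seed, cutoff = config$quartile)
    }
  }

  report$thresholds <- thresholds
  class(report) <- "rv_report"
  if (!is.null(out_dir)) report$paths <- .write_report(report, out_dir)
  report
}

# small random in-frame coding sequences for the synthetic de novo stage
.toy_cds <- function(n_genes, length_codons, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)
  stats::setNames(lapply(seq_len(n_genes), function(i)
    paste(sample(c("A", "C", "G", "T"), 3 * length_codons, replace = TRUE),
          collapse = "")),
    sprintf("CDS%02d", seq_len(n_genes)))
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    .write_tsv(df, p)
    paths[[name]] <<- p
  }
  if (!is.null(report$top_genes)) tsv(report$top_genes, "top_genes.tsv")
  if (!is.null(report$qq)) tsv(report$qq, "qq.tsv")
  if (!is.null(report$denovo)) tsv(report$denovo, "denovo.tsv")
  if (!is.null(report$expression))
    tsv(overlap_null_histogram(report$expression), "expression_null.tsv")
  meta <- report$thresholds
  if (!is.null(report$calibration))
    meta$calibration <- report$calibration[c("x_case", "x_control",
                                             "enrichment", "p_value",
                                             "status")]
  if (!is.null(report$expression))
    meta$expression <- report$expression[c("observed", "n_focal", "n_perm",
                                           "empirical_p")]
  meta$package_version <- as.character(utils::packageVersion("rvburden"))
  p <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths[["run_metadata.json"]] <- p
  paths
}

#' @export
print.rv_report <- function(x, ...) {
  cat("rvburden pipeline report\n")
  if (!is.null(x$top_genes)) {
    cat("\nTop associated genes:\n")
    print(utils::head(x$top_genes, 5))
  }
  if (!is.null(x$calibration)) { cat("\n"); print(x$calibration) }
  if (!is.null(x$denovo)) {
    cat("\nDe novo enrichment by class:\n")
    print(x$denovo)
  }
  if (!is.null(x$expression)) { cat("\n"); print(x$expression) }
  invisible(x)
}
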