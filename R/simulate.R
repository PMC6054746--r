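#' Specification of a synthetic case-control cohort
#'
#' Captures the statistical structure the burden analysis assumes: per-gene
#' qualifying-variant counts are independent Poisson draws with a shared
#' baseline per-gene, per-subject rate, one or more planted risk genes carry
#' an elevated case rate, and synonymous variants provide a neutral variant
#' class whose control rate can be shifted to emulate a sequencing batch
#' effect.
#'
#' Defaults mirror the scale of a European-ancestry PAH-CHD exome study: 144
#' cases against 7509 population controls across 17701 genes, a baseline
#' rate of 5/7509 qualifying variants per gene per subject (about five
#' control variants per gene), one planted risk gene at a 52-fold case rate,
#' and a synonymous rate six times the deleterious baseline with no batch
#' shift.
#'
#' @param n_case,n_control cohort sizes.
#' @param n_genes number of genes in the universe.
#' @param baseline_rate per-gene per-subject qualifying-variant rate.
#' @param planted_genes named numeric vector: gene symbol -> case rate
#'   multiplier (use `numeric(0)` for a fully null cohort).
#' @param synonymous_rate per-gene per-subject rare synonymous rate.
#' @param batch_shift multiplier on the control synonymous rate (1 = no
#'   batch effect).
#' @param seed integer seed.
#' @return A list of class `rv_cohort_spec`.
#' @export
cohort_spec <- function(n_case = 144, n_control = 7509, n_genes = 17701,
                        baseline_rate = 5 / 7509,
                        planted_genes = c(RISK1 = 52),
                        synonymous_rate = 30 / 7509,
                        batch_shift = 1, seed = 1L) {
  stopifnot(n_case > 0, n_control > 0, n_genes >= 1,
            baseline_rate > 0, synonymous_rate > 0, batch_shift > 0)
  if (length(planted_genes)) {
    stopifnot(!is.null(names(planted_genes)), all(planted_genes >= 1))
    if (length(planted_genes) > n_genes)
      stop("more planted genes than genes")
  }
  structure(list(n_case = n_case, n_control = n_control, n_genes = n_genes,
                 baseline_rate = baseline_rate,
                 planted_genes = planted_genes,
                 synonymous_rate = synonymous_rate,
                 batch_shift = batch_shift, seed = as.integer(seed)),
            class = "rv_cohort_spec")
}

.deleterious_consequences <- c("stopgain", "frameshift_indel",
                               "canonical_splice", "missense")

#' Generate a synthetic case-control cohort
#'
#' Draws per-gene qualifying and synonymous variant counts
#' (`control ~ Poisson(n_control * rate)`,
#' `case ~ Poisson(n_case * rate * multiplier)`), and materializes the case
#' counts as an annotated variant table whose consequence/REVEL/allele
#' frequency fields reproduce the intended classification: qualifying
#' variants are absent from the reference panels and are either LGD or
#' missense with REVEL > 0.5; synonymous variants are rare synonymous.
#' Deterministic for a fixed spec (including its seed).
#'
#' @param spec an [cohort_spec()] object.
#' @return A list with `case_variants` (annotated variant `data.frame`:
#'   `gene`, `sample_id`, `consequence`, `revel`, `af_exac`,
#'   `af_gnomad_wes`), `control_counts` (`gene`, `x_control`,
#'   `x_control_syn`), `counts` (`gene`, `x_case`, `x_control`, plus
#'   synonymous columns) ready for [burden_scan()], and the `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "rv_cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  planted <- names(spec$planted_genes)
  genes <- c(planted,
             sprintf("G%05d", seq_len(spec$n_genes - length(planted))))
  mult <- rep(1, spec$n_genes)
  mult[seq_along(planted)] <- spec$planted_genes

  lam_case <- spec$n_case * spec$baseline_rate * mult
  lam_ctrl <- spec$n_control * spec$baseline_rate
  x_case <- stats::rpois(spec$n_genes, lam_case)
  x_control <- stats::rpois(spec$n_genes, lam_ctrl)
  x_case_syn <- stats::rpois(spec$n_genes, spec$n_case * spec$synonymous_rate)
  x_control_syn <- stats::rpois(
    spec$n_genes, spec$n_control * spec$synonymous_rate * spec$batch_shift)

  counts <- data.frame(gene = genes, x_case = x_case, x_control = x_control,
                       x_case_syn = x_case_syn,
                       x_control_syn = x_control_syn,
                       stringsAsFactors = FALSE)

  n_del <- sum(x_case)
  n_syn <- sum(x_case_syn)
  del_gene <- rep(genes, x_case)
  del_cons <- sample(.deleterious_consequences, n_del, replace = TRUE,
                     prob = c(0.25, 0.2, 0.05, 0.5))
  del_revel <- ifelse(del_cons == "missense",
                      stats::runif(n_del, 0.51, 1), NA_real_)
  syn_gene <- rep(genes, x_case_syn)
  case_variants <- data.frame(
    gene = c(del_gene, syn_gene),
    sample_id = sprintf("CASE%04d",
                        sample.int(spec$n_case, n_del + n_syn,
                                   replace = TRUE)),
    consequence = c(del_cons, rep("synonymous", n_syn)),
    revel = c(del_revel, rep(NA_real_, n_syn)),
    af_exac = NA_real_, af_gnomad_wes = NA_real_,
    stringsAsFactors = FALSE)

  list(case_variants = case_variants,
       control_counts = counts[, c("gene", "x_control", "x_control_syn")],
       counts = counts, spec = spec)
}

#' Per-gene qualifying counts from classified case variants
#'
#' Classifies a case variant table and aggregates counts of the requested
#' classes per gene over the control table's gene universe, producing the
#' count table consumed by [burden_scan()].
#'
#' @param case_variants annotated case variant `data.frame` (one row per
#'   variant observation).
#' @param control_counts `data.frame` with `gene` and `x_control` (and
#'   optionally `x_control_syn`).
#' @param classes qualifying classes; default `c("LGD", "D_mis")`.
#' @param af_cutoff,revel_cutoff thresholds for [classify_variants()].
#' @return `data.frame` with `gene`, `x_case`, `x_control`.
#' @export
case_burden_counts <- function(case_variants, control_counts,
                               classes = c("LGD", "D_mis"),
                               af_cutoff = 1e-4, revel_cutoff = 0.5) {
  cv <- classify_variants(case_variants, af_cutoff, revel_cutoff)
  keep <- cv$rare & cv$class %in% classes
  tab <- table(factor(cv$gene[keep], levels = control_counts$gene))
  data.frame(gene = control_counts$gene,
             x_case = as.integer(tab),
             x_control = control_counts$x_control,
             stringsAsFactors = FALSE)
}

#' Generate synthetic trio de novo calls
#'
#' Places de novo substitutions by sampling coding positions and alternate
#' alleles with probability proportional to the trinucleotide rate table
#' over the supplied coding sequences, two transmitted haploid genomes per
#' trio, so the expected total equals [expected_denovo()] with
#' `class = "all"`. Parents are homozygous reference at every event site
#' and the child heterozygous.
#'
#' @param n_trios number of trios.
#' @param rates an `rv_rate_table`.
#' @param cds named list of coding sequences.
#' @param seed integer seed.
#' @return `data.frame` of de novo events: `trio_id`, `gene`, `pos`, `ref`,
#'   `alt`, `consequence`, `child`, `mother`, `father`.
#' @export
generate_trios <- function(n_trios, rates, cds, seed = 1L) {
  stopifnot(n_trios > 0)
  frame <- .substitution_rate_frame(rates, cds)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lambda <- 2 * sum(frame$rate)
  events <- lapply(seq_len(n_trios), function(i) {
    k <- stats::rpois(1, lambda)
    if (k == 0) return(NULL)
    idx <- sample.int(nrow(frame), k, replace = TRUE, prob = frame$rate)
    cbind(trio_id = sprintf("TRIO%03d", i), frame[idx, , drop = FALSE])
  })
  events <- do.call(rbind, events)
  if (is.null(events))
    events <- cbind(trio_id = character(0),
                    frame[integer(0), , drop = FALSE])
  events$rate <- NULL
  events$child <- rep("het", nrow(events))
  events$mother <- rep("hom_ref", nrow(events))
  events$father <- rep("hom_ref", nrow(events))
  rownames(events) <- NULL
  events
}

#' Generate synthetic two-tissue expression tables
#'
#' Background genes receive independent expression quantiles in the two
#' tissues, so a background gene lands in the top quartile of both with
#' probability about 1/16. Each signal gene is, with probability
#' `signal_strength`, assigned concordantly high expression in both tissues
#' (guaranteed top-quartile); otherwise it behaves like background. The
#' expected double-top fraction among signal genes is therefore
#' `signal_strength + (1 - signal_strength) / 16`.
#'
#' @param n_genes total number of genes (background symbols are generated
#'   as `EXPR#####`).
#' @param signal_set character vector of signal gene symbols (prepended to
#'   the universe; counted inside `n_genes`).
#' @param signal_strength probability in \[0, 1\] that a signal gene is
#'   forced double-top.
#' @param seed integer seed.
#' @return A list with `expr_a` and `expr_b` (`gene`, `value`
#'   `data.frame`s).
#' @export
generate_expression <- function(n_genes, signal_set = character(0),
                                signal_strength = 0, seed = 1L) {
  stopifnot(n_genes >= length(signal_set),
            signal_strength >= 0, signal_strength <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_bg <- n_genes - length(signal_set)
  genes <- c(signal_set, sprintf("EXPR%05d", seq_len(n_bg)))
  u_a <- stats::runif(n_genes)
  u_b <- stats::runif(n_genes)
  if (length(signal_set)) {
    hot <- seq_along(signal_set)[
      stats::runif(length(signal_set)) < signal_strength]
    # well inside the top quartile in both tissues even after re-ranking
    u_a[hot] <- stats::runif(length(hot), 0.9, 1)
    u_b[hot] <- stats::runif(length(hot), 0.9, 1)
  }
  list(expr_a = data.frame(gene = genes, value = exp(6 * u_a)),
       expr_b = data.frame(gene = genes, value = exp(6 * u_b)))
}
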