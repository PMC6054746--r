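#' Per-tissue expression quantile ranks
#'
#' Converts raw expression values in two tissues into per-tissue quantile
#' ranks in (0, 1], computed independently per tissue with average-rank tie
#' handling (`rank(x) / n`). Quantiles are therefore invariant to any
#' monotone transformation of the expression values.
#'
#' @param expr_a,expr_b `data.frame`s with columns `gene` and `value`
#'   (expression level in tissue A and tissue B respectively). Genes present
#'   in only one tissue are dropped.
#' @return `data.frame` with columns `gene`, `quantile_a`, `quantile_b`.
#' @export
expression_ranks <- function(expr_a, expr_b) {
  for (e in list(expr_a, expr_b))
    stopifnot(all(c("gene", "value") %in% names(e)))
  if (anyDuplicated(expr_a$gene) || anyDuplicated(expr_b$gene))
    stop("duplicate gene symbols in an expression table")
  common <- intersect(expr_a$gene, expr_b$gene)
  if (!length(common)) stop("no genes shared between the two tables")
  a <- expr_a[match(common, expr_a$gene), ]
  b <- expr_b[match(common, expr_b$gene), ]
  data.frame(gene = common,
             quantile_a = rank(a$value, ties.method = "average") / nrow(a),
             quantile_b = rank(b$value, ties.method = "average") / nrow(b))
}

#' Count focal genes in the top expression quartile of both tissues
#'
#' @param focal character vector of focal gene symbols. Focal genes absent
#'   from the rank table are dropped with a message.
#' @param ranks output of [expression_ranks()].
#' @param cutoff quantile defining "top quartile"; default 0.75, applied as
#'   `quantile >= cutoff` in both tissues.
#' @return Integer count.
#' @export
top_quartile_overlap <- function(focal, ranks, cutoff = 0.75) {
  focal <- unique(focal)
  present <- focal %in% ranks$gene
  if (!any(present))
    stop("no focal gene is present in the expression rank table")
  if (any(!present))
    message(sum(!present), " focal gene(s) absent from the expression table ",
            "dropped")
  sub <- ranks[match(focal[present], ranks$gene), ]
  sum(sub$quantile_a >= cutoff & sub$quantile_b >= cutoff)
}

#' Permutation test for top-quartile expression overlap
#'
#' Tests whether a focal gene set (e.g. putative transcription-factor
#' targets carrying qualifying variants) contains more genes with
#' top-quartile expression in both tissues than expected among comparable
#' genes. The null distribution is built by repeatedly drawing
#' `length(focal)` genes without replacement from a background set (genes
#' carrying at least one qualifying variant) and counting double-top genes.
#' The empirical p-value uses the standard pseudocount rule
#' `(1 + #(null >= observed)) / (1 + n_perm)`, so it is never exactly zero.
#'
#' @param focal,background character vectors of gene symbols; the focal
#'   genes must be a subset of the rank table's universe, and the background
#'   must be at least as large as the focal set (after dropping genes absent
#'   from the rank table).
#' @param ranks output of [expression_ranks()].
#' @param n_perm number of permutations (the study-scale default is 1e5).
#' @param seed optional integer seed for reproducibility.
#' @param cutoff top-quartile cutoff, default 0.75.
#' @return A list of class `rv_overlap`: `observed`, `n_focal`, `n_perm`,
#'   `null_mean`, `null_sd`, `null_counts` (integer vector of permuted
#'   counts), `empirical_p`.
#' @export
overlap_permutation_test <- function(focal, background, ranks,
                                     n_perm = 1e5, seed = NULL,
                                     cutoff = 0.75) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  observed <- top_quartile_overlap(focal, ranks, cutoff)
  n_focal <- sum(unique(focal) %in% ranks$gene)

  background <- unique(background)
  bg_present <- background[background %in% ranks$gene]
  if (length(bg_present) < n_focal)
    stop("background smaller than the focal set after intersection with ",
         "the expression table")
  sub <- ranks[match(bg_present, ranks$gene), ]
  double_top <- sub$quantile_a >= cutoff & sub$quantile_b >= cutoff

  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  nbg <- length(double_top)
  null_counts <- vapply(seq_len(n_perm), function(i)
    sum(double_top[sample.int(nbg, n_focal)]), integer(1))
  out <- list(observed = observed, n_focal = n_focal, n_perm = n_perm,
              null_mean = mean(null_counts), null_sd = stats::sd(null_counts),
              null_counts = null_counts,
              empirical_p = (1 + sum(null_counts >= observed)) / (1 + n_perm))
  class(out) <- "rv_overlap"
  out
}

#' @export
print.rv_overlap <- function(x, ...) {
  cat("Top-quartile expression overlap permutation test\n")
  cat(sprintf("  observed %d / %d double-top genes\n", x$observed, x$n_focal))
  cat(sprintf("  null mean %.2f (sd %.2f) over %d permutations\n",
              x$null_mean, x$null_sd, x$n_perm))
  cat(sprintf("  empirical p = %.3g\n", x$empirical_p))
  invisible(x)
}

#' Null-distribution histogram of an overlap permutation test
#'
#' @param result an `rv_overlap` object.
#' @return `data.frame` with columns `count`, `n_permutations`.
#' @export
overlap_null_histogram <- function(result) {
  stopifnot(inherits(result, "rv_overlap"))
  tab <- table(result$null_counts)
  data.frame(count = as.integer(names(tab)),
             n_permutations = as.integer(tab))
}
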