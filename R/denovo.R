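.dna <- c("A", "C", "G", "T")

#' Validate a trinucleotide mutation-rate table
#'
#' The background de novo model is parameterized by a table of per-site,
#' per-generation substitution probabilities indexed by the trinucleotide
#' context (5' flank, reference base, 3' flank) and the alternate base: 64
#' contexts x 3 alternates = 192 rates.
#'
#' @param rates `data.frame` with columns `before`, `ref`, `after`, `alt`
#'   (single bases) and `rate` (non-negative numeric).
#' @return The validated table, with a `context` key column added, class
#'   `rv_rate_table`.
#' @export
trinuc_rate_table <- function(rates) {
  req <- c("before", "ref", "after", "alt", "rate")
  stopifnot(all(req %in% names(rates)))
  for (col in c("before", "ref", "after", "alt"))
    if (!all(rates[[col]] %in% .dna))
      stop("column '", col, "' must contain only A/C/G/T")
  if (any(rates$rate < 0)) stop("rates must be non-negative")
  if (any(rates$ref == rates$alt)) stop("alt must differ from ref")
  key <- paste(rates$before, rates$ref, rates$after, rates$alt, sep = "")
  if (anyDuplicated(key)) stop("duplicate (context, alt) entries")
  if (nrow(rates) != 192)
    stop("expected 192 entries (64 contexts x 3 alternates), got ",
         nrow(rates))
  rates$context <- key
  class(rates) <- c("rv_rate_table", "data.frame")
  rates
}

#' Read a trinucleotide rate table from TSV
#'
#' @param path TSV with header columns `before`, `ref`, `after`, `alt`,
#'   `rate`.
#' @return An `rv_rate_table`.
#' @export
read_rate_table <- function(path) {
  trinuc_rate_table(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}

#' Synthetic trinucleotide rate table
#'
#' Generates a complete 192-entry rate table for tests and simulations. The
#' values are synthetic: log-normal per-context rates on the order of 1e-8
#' per site per generation, with CpG transitions (`C>T` in a CpG context and
#' the complementary `G>A`) boosted about tenfold, mimicking the broad shape
#' of empirical germline mutation-rate tables without reproducing any
#' published constants.
#'
#' @param seed integer seed; the table is deterministic given the seed.
#' @param mean_rate approximate mean per-site per-alternate rate.
#' @return An `rv_rate_table`.
#' @export
toy_rate_table <- function(seed = 1L, mean_rate = 1e-8) {
  grid <- expand.grid(before = .dna, ref = .dna, after = .dna, alt = .dna,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, , drop = FALSE]
  rownames(grid) <- NULL
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  r <- stats::rlnorm(nrow(grid), meanlog = log(mean_rate), sdlog = 0.5)
  cpg <- (grid$ref == "C" & grid$alt == "T" & grid$after == "G") |
         (grid$ref == "G" & grid$alt == "A" & grid$before == "C")
  r[cpg] <- r[cpg] * 10
  grid$rate <- r
  trinuc_rate_table(grid)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Annotate every possible substitution in a coding sequence
#'
#' For an in-frame coding sequence, determines the consequence of each of
#' the three possible substitutions at every position by translating the
#' altered codon: synonymous, missense, stopgain (classed LGD) or stop-loss
#' (classed other). This is the per-position annotation needed to accumulate
#' class-specific expected de novo counts.
#'
#' @param seq a single in-frame coding sequence (character string over
#'   A/C/G/T, length a multiple of 3).
#' @return `data.frame` with one row per (position, alt): `pos`, `ref`,
#'   `alt`, `consequence`.
#' @export
annotate_cds <- function(seq) {
  bases <- strsplit(toupper(seq), "")[[1]]
  if (!all(bases %in% .dna)) stop("sequence must be over A/C/G/T")
  L <- length(bases)
  if (L %% 3 != 0) stop("coding sequence length must be a multiple of 3")
  code <- Biostrings::GENETIC_CODE
  codons <- substring(paste(bases, collapse = ""),
                      seq(1, L, 3), seq(3, L, 3))
  aa <- unname(code[codons])

  pos <- rep(seq_len(L), each = 3)
  ref <- bases[pos]
  alt <- unlist(lapply(bases, function(b) setdiff(.dna, b)), use.names = FALSE)
  ci <- (pos - 1) %/% 3 + 1      # codon index
  off <- (pos - 1) %% 3 + 1      # position within codon
  alt_codon <- codons[ci]
  substr(alt_codon, off, off) <- alt
  aa_ref <- aa[ci]
  aa_alt <- unname(code[alt_codon])
  consequence <- ifelse(aa_alt == aa_ref, "synonymous",
                 ifelse(aa_alt == "*" & aa_ref != "*", "stopgain",
                 ifelse(aa_ref == "*", "other", "missense")))
  data.frame(pos = pos, ref = ref, alt = alt, consequence = consequence,
             stringsAsFactors = FALSE)
}

# map a substitution consequence to the class used for de novo expectations
.denovo_class <- function(consequence) {
  ifelse(consequence %in% .lgd_consequences, "LGD",
  ifelse(consequence == "missense", "missense",
  ifelse(consequence == "synonymous", "synonymous", "other")))
}

#' Expected de novo count for a variant class
#'
#' Accumulates the background mutation rate over every uniquely mappable
#' coding position and alternate allele whose consequence falls in the
#' requested class, doubled for the two transmitted haploid genomes per trio
#' and scaled by the number of trios:
#' `m0 = 2 * n_trios * sum(rate(context, alt))`. Positions at a sequence
#' edge, where the trinucleotide context is undefined, are skipped and their
#' number reported via a message.
#'
#' @param rates an `rv_rate_table`.
#' @param cds named list (or single string) of coding sequences restricted
#'   to uniquely mappable positions; each annotated internally with
#'   [annotate_cds()].
#' @param n_trios number of trios.
#' @param class one of `"all"`, `"LGD"`, `"missense"`, `"synonymous"`,
#'   `"other"`.
#' @return Expected count `m0` (numeric scalar).
#' @export
expected_denovo <- function(rates, cds, n_trios,
                            class = c("all", "LGD", "missense",
                                      "synonymous", "other")) {
  class <- match.arg(class)
  stopifnot(inherits(rates, "rv_rate_table"), n_trios > 0)
  if (is.character(cds) && is.null(names(cds)) && length(cds) == 1)
    cds <- list(gene = cds)
  rate_lookup <- stats::setNames(rates$rate, rates$context)

  total <- 0
  skipped <- 0L
  for (s in cds) {
    ann <- annotate_cds(s)
    bases <- strsplit(toupper(s), "")[[1]]
    L <- length(bases)
    edge <- ann$pos == 1L | ann$pos == L
    skipped <- skipped + sum(edge)  # 3 alt rows per edge position
    ann <- ann[!edge, , drop = FALSE]
    if (class != "all")
      ann <- ann[.denovo_class(ann$consequence) == class, , drop = FALSE]
    if (!nrow(ann)) next
    ctx <- paste0(bases[ann$pos - 1L], ann$ref, bases[ann$pos + 1L], ann$alt)
    r <- rate_lookup[ctx]
    if (anyNA(r)) stop("rate table is missing context(s): ",
                       paste(unique(ctx[is.na(r)]), collapse = ", "))
    total <- total + sum(r)
  }
  if (skipped > 0)
    message(skipped / 3, " edge position(s) without trinucleotide context ",
            "skipped")
  2 * n_trios * total
}

# one row per (gene, internal position, alt) with its context-specific rate
.substitution_rate_frame <- function(rates, cds) {
  stopifnot(inherits(rates, "rv_rate_table"))
  if (is.character(cds) && is.null(names(cds)) && length(cds) == 1)
    cds <- list(gene = cds)
  rate_lookup <- stats::setNames(rates$rate, rates$context)
  out <- lapply(names(cds), function(g) {
    ann <- annotate_cds(cds[[g]])
    bases <- strsplit(toupper(cds[[g]]), "")[[1]]
    ann <- ann[ann$pos > 1L & ann$pos < length(bases), , drop = FALSE]
    if (!nrow(ann)) return(NULL)
    ctx <- paste0(bases[ann$pos - 1L], ann$ref, bases[ann$pos + 1L], ann$alt)
    cbind(gene = g, ann, rate = unname(rate_lookup[ctx]))
  })
  do.call(rbind, out)
}

#' Exact Poisson enrichment test for de novo counts
#'
#' Tests whether the observed de novo count `m1` exceeds the expectation
#' `m0` from the background mutation-rate model: enrichment `m1/m0` and
#' one-sided upper-tail p-value `P(X >= m1)` for `X ~ Poisson(m0)`.
#'
#' @param m1 observed count (non-negative integer).
#' @param m0 expected count (positive).
#' @param variant_class optional label carried into the result.
#' @return One-row `data.frame`: `variant_class`, `m1`, `m0`, `enrichment`,
#'   `p_value`.
#' @examples
#' poisson_enrichment(5, 1)
#' @export
poisson_enrichment <- function(m1, m0, variant_class = "all") {
  if (any(m0 <= 0)) stop("m0 must be positive")
  if (any(m1 < 0) || any(m1 != round(m1)))
    stop("m1 must be a non-negative integer")
  n <- max(length(m1), length(m0), length(variant_class))
  m1 <- rep_len(m1, n); m0 <- rep_len(m0, n)
  variant_class <- rep_len(variant_class, n)
  p <- stats::ppois(m1 - 1, m0, lower.tail = FALSE)
  p[m1 == 0] <- 1
  data.frame(variant_class = variant_class, m1 = m1, m0 = m0,
             enrichment = m1 / m0, p_value = p)
}

#' Per-class de novo enrichment table
#'
#' Convenience wrapper: computes class-specific expectations with
#' [expected_denovo()] and tests each class (and the union) against the
#' observed de novo calls.
#'
#' @param observed `data.frame` of observed de novo variants with a
#'   `consequence` column.
#' @param rates,cds,n_trios as in [expected_denovo()].
#' @return `data.frame` with one row per class among `synonymous`,
#'   `missense`, `LGD`, `all`.
#' @export
denovo_enrichment <- function(observed, rates, cds, n_trios) {
  cls <- .denovo_class(observed$consequence)
  rows <- lapply(c("synonymous", "missense", "LGD", "all"), function(k) {
    m1 <- if (k == "all") nrow(observed) else sum(cls == k)
    m0 <- suppressMessages(expected_denovo(rates, cds, n_trios, k))
    poisson_enrichment(m1, m0, k)
  })
  do.call(rbind, rows)
}

#' Classify inheritance of a child's variant from trio genotypes
#'
#' A variant is de novo when the child carries the alternate allele and both
#' parents are homozygous reference; it is inherited when a parent carries
#' it (maternal/paternal/biparental); when one parent's genotype is missing
#' and the other does not carry it, the origin cannot be resolved
#' ("unknown", e.g. paternal-or-de-novo). A child homozygous for the
#' alternate allele with a non-carrying genotyped parent is flagged as a
#' Mendelian inconsistency.
#'
#' @param child,mother,father character vectors of genotypes (`"hom_ref"`,
#'   `"het"`, `"hom_alt"`, `"missing"`).
#' @return `data.frame` with columns `status` (`de_novo`, `inherited`,
#'   `unknown`, `not_carried`) , `origin` (`maternal`, `paternal`, `both`,
#'   or `NA`) and `mendelian_flag`.
#' @export
classify_inheritance <- function(child, mother, father) {
  n <- max(length(child), length(mother), length(father))
  child <- rep_len(as.character(child), n)
  mother <- rep_len(as.character(mother), n)
  father <- rep_len(as.character(father), n)
  carries <- function(g) g %in% c("het", "hom_alt")

  status <- rep("unknown", n)
  origin <- rep(NA_character_, n)
  status[!carries(child)] <- "not_carried"

  mc <- carries(mother); fc <- carries(father)
  inh <- carries(child) & (mc | fc)
  status[inh] <- "inherited"
  origin[inh & mc & !fc] <- "maternal"
  origin[inh & fc & !mc] <- "paternal"
  origin[inh & mc & fc] <- "both"

  dn <- carries(child) & mother == "hom_ref" & father == "hom_ref"
  status[dn] <- "de_novo"
  # carrying child, no carrying parent, at least one parent unresolved
  status[carries(child) & !inh & !dn] <- "unknown"

  # hom_alt child needs an allele from each parent; a single non-carrying
  # genotyped parent (while the other carries) leaves one allele unexplained.
  # Both parents hom_ref is the (double) de novo pattern and is not flagged.
  mendel <- child == "hom_alt" &
    ((mother == "hom_ref" & fc) | (father == "hom_ref" & mc))
  data.frame(status = status, origin = origin, mendelian_flag = mendel,
             stringsAsFactors = FALSE)
}
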