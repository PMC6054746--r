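#' Heuristic genotype-level QC filter
#'
#' Flags individual genotype calls that look like technical artifacts:
#' minimum read depth <= 8 reads, allele balance <= 20% (heterozygous calls
#' only), or genotype quality < 30. The allele-balance filter targets
#' suspicious heterozygous calls, so homozygous-alternate calls are exempt
#' from it and reference/missing genotypes are not filtered at all.
#'
#' @param depth numeric vector of read depths (reads covering the site).
#' @param allele_balance numeric vector in \[0, 1\]: alternate-supporting
#'   reads over total reads. May be `NA` for genotypes where it is undefined
#'   (hom_ref, hom_alt, missing).
#' @param genotype_quality numeric vector, phred-like genotype quality.
#' @param genotype character vector with values `"hom_ref"`, `"het"`,
#'   `"hom_alt"` or `"missing"`.
#'
#' @return Character vector the same length as the inputs: `NA` where the
#'   call passes, otherwise the first failing criterion among `"depth"`,
#'   `"allele_balance"`, `"genotype_quality"` (in the order the filters are
#'   defined).
#' @examples
#' filter_genotype(depth = c(8, 30, 30, 9),
#'                 allele_balance = c(0.45, 0.20, 0.45, 0.21),
#'                 genotype_quality = c(60, 60, 30, 99),
#'                 genotype = "het")
#' @export
filter_genotype <- function(depth, allele_balance, genotype_quality,
                            genotype = "het") {
  n <- max(length(depth), length(allele_balance),
           length(genotype_quality), length(genotype))
  depth <- rep_len(depth, n)
  allele_balance <- rep_len(allele_balance, n)
  genotype_quality <- rep_len(genotype_quality, n)
  genotype <- rep_len(as.character(genotype), n)

  bad_gt <- !genotype %in% c("hom_ref", "het", "hom_alt", "missing")
  if (any(bad_gt))
    stop("unknown genotype value(s): ",
         paste(unique(genotype[bad_gt]), collapse = ", "))

  called <- genotype != "missing"
  for (fld in c("depth", "genotype_quality")) {
    if (any(called & is.na(get(fld))))
      stop("missing QC field '", fld, "' on a non-missing genotype")
  }
  if (any(genotype == "het" & is.na(allele_balance)))
    stop("missing QC field 'allele_balance' on a het genotype")

  reason <- rep(NA_character_, n)
  ab_applies <- genotype == "het"
  reason[called & !is.na(genotype_quality) & genotype_quality < 30] <-
    "genotype_quality"
  reason[ab_applies & !is.na(allele_balance) & allele_balance <= 0.20] <-
    "allele_balance"
  reason[called & depth <= 8] <- "depth"
  reason
}

#' Normalize capture intervals
#'
#' Builds the capture-region object used to restrict variants to the
#' sequenced protein-coding target. Input intervals are half-open, 0-based
#' (BED convention); overlapping or adjacent intervals are merged so the
#' stored set is non-overlapping.
#'
#' @param regions a `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open), or a `GRanges` object (taken as 1-based inclusive).
#' @return A reduced `GRanges` of capture intervals (1-based inclusive).
#' @examples
#' capture_regions(data.frame(chrom = "1", start = c(0, 50), end = c(60, 100)))
#' @export
capture_regions <- function(regions) {
  if (inherits(regions, "GRanges")) return(GenomicRanges::reduce(regions))
  stopifnot(is.data.frame(regions),
            all(c("chrom", "start", "end") %in% names(regions)))
  if (any(regions$end <= regions$start))
    stop("malformed interval: end must exceed start (half-open, 0-based)")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(regions$chrom),
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end))
  GenomicRanges::reduce(gr)
}

#' Read a BED file of capture intervals
#'
#' @param path path to a BED file (first three columns used; 0-based
#'   half-open coordinates).
#' @return A `GRanges` of normalized capture intervals.
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  capture_regions(data.frame(chrom = as.character(bed[[1]]),
                             start = as.integer(bed[[2]]),
                             end = as.integer(bed[[3]])))
}

#' Heuristic site-level QC filter
#'
#' Flags whole variant sites: call-rate missingness > 10%, mappability < 1
#' (150 bp fragments), VQSR tranche sensitivity < 99.6, a FILTER status other
#' than "PASS", or a position outside the capture regions. The variant's
#' 1-based start position is tested against the capture intervals.
#'
#' @param sites a `data.frame` with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `missingness`, `mappability`, `vqsr_tranche`, `filter_status`.
#' @param regions capture intervals from [capture_regions()] or [read_bed()],
#'   or `NULL` to skip the region restriction.
#' @return Character vector, one element per site: `NA` for a pass, otherwise
#'   the first failing criterion among `"missingness"`, `"mappability"`,
#'   `"vqsr"`, `"filter_status"`, `"off_target"`.
#' @export
filter_site <- function(sites, regions = NULL) {
  req <- c("chrom", "pos", "missingness", "mappability", "vqsr_tranche",
           "filter_status")
  miss <- setdiff(req, names(sites))
  if (length(miss)) stop("sites is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(sites$missingness < 0 | sites$missingness > 1, na.rm = TRUE))
    stop("missingness must lie in [0, 1]")
  if (any(sites$mappability < 0 | sites$mappability > 1, na.rm = TRUE))
    stop("mappability must lie in [0, 1]")

  reason <- rep(NA_character_, nrow(sites))
  if (!is.null(regions)) {
    gr <- GenomicRanges::GRanges(
      seqnames = as.character(sites$chrom),
      ranges = IRanges::IRanges(start = sites$pos, width = 1L))
    hit <- GenomicRanges::countOverlaps(gr, regions) > 0
    reason[!hit] <- "off_target"
  }
  reason[sites$filter_status != "PASS"] <- "filter_status"
  reason[sites$vqsr_tranche < 99.6] <- "vqsr"
  reason[sites$mappability < 1] <- "mappability"
  reason[sites$missingness > 0.10] <- "missingness"
  reason
}

#' Apply site and genotype QC to a variant table
#'
#' Runs [filter_site()] on every site and [filter_genotype()] on every
#' genotype call of the retained sites, and tallies exclusions per criterion.
#' A site that passes all site-level filters is retained even if every one of
#' its carrier calls fails genotype QC (it then simply contributes no
#' carriers).
#'
#' @param sites site `data.frame` (see [filter_site()]); must carry a unique
#'   `variant_id` column linking it to `calls`.
#' @param calls genotype call `data.frame` with columns `variant_id`,
#'   `sample_id`, `genotype`, `depth`, `allele_balance`, `genotype_quality`.
#'   May be `NULL` when only site-level data are available.
#' @param regions capture intervals, or `NULL`.
#' @return A list of class `rv_qc` with elements `sites` (retained sites),
#'   `calls` (retained calls at retained sites), `site_exclusions` and
#'   `genotype_exclusions` (named integer tallies per criterion).
#' @export
apply_qc <- function(sites, calls = NULL, regions = NULL) {
  if (nrow(sites) && anyDuplicated(sites$variant_id))
    stop("sites$variant_id must be unique (decompose multi-allelic records)")
  site_reason <- if (nrow(sites)) filter_site(sites, regions) else character(0)
  keep <- is.na(site_reason)
  site_tally <- table(site_reason[!keep])

  kept_sites <- sites[keep, , drop = FALSE]
  kept_calls <- NULL
  gt_tally <- table(character(0))
  if (!is.null(calls)) {
    kept_calls <- calls[calls$variant_id %in% kept_sites$variant_id, ,
                        drop = FALSE]
    if (nrow(kept_calls)) {
      gt_reason <- filter_genotype(kept_calls$depth,
                                   kept_calls$allele_balance,
                                   kept_calls$genotype_quality,
                                   kept_calls$genotype)
      gt_tally <- table(gt_reason[!is.na(gt_reason)])
      kept_calls <- kept_calls[is.na(gt_reason), , drop = FALSE]
    }
  }
  structure(list(sites = kept_sites,
                 calls = kept_calls,
                 site_exclusions = c(site_tally),
                 genotype_exclusions = c(gt_tally)),
            class = "rv_qc")
}

#' @export
print.rv_qc <- function(x, ...) {
  cat("Variant QC result\n")
  cat("  sites retained:", nrow(x$sites), "\n")
  if (length(x$site_exclusions))
    cat("  site exclusions:",
        paste(names(x$site_exclusions), x$site_exclusions,
              sep = "=", collapse = ", "), "\n")
  if (!is.null(x$calls)) cat("  calls retained:", nrow(x$calls), "\n")
  if (length(x$genotype_exclusions))
    cat("  genotype exclusions:",
        paste(names(x$genotype_exclusions), x$genotype_exclusions,
              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write the QC exclusion-tally report
#'
#' @param qc an `rv_qc` object from [apply_qc()].
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  part <- function(level, tally) {
    data.frame(level = rep_len(level, length(tally)),
               reason = if (length(tally)) names(tally) else character(0),
               excluded = as.integer(tally))
  }
  tab <- rbind(part("site", qc$site_exclusions),
               part("genotype", qc$genotype_exclusions))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# tranche sensitivity from a FILTER string; "PASS" counts as fully sensitive
.vqsr_from_filter <- function(filter_status) {
  out <- rep(NA_real_, length(filter_status))
  out[filter_status == "PASS"] <- 100
  m <- regmatches(filter_status,
                  regexpr("Tranche[A-Z]*([0-9.]+)to", filter_status))
  has <- nchar(m) > 0
  out[has] <- as.numeric(sub("to$", "", sub("^Tranche[A-Z]*", "", m[has])))
  out
}

#' Read a VCF into QC-ready site and call tables
#'
#' Parses an uncompressed or bgzipped VCF. Multi-allelic records are
#' decomposed into one bi-allelic site row per alternate allele. Site
#' missingness is computed as the fraction of samples without a genotype
#' call; mappability is taken from the INFO key `MP` (default 1 when absent);
#' the VQSR tranche sensitivity is taken from the INFO key `VQSR` when
#' present, otherwise parsed from tranche-style FILTER strings, with a plain
#' `PASS` treated as fully sensitive. Allele balance for heterozygous calls
#' is computed from the `AD` FORMAT field.
#'
#' @param path path to the VCF file.
#' @return A list with `sites` and `calls` data frames as used by
#'   [apply_qc()].
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  ad <- vcfR::extract.gt(v, element = "AD")
  info_mp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MP")))
  info_vqsr <- suppressWarnings(as.numeric(vcfR::extract.info(v, "VQSR")))

  samples <- colnames(gt_raw)
  n_rec <- nrow(fix)
  sites <- list(); calls <- list()
  for (i in seq_len(n_rec)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    gts <- gt_raw[i, ]
    called <- !is.na(gts) & !gts %in% c("./.", ".|.", ".")
    missingness <- 1 - mean(called)
    vq <- info_vqsr[i]
    if (is.na(vq)) vq <- .vqsr_from_filter(fix$FILTER[i])
    if (is.na(vq)) vq <- 0
    mp <- if (is.na(info_mp[i])) 1 else info_mp[i]
    for (k in seq_along(alts)) {
      vid <- paste(fix$CHROM[i], fix$POS[i], fix$REF[i], alts[k], sep = ":")
      sites[[length(sites) + 1L]] <- data.frame(
        variant_id = vid, chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k], missingness = missingness,
        mappability = mp, vqsr_tranche = vq, filter_status = fix$FILTER[i],
        stringsAsFactors = FALSE)
      geno <- vapply(seq_along(gts), function(j) {
        if (!called[j]) return("missing")
        a <- suppressWarnings(as.integer(strsplit(gts[j], "[/|]")[[1]]))
        if (any(is.na(a))) return("missing")
        nk <- sum(a == k)
        if (nk == 0) "hom_ref" else if (nk == length(a)) "hom_alt" else "het"
      }, character(1))
      ab <- vapply(seq_along(gts), function(j) {
        if (geno[j] != "het" || is.na(ad[i, j])) return(NA_real_)
        counts <- suppressWarnings(as.numeric(
          strsplit(ad[i, j], ",", fixed = TRUE)[[1]]))
        tot <- sum(counts, na.rm = TRUE)
        if (tot <= 0 || length(counts) < k + 1) return(NA_real_)
        counts[k + 1] / tot
      }, numeric(1))
      calls[[length(calls) + 1L]] <- data.frame(
        variant_id = vid, sample_id = samples, genotype = geno,
        depth = as.numeric(dp[i, ]), allele_balance = ab,
        genotype_quality = as.numeric(gq[i, ]),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  list(sites = do.call(rbind, sites), calls = do.call(rbind, calls))
}
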