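#' Rarity test against reference population allele frequencies
#'
#' A variant is rare when its allele frequency is below the cutoff in both
#' the ExAC and gnomAD exome reference panels. A variant absent from a panel
#' (frequency `NA`) is treated as frequency 0, i.e. rare with respect to that
#' panel: variants reported in none of the panels qualify.
#'
#' @param af_exac,af_gnomad numeric vectors of allele frequencies in \[0, 1\],
#'   `NA` where the variant is absent from the panel.
#' @param af_cutoff rarity cutoff; default `1e-4` (0.01%).
#' @return Logical vector: `TRUE` where rare in both panels.
#' @examples
#' is_rare(c(NA, 5e-5, NA), c(NA, 9e-5, 1e-4))  # TRUE TRUE FALSE
#' @export
is_rare <- function(af_exac, af_gnomad, af_cutoff = 1e-4) {
  n <- max(length(af_exac), length(af_gnomad))
  af_exac <- rep_len(af_exac, n)
  af_gnomad <- rep_len(af_gnomad, n)
  if (any(c(af_exac, af_gnomad) < 0, na.rm = TRUE))
    stop("allele frequencies must be non-negative")
  if (any(c(af_exac, af_gnomad) > 1, na.rm = TRUE))
    stop("allele frequencies must not exceed 1")
  af_exac[is.na(af_exac)] <- 0
  af_gnomad[is.na(af_gnomad)] <- 0
  af_exac < af_cutoff & af_gnomad < af_cutoff
}

.consequence_levels <- c("stopgain", "frameshift_indel", "canonical_splice",
                         "exon_deletion", "missense", "synonymous", "other")
.class_levels <- c("LGD", "D_mis", "synonymous", "other")
.lgd_consequences <- c("stopgain", "frameshift_indel", "canonical_splice",
                       "exon_deletion")

#' Deleteriousness class of a variant
#'
#' Partitions variants into the four classes used throughout the burden
#' analysis: LGD (likely gene-disrupting: premature stopgain, frameshift
#' indel, canonical splice-site variant, or exon deletion), D-mis (missense
#' with REVEL score above the cutoff), synonymous, and other. Every variant
#' receives exactly one class. A missense variant without a REVEL score
#' cannot be called damaging and falls into "other", with a warning.
#'
#' @param consequence character vector of consequence labels (one of
#'   stopgain, frameshift_indel, canonical_splice, exon_deletion, missense,
#'   synonymous, other).
#' @param revel numeric vector of REVEL scores in \[0, 1\], `NA` when
#'   unavailable; only used for missense variants.
#' @param revel_cutoff D-mis threshold, strict: `revel > revel_cutoff`.
#'   Default 0.5.
#' @return Factor with levels `LGD`, `D_mis`, `synonymous`, `other`.
#' @examples
#' classify_variant(c("stopgain", "missense", "missense", "synonymous"),
#'                  revel = c(NA, 0.91, 0.50, NA))
#' @export
classify_variant <- function(consequence, revel = NA_real_,
                             revel_cutoff = 0.5) {
  n <- max(length(consequence), length(revel))
  consequence <- rep_len(as.character(consequence), n)
  revel <- rep_len(revel, n)
  bad <- !consequence %in% .consequence_levels
  if (any(bad))
    stop("unknown consequence label(s): ",
         paste(unique(consequence[bad]), collapse = ", "))
  if (any(revel < 0 | revel > 1, na.rm = TRUE))
    stop("REVEL scores must lie in [0, 1]")

  cls <- rep("other", n)
  cls[consequence %in% .lgd_consequences] <- "LGD"
  mis <- consequence == "missense"
  no_score <- mis & is.na(revel)
  if (any(no_score))
    warning(sum(no_score),
            " missense variant(s) without a REVEL score classified as 'other'")
  cls[mis & !is.na(revel) & revel > revel_cutoff] <- "D_mis"
  cls[consequence == "synonymous"] <- "synonymous"
  factor(cls, levels = .class_levels)
}

#' Classify a table of annotated variants
#'
#' Adds `rare` and `class` columns to an annotated variant table. Columns
#' used: `consequence`, and when present `revel`, `af_exac`,
#' `af_gnomad_wes`. A `qualifying` column marks rare LGD or D-mis variants,
#' the unit counted by the burden tests.
#'
#' @param variants `data.frame` of annotated variants.
#' @param af_cutoff,revel_cutoff thresholds passed to [is_rare()] and
#'   [classify_variant()].
#' @return The input with `rare`, `class` and `qualifying` columns added.
#' @export
classify_variants <- function(variants, af_cutoff = 1e-4, revel_cutoff = 0.5) {
  stopifnot("consequence" %in% names(variants))
  revel <- if ("revel" %in% names(variants)) variants$revel else NA_real_
  af1 <- if ("af_exac" %in% names(variants)) variants$af_exac else NA_real_
  af2 <- if ("af_gnomad_wes" %in% names(variants)) variants$af_gnomad_wes
         else NA_real_
  variants$rare <- is_rare(af1, af2, af_cutoff)
  variants$class <- classify_variant(variants$consequence, revel, revel_cutoff)
  variants$qualifying <- variants$rare & variants$class %in% c("LGD", "D_mis")
  variants
}

# ANNOVAR-style exonic-function labels -> consequence enum
.annovar_map <- c(
  "stopgain" = "stopgain",
  "stopgain snv" = "stopgain",
  "frameshift insertion" = "frameshift_indel",
  "frameshift deletion" = "frameshift_indel",
  "frameshift substitution" = "frameshift_indel",
  "frameshift_indel" = "frameshift_indel",
  "splicing" = "canonical_splice",
  "canonical_splice" = "canonical_splice",
  "exon_deletion" = "exon_deletion",
  "nonsynonymous snv" = "missense",
  "missense" = "missense",
  "synonymous snv" = "synonymous",
  "synonymous" = "synonymous",
  "nonframeshift insertion" = "other",
  "nonframeshift deletion" = "other",
  "nonframeshift substitution" = "other",
  "stoploss" = "other",
  "unknown" = "other")

#' Map annotation labels or alleles to a consequence
#'
#' Resolves the consequence enum from, in order of precedence: a recognized
#' annotation label (ANNOVAR-style exonic function strings), proximity to an
#' intron/exon boundary (within 2 intronic bases = canonical splice), or the
#' ref/alt length difference for indels inside the coding sequence (length
#' change not divisible by 3 = frameshift, otherwise in-frame "other").
#' Unrecognized labels map to "other" with a warning.
#'
#' @param ref,alt allele strings.
#' @param label optional annotation label.
#' @param splice_distance optional distance in intronic bases to the nearest
#'   exon boundary (`NA` for exonic positions).
#' @param in_cds logical, whether the variant lies in coding sequence.
#' @return A consequence string.
#' @examples
#' consequence_from_alleles("C", "T", label = "stopgain")
#' consequence_from_alleles("TGACCCCGACCCGGGCCCGGGAG", "T")  # 22 bp deletion
#' consequence_from_alleles("TTTC", "T")                     # in-frame
#' @export
consequence_from_alleles <- function(ref, alt, label = NULL,
                                     splice_distance = NA, in_cds = TRUE) {
  if (!is.null(label) && !is.na(label) && nzchar(label)) {
    key <- tolower(label)
    if (key %in% names(.annovar_map)) return(unname(.annovar_map[[key]]))
    warning("unknown annotation label '", label, "' mapped to 'other'")
    return("other")
  }
  if (!is.na(splice_distance) && abs(splice_distance) <= 2 &&
      splice_distance != 0)
    return("canonical_splice")
  dl <- nchar(alt) - nchar(ref)
  if (dl != 0) {
    if (!in_cds) return("other")
    return(if (dl %% 3 != 0) "frameshift_indel" else "other")
  }
  "other"
}

#' Read an annotated-variant TSV
#'
#' Expected columns: `gene`, `consequence`, and optionally `chrom`, `pos`,
#' `ref`, `alt`, `af_exac`, `af_gnomad_wes`, `revel`, `cadd`. Empty strings,
#' `"."` and `"-"` in numeric columns are read as `NA` (absent).
#'
#' @param path path to a tab-separated annotation file with a header row.
#' @return A `data.frame`.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", "", ".", "-"))
  stopifnot(all(c("gene", "consequence") %in% names(df)))
  for (col in intersect(c("af_exac", "af_gnomad_wes", "revel", "cadd"),
                        names(df)))
    df[[col]] <- as.numeric(df[[col]])
  df
}
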