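# Independent brute-force oracles used to cross-check the analytic paths.

# one-sided upper-tail binomial probability by pmf summation
binom_tail_oracle <- function(x, size, prob) {
  if (x <= 0) return(1)
  if (x > size) return(0)
  sum(dbinom(x:size, size, prob))
}

# one-sided upper-tail Poisson probability by direct pmf summation
# (summed over the tail itself so deep tails keep full precision)
pois_tail_oracle <- function(m1, m0) {
  if (m1 <= 0) return(1)
  sum(dpois(m1:(m1 + 600), m0))
}

# step-up Benjamini-Hochberg, written independently of p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# two-sided Fisher p by full hypergeometric enumeration (minimum-likelihood)
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, c1, n - c1, r1)
  obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# small fixture builders ----------------------------------------------------

make_sites <- function(n = 1, chrom = "1", pos = seq_len(n) * 100,
                       missingness = 0, mappability = 1,
                       vqsr_tranche = 100, filter_status = "PASS") {
  data.frame(variant_id = sprintf("v%02d", seq_len(n)),
             chrom = rep_len(chrom, n), pos = rep_len(pos, n),
             ref = rep_len("A", n), alt = rep_len("T", n),
             missingness = rep_len(missingness, n),
             mappability = rep_len(mappability, n),
             vqsr_tranche = rep_len(vqsr_tranche, n),
             filter_status = rep_len(filter_status, n),
             stringsAsFactors = FALSE)
}

make_calls <- function(variant_id, n = 1, genotype = "het", depth = 30,
                       allele_balance = 0.5, genotype_quality = 99) {
  data.frame(variant_id = variant_id,
             sample_id = sprintf("S%02d", seq_len(n)),
             genotype = genotype, depth = depth,
             allele_balance = allele_balance,
             genotype_quality = genotype_quality,
             stringsAsFactors = FALSE)
}

# minimal two-sample VCF with QC FORMAT fields, written as plain text
write_test_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MP,Number=1,Type=Float,Description=\"Mappability\">",
    "##INFO=<ID=VQSR,Number=1,Type=Float,Description=\"Tranche sensitivity\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "SAMP1", "SAMP2", sep = "\t"),
    paste("1", "150", ".", "A", "T", "100", "PASS", "MP=1;VQSR=99.8",
          "GT:DP:GQ:AD", "0/1:40:99:22,18", "0/0:35:80:35,0", sep = "\t"),
    # multi-allelic record: decomposes into two sites
    paste("1", "300", ".", "G", "A,C", "90", "PASS", "MP=1;VQSR=99.7",
          "GT:DP:GQ:AD", "0/1:30:60:15,15,0", "0/2:28:55:14,0,14",
          sep = "\t"),
    # tranche-filtered record, no VQSR INFO key
    paste("1", "450", ".", "C", "T", "50",
          "VQSRTrancheSNP99.60to99.80", "MP=0.8", "GT:DP:GQ:AD",
          "0/1:20:50:10,10", "./.:.:.:.", sep = "\t"))
  writeLines(lines, path)
  path
}
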