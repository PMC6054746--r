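---
title: "Rare-variant burden association with population controls: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant burden association with population controls: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvburden)
```

# The analysis problem

Gene discovery for a rare disease with a modest case collection (a few
hundred exomes) cannot rely on a matched, jointly called control cohort of
similar size: there is too little power. A widely used alternative is the
*collapsing* or *burden* design against population reference controls:
count, per gene, the rare variants predicted to damage the gene product in
cases and in a large public reference cohort (such as the gnomAD non-Finnish
European genomes), and test whether cases carry more than their share.
`rvburden` implements that design end to end — variant-level quality
control, classification into deleteriousness classes, the per-gene and
per-gene-set binomial tests with multiple-testing control, the
batch-effect calibration that the design requires, trio de novo enrichment
against a context-dependent background mutation model, and a permutation
test for expression overlap of implicated gene sets — together with
synthetic-data generators so the whole pipeline is exercisable and testable
without access to protected genotype data.

# The burden model

Let a gene have $x_1$ qualifying variants among $n_1$ cases and $x_0$ among
$n_0$ controls. Under the null hypothesis that qualifying variants accrue at
the same per-subject rate in both cohorts, conditioning on the total
$x_1 + x_0$ gives

$$ X_1 \mid (X_1 + X_0 = x_1 + x_0) \;\sim\;
   \mathrm{Binomial}\!\left(x_1 + x_0,\; \frac{n_1}{n_1 + n_0}\right), $$

and the evidence for enrichment is the one-sided upper tail
$P(X_1 \ge x_1)$. This conditional construction is exact for Poisson-many
variant counts in each cohort and requires no per-gene rate estimate. The
effect size is reported as the per-subject frequency ratio

$$ \widehat{R} = \frac{x_1 / n_1}{x_0 / n_0}, $$

which is also the odds transform of the conditional binomial proportion —
both identities are unit-tested. With the counts that motivate the package's
worked examples ($x_1 = x_0 = 5$, $n_1 = 144$, $n_0 = 7509$) the test gives
$p = 5.5 \times 10^{-7}$ and $\widehat{R} = 52$.

Two conventions matter and are applied consistently:

* the **unit counted is a qualifying variant observation**, not a distinct
  carrier — a subject with two qualifying variants in one gene contributes
  two (in sparse rare-variant data the two coincide almost always);
* $x_1 = 0$ yields $p = 1$ by the upper-tail convention, and genes with
  $x_0 = 0$ report infinite $\widehat{R}$ but keep a valid $p$-value and a
  flag, since absence from the reference panel is itself informative.

**Multiple testing.** A genome-wide scan over $m$ genes applies the
Bonferroni family-wise bound (threshold $\alpha/m$, e.g.
$0.05/17{,}701 = 2.8\times10^{-6}$) and Benjamini–Hochberg step-up FDR
(via `p.adjust`). The number of tests can be set explicitly when the count
table is a subset of the genes actually scanned.

**Calibration.** Cases and reference controls are sequenced and processed on
different platforms, so the design is only credible if a neutral variant
class shows no differential burden. `synonymous_calibration()` pools rare
synonymous counts exome-wide, reports the pooled enrichment, and raises a
flag outside a configurable band (default $[0.9, 1.1]$; at the pooled-count
scale of a real study, $5\times10^4$ variants and up, the ratio's sampling
error is about 3%, so the band is wide relative to noise).

## Conservativeness of the exact test

The conditional binomial test is discrete: at a nominal level
$\alpha = 0.001$ its achievable rejection probability per gene is the tail
mass of the most extreme attainable outcomes, which is strictly below
$\alpha$ for the count totals typical of rare-variant data (a handful of
variants per gene). Empirically, on null synthetic cohorts of 10,000 genes
the rejection rate at $\alpha = 0.001$ falls between $1\times10^{-4}$ and
$4\times10^{-4}$ depending on the baseline count scale. The test is
therefore *valid* (never anti-conservative) but not *exactly calibrated* at
nominal level; the test suite asserts the validity bound, and users should
expect genome-wide scans of sparse counts to be conservative. This is a
property of all exact discrete tests, not an implementation artifact.

# Variant QC and classification

Genotype calls are filtered on read depth ($\le 8$ fails), allele balance
($\le 20\%$ fails) and genotype quality ($< 30$ fails); sites are filtered
on missingness ($> 10\%$ fails), mappability ($< 1$ on 150 bp fragments
fails), VQSR tranche sensitivity ($< 99.6$ fails), FILTER status (anything
but `PASS` fails) and position outside the capture regions. Boundary
semantics are taken literally from those inequalities, so depth 9, allele
balance 0.201, genotype quality 30, missingness 0.10, mappability 1.0 and
tranche 99.6 all pass. Design choices where the conventions were genuinely
open:

* the allele-balance filter targets suspect **heterozygous** calls;
  homozygous-alternate calls are exempt and reference/missing genotypes are
  not filtered;
* a tranche sensitivity is parsed from a numeric `VQSR` INFO key when
  present, otherwise from tranche-style FILTER strings; a plain `PASS` is
  treated as fully sensitive;
* multi-allelic records are decomposed into bi-allelic site records before
  filtering, so QC fields are per-alternate;
* VCF coordinates are 1-based inclusive, BED intervals half-open 0-based,
  and region membership is tested on the variant's 1-based start position,
  making the restriction invariant to union-preserving interval splits.

Classification is a pure function of the annotation: stopgain, frameshift
indel, canonical splice-site (the two intronic bases at each exon boundary)
and exon-deletion consequences are **LGD** (likely gene-disrupting);
missense with REVEL $> 0.5$ is **D-mis**; synonymous is its own class;
everything else — including in-frame indels — is **other**. A variant absent
from both reference panels is treated as frequency 0 and hence rare
(AF $< 0.01\%$ in both panels is required); a missense variant with no REVEL
score cannot be called damaging and falls to *other* with a warning rather
than an error. CADD scores are carried as metadata only; no CADD cutoff
enters the qualifying definition. In-frame deletions are deliberately not
admitted to LGD even though curated risk-gene screens sometimes count
specific in-frame events as deleterious on external evidence; an
annotation-only pipeline has no principled rule to admit them.

# De novo enrichment

The expected number of de novo variants of a class $c$ in $n$ trios is

$$ m_0(c) = 2n \sum_{\text{positions } i}\; \sum_{\text{alt } b}
   \mathbf{1}\{\mathrm{cons}(i,b) \in c\}\; \mu(\mathrm{ctx}_i, b), $$

where $\mu$ is a trinucleotide-context substitution rate table (64 contexts
$\times$ 3 alternates) and the factor 2 accounts for the two transmitted
haploid genomes. Consequences of all three substitutions at every coding
position are derived from the standard genetic code; positions at a
sequence edge, whose context is undefined, are skipped and counted.
Observed counts are tested with the exact Poisson upper tail
$P(X \ge m_1)$, $X \sim \mathrm{Poisson}(m_0)$, and enrichment $m_1/m_0$.
The model covers substitutions only: de novo indels are counted among
observations but contribute nothing to $m_0$, so classes containing indels
are tested slightly anti-conservatively and should be read accordingly. The
package ships **no published rate constants**: `toy_rate_table()` generates
a synthetic table (log-normal rates around a configurable mean, CpG
transitions boosted tenfold) for tests and simulations, and real analyses
should supply an empirical table via `read_rate_table()`.

Trio inheritance calls follow the genotype pattern: de novo requires a
carrying child with both parents homozygous reference; a carrying parent
makes the variant inherited (with origin); a missing parent leaves the
origin unknown; and a homozygous-alternate child with exactly one
non-carrying genotyped parent is flagged as a Mendelian inconsistency.

# Expression overlap

To ask whether an implicated gene set (for instance, transcription-factor
targets carrying qualifying variants) is preferentially expressed in two
disease-relevant tissues, expression values are converted to per-tissue
quantile ranks (average-rank ties, `rank/n`, hence invariant to monotone
transformations), a gene is *double-top* if its quantile is $\ge 0.75$ in
both tissues, and the observed double-top count among $k$ focal genes is
compared with draws of $k$ genes without replacement from a background of
genes carrying at least one qualifying variant. The empirical $p$ uses the
pseudocount rule $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$, so it is
never zero and equals $\approx 10^{-5}$ when nothing among $B = 10^5$ draws
reaches the observed count. Under independent tissues the per-gene
double-top probability is $1/16$, giving a
$\mathrm{Binomial}(k, 1/16)$ oracle for the null moments that the test
suite checks.

# What the synthetic generators emulate — and what they do not

`generate_cohort()` draws per-gene counts directly:
$x_0 \sim \mathrm{Poisson}(n_0 r)$,
$x_1 \sim \mathrm{Poisson}(n_1 r \cdot \text{multiplier})$, which is exactly
the sampling model under which the conditional binomial test is exact. Case
counts are materialized as annotated variant rows whose consequence, REVEL
and allele-frequency fields reproduce the intended classification, so the
classify-then-count path is exercised, not bypassed. Defaults mirror the
study scale the package was built around: 144 cases, 7509 controls, 17,701
genes, a baseline rate of $5/7509$ qualifying variants per gene per subject
(about five control variants per gene, the order observed for rare
deleterious variants in large reference cohorts), one planted risk gene at
a 52-fold case rate, and a synonymous rate six times the deleterious
baseline (rare synonymous variants are several-fold more numerous than rare
LGD plus damaging missense). A `batch_shift` multiplier on the control
synonymous rate emulates a platform batch effect for calibration testing.

What the generators deliberately do **not** emulate: linkage and haplotype
structure, ancestry admixture, per-sample variation in coverage or call
rate, gene length and constraint heterogeneity (every null gene shares one
baseline rate), and correlated errors between variant classes. Passing
tests therefore demonstrate the statistical machinery under the model's own
assumptions; they do not certify robustness to stratification or
platform artifacts in real data — that is precisely what the synonymous
calibration is for at analysis time.

`generate_trios()` samples de novo events with probability proportional to
the rate table over the supplied coding sequences (two haploid genomes per
trio), so the expected total equals $m_0$ by construction;
`generate_expression()` gives background genes independent uniform
quantiles and forces each signal gene, with probability `signal_strength`,
into concordantly high expression in both tissues, making the expected
double-top fraction among signal genes
$s + (1 - s)/16$ — the analytic handle used to plant a chosen overlap.

# Numerical and design choices

* One-sided "greater" alternatives throughout: the scientific question is
  enrichment, and the printed significance of the motivating study is
  reproduced by the upper tail.
* Cohort sizes are explicit arguments everywhere rather than package
  constants; the motivating study itself reports both 143 and 144 European
  cases in different sections, and the worked examples use 144 (the
  difference does not move the headline numbers at their printed
  precision).
* The attributable-fraction estimator is the carrier-frequency difference
  $100(x_1/n_1 - x_0/n_0)$, recorded in the result's `method` attribute.
  For the motivating counts it gives 3.4%; published contribution estimates
  near 3% may use unstated variants of this formula, so the estimator
  choice is explicit and swappable.
* QQ data pair sorted observed $-\log_{10} p$ with uniform order-statistic
  expectations $-\log_{10}(i/(n+1))$.
* Ties in expression ranks use average ranks; "top quartile" is
  quantile $\ge 0.75$.
* Degenerate inputs fail loudly and early: negative counts, empty gene
  sets, degenerate 2x2 margins and zero expectations are errors, while
  zero-variant calibration returns an explicit "insufficient data" status.
* Scan ordering breaks $p$-value ties by descending case count.

## Problem sizes used by the test suite

The suite exercises the scan at 10,000 null genes for type-I validity,
20 independent 1000-gene cohorts for planted-gene recovery, $10^5$
permutations for the planted expression-overlap check and
$2\times10^4$–$5\times10^4$ permutations for null-moment checks — sizes at
which the relevant sampling errors are small compared to the asserted
tolerances while the whole suite runs in well under a minute per file.
Exact-tail oracles enumerate all binomial totals up to 50 and Poisson
expectations up to 20 (observations to 40).

# Known limitations

* Exact discrete tests are conservative at small counts (see above); no
  mid-$p$ or continuity-corrected variants are offered.
* No covariate adjustment, kernel/dispersion tests, or ancestry inference:
  cases are assumed pre-subset to match the reference-control ancestry,
  and the package consumes — never computes — alignment, calling,
  annotation, in-silico scores and mappability.
* The de novo expectation models substitutions only.
* Gene-level counts, not genotype matrices, drive the burden tests; allele
  sharing between related cases would violate the independence the model
  assumes and is not detected here.
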