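---
title: "Methods and design of rrdkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of rrdkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrdkit)
```

# Scope

`rrdkit` implements the biomarker computations used when analysing cohorts
of hypermutant, replication-repair-deficient (RRD) cancers treated with
immune checkpoint inhibition. Each stage is a pure function over explicit
inputs; upstream heavy lifting — read alignment, variant calling itself,
purity/ploidy estimation, HLA typing, clonotype assembly — is out of scope
and enters only as data. A seeded synthetic-data module produces every
input with known ground truth, which is how the package validates itself.

# Consensus variants and TMB

Somatic call sets from four callers are merged on the key
(chrom, pos, ref, alt). Callers represent the same indel differently, so
before keying, each record's shared ref/alt suffix is trimmed, then the
shared prefix (advancing the position), keeping at least one base of each
allele — a minimal left-alignment sufficient for 1-bp indels and anchored
representations. A variant is retained when at least `min_callers`
(default 2) *distinct* callers support it; duplicate records within one
caller count once. SNVs and indels are merged separately and unioned,
which is equivalent to a single pass but mirrors how consensus VCFs are
built per class. The consensus VAF and depth are medians across
supporting callers: robust, and neutral when callers disagree.

TMB divides the consensus SNV count by the callable territory in
megabases (default 50, a whole-exome capture); indels are excluded from
the numerator. Immune-escape flagging tallies consensus variants in a
configurable gene panel (default the antigen-presentation/interferon set
*B2M … IRF*). The trailing symbol is kept as the bare string `IRF`
because the source convention does not fix a family member; matching is
case-insensitive after whitespace stripping, and users can substitute any
symbol list.

# Cancer cell fraction and clonality

$$\mathrm{CCF} = \mathrm{VAF}\cdot\frac{p\,c + (1-p)\,c_\mathrm{normal}}{m\,p}$$

with purity $p\in(0,1]$, local tumor copy number $c$, normal copy number
$c_\mathrm{normal}$ (2 for autosomes) and multiplicity $m\ge 1$. This is
the standard inversion of the expected-VAF model used across the
clonality literature; it is confined to `compute_ccf()` so an alternative
parameterization is a one-function swap. Sampling noise can push the raw
estimate above 1, so the value used for classification is capped at 1
while the raw value is kept as an attribute. A variant is clonal iff
CCF strictly exceeds 0.85; the boundary value is subclonal. When $m$ is
unknown it defaults to
$\mathrm{clip}(\mathrm{round}(\mathrm{VAF}\,(p c+(1-p)c_n)/p),\,1,\,c)$.

At binomial depth 500 the separation between CCF 1.0 and CCF 0.4 variants
is large relative to the VAF sampling noise, which is why the test suite
can demand ≥ 95% classification accuracy without any tuning.

# MMRDness score

Mismatch-repair deficiency leaves a quantifiable excess of single-base
deletions at adenine homopolymers in low-pass sequencing. For loci with
repeat base `A`, length 10–15 inclusive, and at least `min_coverage`
reads (default 10 — below that, a per-locus proportion is too unstable to
sum), the score is

$$\log_{10}\Big(\sum_\ell \frac{\text{del1 reads}_\ell}{\text{total reads}_\ell}\Big) + 1.1 .$$

Only single-base deletions count; insertions and longer deletions are
ignored. One row per locus is enforced. A zero sum has no defined
logarithm: the result carries an explicit `below_detection` status rather
than $-\infty$. With 100 informative loci the expected score is
$\log_{10}(100\bar\pi)+1.1$ — about 1.80 at a deficient per-locus mean
deletion proportion of $\bar\pi=0.05$ and about 0.80 at a proficient
0.005; those two generator defaults are placeholders chosen to separate
the regimes cleanly, not biological estimates, because per-locus
magnitudes are not established quantities.

# Panel normalization and the TIS

QC: the geometric mean of the four housekeeping genes' raw counts
(*DDX50, EIF2B4, MRPS5, SAP130*) is the per-sample RNA quality metric;
samples strictly below 100 are excluded (exactly 100 passes). A zero in
any housekeeping gene zeroes the geomean and excludes the sample.

Normalization is sequential: per-sample geometric mean of the positive
controls, grand geometric mean of those, factor = grand/per-sample,
applied to all genes; then the identical step with the housekeeping
genes. Two algebraic facts are worth recording because they shape the
invariants we test. First, the composition collapses to
$\text{final}_s = \text{raw}_s \cdot G_{hk}/g_{hk,s}$ (the
positive-control step cancels inside the housekeeping step), so
renormalizing a normalized matrix leaves the counts exactly fixed while
the second run's two factor vectors are individually non-unit and cancel
(product 1). Second, scaling one sample's raw counts by $k$ rescales the
*whole* normalized matrix by $k^{1/n}$ through the grand geomean; all
between-sample and between-gene ratios are invariant, but the absolute
values are not. Negative controls are read and carried through unused —
no background subtraction is performed.

The TIS score is $\sum_g w_g \log_2(x_{gs} + 1)$ over the genes of a
user-supplied weights table. The pseudocount of 1 handles zero counts.
The published weights belong to the signature's original reference and
are deliberately not hard-coded; `unit_tis_weights()` is a documented
placeholder that makes the score a plain sum of log2 counts. The
operative gene set is whatever the weights table lists, which also
sidesteps the 17-versus-18 gene enumeration ambiguity.

# Indel signature refitting

Given an 83-channel indel catalog $y$ and reference signature matrix $S$
(columns are probability vectors), the refit solves
$\min_{w\ge 0}\|y - Sw\|_2$ by nonnegative least squares (Lawson–Hanson,
via `pracma::lsqnonneg`). Absolute contributions are $w$; relative
contributions $w/\sum w$ (undefined for an all-zero catalog, reported as
a status). No sparsity penalty or signature pre-selection is applied —
plain fitting. Residual is zero exactly when the catalog lies in the
nonnegative cone of the signatures, and relatives are scale-invariant;
the tests verify both, plus agreement with an independent grid-search
oracle at $10^{-3}$ on two-signature problems.

The bundled signature matrix is synthetic (the filename says so): valid
probability columns with ID1-like (1-bp T insertions at long
homopolymers), ID2-like (1-bp T deletions) and ID8-like (long deletions
and microhomology deletions, the end-joining footprint of ionizing
radiation) shapes. A real COSMIC v3.2 ID-83 TSV is a drop-in via the same
format. `classify_1bp_indels()` bridges anchored VCF indels to the 1-bp
homopolymer channels given a run-length context provider; everything else
lands in an explicit unclassified bucket and is excluded from refitting —
full ID-83 classification from a reference genome is out of scope.

# HLA loss of heterozygosity

The decision layer is deliberately simple: LOH iff the paired
allelic-imbalance p-value is strictly below 0.01, per gene, with no
multiple-testing correction and no copy-number gate (a combined
copy-number + p cutoff under-calls LOH in hypermutant tumors where true
copy losses are rare; the copy-number estimate is reported for context
only). The test behind the p-value is a paired two-sided test on
per-position statistics
$\log\frac{t_1+0.5}{t_2+0.5} - \log\frac{n_1+0.5}{n_2+0.5}$ — tumor
allele ratio normalized by the normal's — with a paired t default and a
Wilcoxon signed-rank option. The 0.5 pseudocount guards zero coverage.
Fewer than 5 mismatch positions yields an `insufficient` status, never a
fabricated p; perfectly balanced input (all-zero differences) returns
p = 1. Under a Poisson-coverage null the statistic is close enough to
symmetric-normal that the t-test holds its 1% size, which the suite
verifies empirically.

# TCR repertoire

Down-sampling to a fixed read total is an exact multivariate
hypergeometric draw, implemented as sequential conditional `rhyper` draws
per clonotype (no per-read materialization). It never invents a
clonotype, preserves the target total exactly, and returns an undersized
table unchanged with a warning. Metrics: clone count; clonotypes per
1,000 reads = clone count / (total/1000); Shannon
$H = -\sum f_i\ln f_i$ in natural log (stated explicitly since
conventions differ), so $H=\ln k$ for $k$ equal clones.

# Survival and contingency layer

Intervals: PFS1 (monotherapy start → radiologic progression), OS1
(monotherapy start → death), PFS2 (salvage start → progression or
death), OS2 (salvage start → death), censored at last follow-up; months
are days/30.4375 (mean Gregorian month — the sources print months without
a conversion rule). A stop date before its start is an error naming the
subject.

Kaplan–Meier uses the product-limit estimator (`survival::survfit`,
log(−log) CIs). The median is computed from the curve as the earliest
time with $S(t)\le 0.5$ — stated because `survfit`'s printed median
averages over a flat run when $S$ hits exactly 0.5. Log-rank is the
standard $\chi^2$ on groups−1 df. Fisher's exact p uses the
point-probability two-sided method with the conditional-MLE odds ratio
(`stats::fisher.test`; the suite checks it against full hypergeometric
enumeration for every 2×2 table with margins ≤ 15). Wilcoxon–Mann–Whitney
is exact for combined n ≤ 20 without ties, else normal approximation with
corrections.

Response summaries use the reporting convention for percentages: nearest
whole percent, ties away from zero, except exact half percents (12.5,
62.5) which keep one decimal — the rule that reproduces printed cohort
figures from their counts. Disease control is CR+PR+SD.

# The synthetic cohort

`sim_config()` fixes the study conditions; all generators derive
per-stage substreams from one seed, so identical configuration and seed
give byte-identical outputs and truth tables always accompany data.
Defaults: 500 variants at purity 0.7, 70% clonal (subclonal CCF uniform
on 0.2–0.6), depth 150 (a typical exome), 10% 1-bp indels; true variants
are emitted by k of 4 callers with k ~ {5%, 15%, 30%, 50%} on {1,2,3,4}
(exercising both sides of the 2-of-4 rule) and each caller observes an
independent binomial read draw, with caller-private false positives at
rate 0.05. Microsatellites: 100 A-homopolymer loci, lengths uniform on
10–15, deletion proportions as above. Panel: a positive-control titration
ladder (always detected — spike-ins don't drop to zero on a real lane),
background negative controls, the four housekeeping genes and 103
non-control genes including the TIS set, negative-binomial with
dispersion 0.1 (mild overdispersion typical of count panels), lognormal
per-sample technical factors. Survival: exponential event times with
rate ln2/median per group, defaults 11.6 vs 1.2 months (the
continue/stop contrast), n = 50/group; "uniform censoring at rate r"
means each record is independently censored with probability r at a
Uniform(0, event time) draw.

What the generator does **not** emulate: sequencing error and mapping
artifacts, caller-specific biases beyond representation differences
(position jitter is off by default), germline contamination, copy-number
noise, batch effects in panels, and real COSMIC signature shapes. Passing
recovery tests therefore demonstrates the correctness and calibration of
the computations, not robustness to every artifact of real data.

# Problem sizes and numerical tolerances

The suite validates worked examples to 1e-9 (or exact identity),
algebraic invariants to 1e-9, and stochastic recoveries at the sizes a
desk-scale study would use: clonality classification at depth 500 with
1,000 variants; regime separation at 50 samples/arm × 100 loci × depth
100; mixture refits at 10,000 indels; KM median recovery at n = 2,000;
type-I error of the log-rank test (nominal 0.05 ± 0.01) and of the HLA
imbalance test (nominal 0.01 ± 0.005) at 10,000 replicates; Fisher
enumeration over all 12,375 tables with margins ≤ 15. Published survival
medians and p-values from the motivating setting are not recomputable
without patient-level times, so no claims are made about them; the
percentage layer is validated on printed numerator/denominator pairs,
which are exact.

# Known limitations

Indel normalization is prefix/suffix trimming, not full left-alignment
against a reference; the ID-83 bridge classifies only 1-bp homopolymer
indels; the HLA test is a simplified stand-in for a full allele-specific
copy-number caller (the decision rule, which is the contribution here, is
faithful); `cohort_percent`'s convention is a reporting choice and other
venues round differently; and the bundled signature matrix is synthetic —
conclusions about real ID8 burden require the real reference matrix.
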