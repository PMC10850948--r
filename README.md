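# rrdkit

Biomarker computations for immuno-oncology cohort studies of hypermutant,
**replication-repair-deficient (RRD)** cancers — tumors with germline or
somatic loss of mismatch repair (PMS2/MLH1/MSH2/MSH6) or polymerase
proofreading (POLE/POLD1), most often high-grade gliomas. These tumors carry
extreme mutation burdens and microsatellite instability, which makes them
candidates for checkpoint inhibition; analysing such cohorts requires a
recurring set of genomic, transcriptomic and statistical computations that
this package implements as small, tested, composable stages:

- **Consensus variants & TMB** — merge per-caller somatic call sets by the
  2-of-4 rule (keyed on chrom/pos/ref/alt after indel normalization) and
  compute tumor mutational burden, TMB = somatic SNVs / callable Mb
  (default ~50 Mb exome); flag variants in immune-escape genes
  (*B2M, JAK1, JAK2, IFNGR1, IFNGR2, TYK2, STAT1/2/5A/5B, IRF*).
- **Clonality** — cancer cell fraction
  CCF = VAF · (p·c + (1−p)·c_normal) / (m·p), with purity *p*, local copy
  number *c*, multiplicity *m*; clonal iff CCF > 0.85 (strict).
- **MMRDness MSI score** — for A-homopolymers 10–15 bp with adequate
  coverage, score = log10(Σ per-locus single-base-deletion read
  proportions) + 1.1.
- **Panel normalization & TIS** — housekeeping-geomean QC (exclude < 100),
  two-step geometric-mean normalization (positive controls, then the
  housekeeping genes *DDX50, EIF2B4, MRPS5, SAP130*), and the tumor
  inflammation signature as a weighted sum of log2 counts.
- **Indel signature refitting** — nonnegative least squares of an
  83-channel indel catalog against reference signatures; reports absolute
  and relative contributions (e.g. of the radiation-associated ID8).
- **HLA-LOH** — paired allelic-imbalance test on per-position log coverage
  ratios; LOH is called by p < 0.01 alone, never gated on copy number.
- **TCR repertoire** — exact multivariate-hypergeometric down-sampling of
  clonotype tables; clone count, clonotypes per 1,000 reads, Shannon
  diversity.
- **Survival & contingency statistics** — the four interval conventions
  (PFS1/OS1 anchored at monotherapy start, PFS2/OS2 at salvage start;
  months = days/30.4375), Kaplan–Meier with log(−log) CIs, log-rank,
  Fisher exact, Wilcoxon–Mann–Whitney, and response summaries with the
  cohort's percentage-rounding convention.
- **Synthetic data** — a seeded generator for every input above with known
  ground truth, so each stage is validated end to end without patient
  data.

## Worked example

```r
library(rrdkit)
cfg <- sim_config(seed = 7, n_variants = 300, purity = 0.7)
sim <- simulate_variant_callsets(cfg)
cons <- merge_consensus(sim$callsets, min_callers = 2)
compute_tmb(cons, callable_mb = 50)
#> TMB: 5.10 mutations/Mb (255 SNVs / 50 Mb callable)

mmrdness_score(simulate_ms_loci(cfg))
#> MMRDness score: 1.7705 (sum of deletion proportions 4.6822 over 100 loci)

r <- refit_signatures(simulate_indel_catalog(cfg)$catalog)
relative_contribution(r, "ID8")
#> [1] 0.200   # generator truth: 0.2

sv <- simulate_survival(cfg)   # continued vs discontinued, medians 11.6 / 1.2
km_estimate(sv[sv$group == "continued", ])
#> Kaplan-Meier: 50 subjects, 44 events; median 14.78 months (95% CI 7.898-20.15)
logrank_test(sv)
#> Log-rank: chi-squared = 66.152 on 1 df, p = 4.174e-16

summarize_responses(c("CR", "PR", "PR", rep("SD", 15), rep("PD", 6)))
#> Best responses (n = 24):
#>   CR/PR  3 (12.5%)
#>   SD    15 (62.5%)
#>   PD     6 (25%)
#>   disease control 18 (75%)
```

The TMB of 5.1 mut/Mb is the consensus SNV count over a 50 Mb callable
exome; the MMRDness score near 1.8 is what a mismatch-repair-deficient
regime (mean deletion proportion 0.05 over 100 informative loci) produces,
versus ~0.8 for a proficient one; the refit recovers the simulated ID8
fraction; and the survival contrast mirrors a cohort in which patients
continuing therapy have a ~12-month median versus ~1 month for those
stopping. The response summary turns 24 best responses into a 75%
disease-control rate.

There is also an umbrella driver that chains all stages over one seed:

```r
report <- run_pipeline(pipeline_config(seed = 3))
```

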