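Package: rrdkit
Title: Biomarker Computations for Replication-Repair-Deficient Cancer Immunotherapy Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the genomic and immune biomarker computations used in
    immuno-oncology studies of hypermutant, replication-repair-deficient
    (RRD) cancers: consensus merging of somatic variant call sets and tumor
    mutational burden (TMB), cancer cell fraction (CCF) and clonality
    classification, a microsatellite-instability ("MMRDness") score from
    single-base-deletion read proportions at A-homopolymers, two-step
    geometric-mean normalization of expression-panel counts and the tumor
    inflammation signature (TIS), non-negative least-squares refitting of
    83-channel indel catalogs against reference mutational signatures,
    the HLA loss-of-heterozygosity decision rule on paired allelic-imbalance
    tests, T-cell receptor clonotype down-sampling and diversity metrics,
    and the survival-interval and contingency statistics layer. A seeded
    synthetic-data module generates every input with known ground truth so
    each stage can be exercised and validated without patient data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    pracma,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
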