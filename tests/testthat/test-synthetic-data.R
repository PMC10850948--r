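test_that("sim_config validates fractions, mixes and depth", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(purity = 0), "purity")
  expect_error(sim_config(purity = 1.2), "purity")
  expect_error(sim_config(depth = 0), "depth")
  expect_error(sim_config(signature_mix = c(ID1 = 0.6, ID8 = 0.5)), "sum to 1")
  expect_error(sim_config(survival_medians = c(a = -1)), "medians")
  expect_error(sim_config(subclonal_ccf_range = c(0.6, 0.2)), "low, high")
})

test_that("noise-free variant simulation reproduces the truth set exactly", {
  cfg <- sim_config(seed = 11, n_variants = 60, false_positive_rate = 0,
                    caller_count_dist = c("1" = 0, "2" = 0, "3" = 0, "4" = 1))
  sim <- simulate_variant_callsets(cfg)
  cons <- merge_consensus(sim$callsets, min_callers = 2)
  truth_keys <- paste(sim$truth$chrom, sim$truth$pos, sim$truth$ref,
                      sim$truth$alt, sep = ":")
  cons_keys <- paste(cons$chrom, cons$pos, cons$ref, cons$alt, sep = ":")
  expect_setequal(cons_keys, truth_keys)
  expect_true(all(cons$n_callers == 4))
})

test_that("diploid heterozygous clonal variants have truth VAF purity/2", {
  cfg <- sim_config(seed = 2, purity = 1, clonal_fraction = 1,
                    cn_profile = list(c(2, 1)))
  sim <- simulate_variant_callsets(cfg)
  expect_true(all(abs(sim$truth$true_vaf - 0.5) < 1e-12))
  # and generally vaf = ccf*m*p / (p*c + (1-p)*2)
  cfg2 <- sim_config(seed = 3, purity = 0.6, cn_profile = list(c(3, 2)))
  tr <- simulate_variant_callsets(cfg2)$truth
  expect_equal(tr$true_vaf,
               tr$ccf * tr$multiplicity * 0.6 / (0.6 * 3 + 0.4 * 2))
})

test_that("generators are byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 7, n_variants = 40)
  expect_identical(simulate_variant_callsets(cfg), simulate_variant_callsets(cfg))
  expect_identical(simulate_ms_loci(cfg), simulate_ms_loci(cfg))
  expect_identical(simulate_panel_counts(cfg), simulate_panel_counts(cfg))
  expect_identical(simulate_indel_catalog(cfg), simulate_indel_catalog(cfg))
  expect_identical(simulate_survival(cfg), simulate_survival(cfg))
  # VCF writing of a deterministic call set is byte-identical
  calls <- simulate_variant_callsets(cfg)$callsets$callerA
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_vcf_minimal(calls, f1); write_vcf_minimal(calls, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("microsatellite loci respect regime means and degenerate cases", {
  cfg0 <- sim_config(seed = 5, per_locus_deletion_mean = 0)
  expect_true(all(simulate_ms_loci(cfg0)$del1_reads == 0))
  # law of large numbers: 100 loci at mean 0.05, depth 10,000
  cfg <- sim_config(seed = 5, n_ms_loci = 100, depth = 10000,
                    per_locus_deletion_mean = 0.05)
  loci <- simulate_ms_loci(cfg)
  expect_true(all(loci$base == "A"))
  expect_true(all(loci$length >= 10 & loci$length <= 15))
  expect_lt(abs(sum(loci$del1_reads / loci$total_reads) - 5.0), 0.15)
  # proficient default is 0.005
  expect_equal(sim_config(ms_regime = "proficient")$per_locus_deletion_mean, 0.005)
})

test_that("panel simulation carries controls, housekeeping and TIS genes", {
  cfg <- sim_config(seed = 9, n_samples = 6)
  pm <- simulate_panel_counts(cfg)
  expect_gte(sum(pm$gene_class == "positive_control"), 6)
  expect_true(all(housekeeping_genes() %in% rownames(pm$counts)))
  expect_true(all(tis_gene_set() %in% rownames(pm$counts)))
  expect_equal(sum(pm$gene_class != "positive_control" &
                     pm$gene_class != "negative_control"), 103)
})

test_that("indel catalog draws match the mixed channel distribution", {
  expect_error(simulate_indel_catalog(sim_config(signature_mix = c(IDX = 1))),
               "absent")
  cfg0 <- sim_config(seed = 4, n_indels = 0)
  expect_true(all(simulate_indel_catalog(cfg0)$catalog == 0))
  # pure ID8 catalog is proportional to the ID8 column
  cfg <- sim_config(seed = 4, n_indels = 100000,
                    signature_mix = c(ID8 = 1))
  sim <- simulate_indel_catalog(cfg)
  emp <- sim$catalog / sum(sim$catalog)
  expect_lt(sum(abs(emp - example_signatures()[, "ID8"])), 0.02)
  # multinomial consistency at a mixed distribution
  cfgm <- sim_config(seed = 6, n_indels = 100000,
                     signature_mix = c(ID1 = 0.4, ID2 = 0.35, ID8 = 0.25))
  simm <- simulate_indel_catalog(cfgm)
  mixed <- example_signatures() %*% c(0.4, 0.35, 0.25)
  expect_lt(sum(abs(simm$catalog / sum(simm$catalog) - mixed)), 0.02)
})

test_that("survival simulation honors censoring and median parameters", {
  cfg0 <- sim_config(seed = 8, censoring_rate = 0)
  expect_true(all(simulate_survival(cfg0)$event == 1))
  cfg <- sim_config(seed = 8, survival_medians = c(g = 12),
                    n_per_group = 2000, censoring_rate = 0)
  sv <- simulate_survival(cfg)
  km <- km_estimate(sv)
  expect_lt(abs(km$median - 12) / 12, 0.10)
})
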