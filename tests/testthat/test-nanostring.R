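mk_panel <- function(hk = c(200, 200, 200, 200), pos = c(400, 400),
                     endo = c(GENE1 = 50), n_samples = 1,
                     sample_scale = rep(1, n_samples)) {
  genes <- c(housekeeping_genes(), paste0("POS_", seq_along(pos)), names(endo))
  cls <- c(rep("housekeeping", 4), rep("positive_control", length(pos)),
           rep("endogenous", length(endo)))
  base <- c(hk, pos, unname(endo))
  counts <- outer(base, sample_scale)
  dimnames(counts) <- list(genes, sprintf("S%d", seq_len(n_samples)))
  panel_count_matrix(counts, setNames(cls, genes))
}

test_that("QC excludes samples strictly below a housekeeping geomean of 100", {
  m <- mk_panel(n_samples = 3, sample_scale = c(0.5, 1, 0.4995))
  # geomeans: 100, 200, 99.9
  qc <- qc_filter(m)
  expect_setequal(qc$passing, c("S1", "S2"))
  expect_equal(qc$excluded, "S3")
  expect_match(qc$reasons[["S3"]], "99.90")
  # zero in any housekeeping gene forces geomean 0, hence exclusion
  z <- mk_panel(hk = c(0, 500, 500, 500), n_samples = 2,
                sample_scale = c(1, 1))
  z$counts["DDX50", "S2"] <- 400
  expect_equal(qc_filter(z)$excluded, "S1")
})

test_that("a missing housekeeping gene is a named validation error", {
  m <- mk_panel()
  rownames(m$counts)[1] <- "NOTHK"
  m$gene_class <- setNames(m$gene_class, rownames(m$counts))
  expect_error(qc_filter(m), "DDX50")
  expect_error(normalize_panel(m), "DDX50")
})

test_that("two-step geomean normalization matches the closed-form factors", {
  # positive-control geomeans 200 and 800 -> grand 400 -> factors 2 and 0.5
  m <- mk_panel(pos = c(200, 200), n_samples = 2, sample_scale = c(1, 4))
  norm <- normalize_panel(m)
  expect_equal(unname(norm$positive_factors), c(2, 0.5))
  # after step 1 all positive-control geomeans equal the grand geomean;
  # with proportional samples, housekeeping factors are then exactly 1
  expect_equal(unname(norm$housekeeping_factors), c(1, 1))
  pos_gm <- apply(norm$normalized$counts[c("POS_1", "POS_2"), ], 2,
                  function(x) exp(mean(log(x))))
  expect_equal(unname(pos_gm), c(400, 400))
  # single sample: both factors 1, counts unchanged
  one <- normalize_panel(mk_panel())
  expect_equal(unname(one$positive_factors), 1)
  expect_equal(one$normalized$counts, mk_panel()$counts)
})

test_that("normalization is idempotent and scale-invariant per sample", {
  cfg <- sim_config(seed = 13, n_samples = 8)
  pm <- qc_filter(simulate_panel_counts(cfg))$pass
  n1 <- normalize_panel(pm)
  n2 <- normalize_panel(n1$normalized)
  # the two-step map is idempotent: renormalizing leaves the counts fixed,
  # with the second run's step-1 and step-2 factors cancelling exactly
  expect_equal(n2$normalized$counts, n1$normalized$counts, tolerance = 1e-9)
  expect_lt(max(abs(n2$positive_factors * n2$housekeeping_factors - 1)), 1e-9)
  # multiplying one sample's raw counts by k > 0 leaves the normalized
  # matrix unchanged up to the single global factor k^(1/n) coming from the
  # grand geomean convention: every between-sample and between-gene ratio
  # is invariant
  scaled <- pm
  scaled$counts[, 3] <- scaled$counts[, 3] * 7
  ns <- normalize_panel(scaled)
  ratio <- ns$normalized$counts / n1$normalized$counts
  expect_equal(unname(ratio), matrix(7^(1 / ncol(pm$counts)), nrow(ratio),
                                     ncol(ratio)), tolerance = 1e-9)
})

test_that("sample order never affects normalized results", {
  cfg <- sim_config(seed = 14, n_samples = 6)
  pm <- qc_filter(simulate_panel_counts(cfg))$pass
  perm <- c(4, 1, 6, 2, 5, 3)
  pm_perm <- panel_count_matrix(pm$counts[, perm], pm$gene_class)
  n <- normalize_panel(pm)$normalized$counts
  np <- normalize_panel(pm_perm)$normalized$counts
  expect_equal(np, n[, perm])
})

test_that("TIS score is the weighted sum of log2 counts", {
  m <- mk_panel(endo = c(TISG = 7))
  expect_equal(unname(tis_score(m, c(TISG = 1))), log2(8))
  expect_equal(unname(tis_score(m, c(TISG = 0))), 0)
  expect_error(tis_score(m, c(ABSENT = 1)), "ABSENT")
  # doubling every count with unit weights raises scores by ~ the gene count
  cfg <- sim_config(seed = 15, n_samples = 4)
  nm <- normalize_panel(qc_filter(simulate_panel_counts(cfg))$pass)$normalized
  w <- unit_tis_weights()
  s1 <- tis_score(nm, w, pseudocount = 0)
  doubled <- nm; doubled$counts <- doubled$counts * 2
  s2 <- tis_score(doubled, w, pseudocount = 0)
  expect_equal(unname(s2 - s1), rep(length(w), 4))
})

test_that("weights files round-trip and the gene set is table-driven", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene = c("G1", "G2"), weight = c(0.5, -0.25)),
              f, sep = "\t", row.names = FALSE, quote = FALSE)
  w <- read_tis_weights(f)
  expect_equal(w, c(G1 = 0.5, G2 = -0.25))
  expect_equal(length(unit_tis_weights()), length(tis_gene_set()))
})
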