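test_that("interval construction follows the four anchor conventions", {
  ev <- data.frame(
    subject_id = c("P1", "P2", "P3"),
    group = c("a", "a", "b"),
    mono_start = as.Date(c("2020-01-01", "2020-01-01", "2020-02-01")),
    salvage_start = as.Date(c("2020-06-01", NA, NA)),
    progression_date = as.Date(c("2020-11-01", NA, "2020-02-01")),
    death_date = as.Date(c("2020-12-31", NA, "2021-02-01")),
    last_followup = as.Date(c("2020-12-31", "2021-06-30", "2021-02-01")),
    stringsAsFactors = FALSE)
  os1 <- build_intervals(ev, "OS1")
  # 365 days -> 11.99 months under the 30.4375 days/month convention
  expect_equal(os1$time[os1$subject_id == "P1"], 365 / 30.4375,
               tolerance = 1e-9)
  expect_equal(round(os1$time[os1$subject_id == "P1"], 2), 11.99)
  expect_equal(os1$event[os1$subject_id == "P1"], 1L)
  # alive at last follow-up: censored at that date
  expect_equal(os1$event[os1$subject_id == "P2"], 0L)
  expect_equal(os1$time[os1$subject_id == "P2"],
               as.numeric(as.Date("2021-06-30") - as.Date("2020-01-01")) / 30.4375)
  # progression on the start date: time 0, event
  pfs1 <- build_intervals(ev, "PFS1")
  expect_equal(pfs1$time[pfs1$subject_id == "P3"], 0)
  expect_equal(pfs1$event[pfs1$subject_id == "P3"], 1L)
  # PFS2 uses the earlier of progression and death from salvage start;
  # subjects without a salvage anchor are dropped
  pfs2 <- build_intervals(ev, "PFS2")
  expect_equal(pfs2$subject_id, "P1")
  expect_equal(pfs2$event, 1L)
  expect_equal(pfs2$time,
               as.numeric(as.Date("2020-11-01") - as.Date("2020-06-01")) / 30.4375)
  # a stop date before start is an error naming the subject
  bad <- ev; bad$death_date[1] <- as.Date("2019-12-01")
  expect_error(build_intervals(bad, "OS1"), "P1")
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(61)
  rec <- data.frame(time = rexp(300, 0.1), event = 1)
  km <- km_estimate(rec)
  expect_equal(km$fit$surv, empirical_survival(rec$time, km$fit$time))
  # hand-computed median on times 1..10, all events: first t with S <= 0.5
  km10 <- km_estimate(data.frame(time = 1:10, event = 1))
  expect_equal(km10$median, 5)
  # all censored: survival stays 1, median undefined
  kmc <- km_estimate(data.frame(time = 1:5, event = 0))
  expect_equal(kmc$status, "no_events")
  expect_true(is.na(kmc$median))
})

test_that("KM recovers an exponential median within 10% at n = 2000", {
  cfg <- sim_config(seed = 62, survival_medians = c(g = 12),
                    n_per_group = 2000, censoring_rate = 0)
  km <- km_estimate(simulate_survival(cfg))
  expect_lt(abs(km$median - 12) / 12, 0.10)
})

test_that("log-rank handles identical groups, relabeling and power", {
  rec <- data.frame(time = rep(c(1, 2, 3, 4), 2), event = 1,
                    group = rep(c("x", "y"), each = 4))
  lr <- logrank_test(rec)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  expect_error(logrank_test(data.frame(time = 1:3, event = 1, group = "x")),
               "2 groups")
  # invariance under group relabeling
  set.seed(63)
  rec2 <- data.frame(time = rexp(80), event = rbinom(80, 1, 0.8),
                     group = rep(c("x", "y"), 40))
  rec2b <- rec2; rec2b$group <- ifelse(rec2$group == "x", "y", "x")
  expect_equal(logrank_test(rec2)$p_value, logrank_test(rec2b)$p_value)
  # power at the cohort's monotherapy-stop contrast (medians 11.6 vs 1.2,
  # n = 38 vs 17, light censoring): p < 0.001 in most seeds
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    g1 <- rexp(38, log(2) / 11.6); g2 <- rexp(17, log(2) / 1.2)
    rec3 <- data.frame(time = c(g1, g2),
                       event = rbinom(55, 1, 0.9),
                       group = rep(c("cont", "stop"), c(38, 17)))
    if (sum(rec3$event) > 0 && logrank_test(rec3)$p_value < 0.001)
      hits <- hits + 1L
  }
  expect_gte(hits, 19)
})

test_that("Fisher exact matches the hypergeometric enumeration oracle", {
  t1 <- matrix(c(0, 10, 10, 0), 2)
  expect_equal(fisher_exact(t1)$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(fisher_exact(t1)$p_value, fisher_enum_p(0, 10, 10, 0),
               tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 7), 2))$p_value, 1)  # zero margin
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})

test_that("Wilcoxon-Mann-Whitney matches exact enumeration on small samples", {
  r <- wilcoxon_mw(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p_value, 0.1)              # 2/20 arrangements as extreme
  expect_equal(r$method, "exact")
  # identical samples sit at the center: U = n1*n2/2
  ri <- suppressWarnings(wilcoxon_mw(rep(1:4, 3), rep(1:4, 3)))
  expect_equal(unname(ri$U), 12 * 12 / 2)
  expect_gt(ri$p_value, 0.9)
  # rank invariance under a common monotone transform
  set.seed(64)
  x <- rnorm(15); y <- rnorm(18, 0.8)
  expect_equal(wilcoxon_mw(x, y)$p_value,
               wilcoxon_mw(exp(x), exp(y))$p_value)
})

test_that("response summaries reproduce printed percentages from counts", {
  dual <- summarize_responses(c(rep("PR", 2), "CR", rep("SD", 15), rep("PD", 6)))
  expect_equal(dual$n_total, 24)
  expect_equal(dual$disease_control_n, 18)
  expect_equal(dual$disease_control_pct, 75)
  expect_equal(dual$table$pct[dual$table$category == "CR/PR"], 12.5)
  expect_equal(dual$table$pct[dual$table$category == "SD"], 62.5)
  mek <- summarize_responses(c("PR", "PR", "CR", "PD", "SD"))
  expect_equal(mek$table$n[mek$table$category == "CR/PR"], 3)
  expect_equal(mek$table$pct[mek$table$category == "CR/PR"], 60)
  zero <- summarize_responses(rep("PD", 7))
  expect_equal(zero$disease_control_pct, 0)
  expect_error(summarize_responses(c("CR", "MR")), "unknown")
})

test_that("cohort_percent applies integer rounding except exact half percents", {
  expect_equal(cohort_percent(55, 75), 73)    # 73.33 -> 73
  expect_equal(cohort_percent(20, 75), 27)    # 26.67 -> 27
  expect_equal(cohort_percent(17, 55), 31)
  expect_equal(cohort_percent(38, 55), 69)
  expect_equal(cohort_percent(3, 24), 12.5)   # exact half percent kept
  expect_equal(cohort_percent(12, 17), 71)    # 70.59 -> 71
  expect_equal(cohort_percent(2, 17), 12)
})
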