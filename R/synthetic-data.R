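#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by all
#' `simulate_*()` generators. Defaults describe a plausible hypermutant
#' high-grade-glioma cohort profiled by whole-exome sequencing at ~150x,
#' a low-pass microsatellite assay, an immuno-oncology expression panel,
#' indel mutational signatures, and a two-arm survival comparison.
#'
#' @param seed integer master seed; every generator derives its own
#'   substream from it, so partial re-runs are reproducible.
#' @param n_variants number of true somatic variants to simulate.
#' @param purity tumor purity fraction in (0, 1].
#' @param cn_profile list of `c(local_cn, multiplicity)` copy-number states
#'   sampled per variant.
#' @param clonal_fraction fraction of true variants that are clonal (CCF 1).
#' @param subclonal_ccf_range length-2 vector; subclonal CCFs are drawn
#'   uniformly from this interval.
#' @param depth mean sequencing depth (reads) for variants and loci.
#' @param indel_fraction fraction of true variants that are 1-bp indels.
#' @param caller_count_dist named numeric vector over "1".."4": probability
#'   that a true variant is emitted by that many of the four callers.
#' @param false_positive_rate expected caller-private false calls per caller,
#'   as a fraction of `n_variants`.
#' @param n_ms_loci number of A-homopolymer microsatellite loci.
#' @param ms_regime `"deficient"` or `"proficient"` mismatch-repair regime.
#' @param per_locus_deletion_mean per-locus single-base-deletion read
#'   proportion; defaults 0.05 (deficient) / 0.005 (proficient).
#' @param ms_len_range inclusive homopolymer length range to simulate.
#' @param n_samples number of panel samples.
#' @param panel_dispersion negative-binomial dispersion of panel counts.
#' @param signature_mix named fractions over signature ids, summing to 1.
#' @param n_indels number of indels drawn for the 83-channel catalog.
#' @param survival_medians named vector of group median survivals (months).
#' @param n_per_group subjects per survival group.
#' @param censoring_rate probability a survival record is censored.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_variants = 500L,
                       purity = 0.7,
                       cn_profile = list(c(2, 1)),
                       clonal_fraction = 0.7,
                       subclonal_ccf_range = c(0.2, 0.6),
                       depth = 150,
                       indel_fraction = 0.1,
                       caller_count_dist = c("1" = 0.05, "2" = 0.15,
                                             "3" = 0.30, "4" = 0.50),
                       false_positive_rate = 0.05,
                       n_ms_loci = 100L,
                       ms_regime = c("deficient", "proficient"),
                       per_locus_deletion_mean = NULL,
                       ms_len_range = c(10L, 15L),
                       n_samples = 12L,
                       panel_dispersion = 0.1,
                       signature_mix = c(ID1 = 0.5, ID2 = 0.3, ID8 = 0.2),
                       n_indels = 1000L,
                       survival_medians = c(continued = 11.6,
                                            discontinued = 1.2),
                       n_per_group = 50L,
                       censoring_rate = 0.2) {
  ms_regime <- match.arg(ms_regime)
  if (is.null(per_locus_deletion_mean))
    per_locus_deletion_mean <- if (ms_regime == "deficient") 0.05 else 0.005
  cfg <- list(seed = as.integer(seed), n_variants = as.integer(n_variants),
              purity = purity, cn_profile = cn_profile,
              clonal_fraction = clonal_fraction,
              subclonal_ccf_range = subclonal_ccf_range, depth = depth,
              indel_fraction = indel_fraction,
              caller_count_dist = caller_count_dist,
              false_positive_rate = false_positive_rate,
              n_ms_loci = as.integer(n_ms_loci), ms_regime = ms_regime,
              per_locus_deletion_mean = per_locus_deletion_mean,
              ms_len_range = as.integer(ms_len_range),
              n_samples = as.integer(n_samples),
              panel_dispersion = panel_dispersion,
              signature_mix = signature_mix,
              n_indels = as.integer(n_indels),
              survival_medians = survival_medians,
              n_per_group = as.integer(n_per_group),
              censoring_rate = censoring_rate)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  check_fraction(cfg$purity, "purity", allow_zero = FALSE)
  check_fraction(cfg$clonal_fraction, "clonal_fraction")
  check_fraction(cfg$indel_fraction, "indel_fraction")
  check_fraction(cfg$censoring_rate, "censoring_rate")
  check_fraction(cfg$per_locus_deletion_mean, "per_locus_deletion_mean")
  check_fraction(cfg$subclonal_ccf_range, "subclonal_ccf_range")
  if (cfg$subclonal_ccf_range[1] > cfg$subclonal_ccf_range[2])
    stop("subclonal_ccf_range must be (low, high)")
  if (!is.finite(cfg$depth) || cfg$depth <= 0)
    stop("depth must be positive")
  if (abs(sum(cfg$signature_mix) - 1) > 1e-9)
    stop("signature_mix must sum to 1")
  if (any(cfg$signature_mix < 0)) stop("signature_mix fractions must be >= 0")
  if (abs(sum(cfg$caller_count_dist) - 1) > 1e-9 ||
      !setequal(names(cfg$caller_count_dist), c("1", "2", "3", "4")))
    stop("caller_count_dist must be a distribution over 1..4 callers")
  if (cfg$false_positive_rate < 0) stop("false_positive_rate must be >= 0")
  if (any(cfg$survival_medians <= 0)) stop("survival medians must be > 0")
  if (cfg$ms_len_range[1] > cfg$ms_len_range[2] || cfg$ms_len_range[1] < 1)
    stop("ms_len_range must be an increasing pair of positive lengths")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (seed", x$seed, ")\n")
  cat("  variants:", x$n_variants, " purity:", x$purity,
      " clonal fraction:", x$clonal_fraction, "\n")
  cat("  microsatellite loci:", x$n_ms_loci, sprintf("(%s regime)", x$ms_regime), "\n")
  cat("  panel samples:", x$n_samples, " indels:", x$n_indels, "\n")
  cat("  survival groups:", paste(names(x$survival_medians), collapse = ", "), "\n")
  invisible(x)
}

.callers <- c("callerA", "callerB", "callerC", "callerD")

# Gene pool used for annotation; includes the immune-escape panel so that
# downstream flagging is exercised.
.gene_pool <- function() {
  c(immune_escape_genes(), sprintf("GENE%03d", 1:40))
}

#' Simulate per-caller somatic variant call sets with ground truth
#'
#' Generates `n_variants` true somatic variants (SNVs and 1-bp indels) with
#' known CCF, copy-number state and multiplicity; derives the expected VAF
#' via `vaf = ccf * m * p / (p*c + (1-p)*2)`; and emits each variant in `k`
#' of the four pseudo-callers, `k` drawn from `caller_count_dist`. Each
#' caller observes an independent binomial read draw at its own Poisson
#' depth. Caller-private false positives are added at `false_positive_rate`.
#'
#' @param config a [sim_config()].
#' @return list with `callsets` (named list, one variant data frame per
#'   caller) and `truth` (one row per true variant, all generated values).
#' @export
simulate_variant_callsets <- function(config) {
  config <- validate_sim_config(config)
  set.seed(derive_seed(config$seed, "variants"))
  n <- config$n_variants
  bases <- c("A", "C", "G", "T")

  chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
  pos <- sample.int(2e8, n)
  is_indel <- stats::runif(n) < config$indel_fraction
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  # 1-bp insertions/deletions in VCF anchored representation
  del <- is_indel & stats::runif(n) < 0.5
  ref[is_indel & del] <- paste0(ref[is_indel & del],
                                sample(bases, sum(is_indel & del), replace = TRUE))
  alt[is_indel & del] <- substr(ref[is_indel & del], 1, 1)
  ins <- is_indel & !del
  alt[ins] <- paste0(ref[ins], sample(bases, sum(ins), replace = TRUE))

  state <- config$cn_profile[sample.int(length(config$cn_profile), n, replace = TRUE)]
  c_local <- vapply(state, `[`, numeric(1), 1)
  mult <- vapply(state, `[`, numeric(1), 2)
  clonal <- stats::runif(n) < config$clonal_fraction
  ccf <- ifelse(clonal, 1,
                stats::runif(n, config$subclonal_ccf_range[1],
                             config$subclonal_ccf_range[2]))
  p <- config$purity
  true_vaf <- ccf * mult * p / (p * c_local + (1 - p) * 2)
  gene <- sample(.gene_pool(), n, replace = TRUE)

  k <- as.integer(sample(names(config$caller_count_dist), n, replace = TRUE,
                         prob = config$caller_count_dist))
  support <- lapply(k, function(ki) sample(.callers, ki))

  truth <- data.frame(variant_id = sprintf("V%05d", seq_len(n)),
                      chrom = chrom, pos = pos, ref = ref, alt = alt,
                      vclass = ifelse(is_indel, "indel", "SNV"),
                      gene = gene, ccf = ccf, clonal = clonal,
                      purity = p, local_cn = c_local, multiplicity = mult,
                      true_vaf = true_vaf,
                      n_callers = k, stringsAsFactors = FALSE)

  callsets <- lapply(.callers, function(cl) {
    idx <- which(vapply(support, function(s) cl %in% s, logical(1)))
    dp <- pmax(1L, stats::rpois(length(idx), config$depth))
    altn <- stats::rbinom(length(idx), dp, true_vaf[idx])
    df <- data.frame(chrom = chrom[idx], pos = pos[idx], ref = ref[idx],
                     alt = alt[idx],
                     vclass = ifelse(is_indel[idx], "indel", "SNV"),
                     caller = cl, vaf = altn / dp, depth = dp,
                     gene = gene[idx], stringsAsFactors = FALSE)
    n_fp <- stats::rpois(1, config$false_positive_rate * n)
    if (n_fp > 0) {
      fp_ref <- sample(bases, n_fp, replace = TRUE)
      fp_dp <- pmax(1L, stats::rpois(n_fp, config$depth))
      fp <- data.frame(chrom = paste0("chr", sample(1:22, n_fp, replace = TRUE)),
                       pos = sample.int(2e8, n_fp),
                       ref = fp_ref,
                       alt = vapply(fp_ref, function(r)
                         sample(setdiff(bases, r), 1), character(1)),
                       vclass = "SNV", caller = cl,
                       vaf = stats::runif(n_fp, 0.01, 0.10), depth = fp_dp,
                       gene = sample(.gene_pool(), n_fp, replace = TRUE),
                       stringsAsFactors = FALSE)
      df <- rbind(df, fp)
    }
    df[order(df$chrom, df$pos), , drop = FALSE]
  })
  names(callsets) <- .callers
  list(callsets = callsets, truth = truth)
}

#' Simulate A-homopolymer microsatellite locus read summaries
#'
#' Each locus is an adenine homopolymer with length uniform on
#' `ms_len_range`; total reads are Poisson(`depth`) and the count of reads
#' carrying a single-base deletion is binomial with the regime's per-locus
#' proportion (`deficient` default 0.05, `proficient` default 0.005).
#'
#' @param config a [sim_config()].
#' @return data frame with columns locus_id, base, length, total_reads,
#'   del1_reads.
#' @export
simulate_ms_loci <- function(config) {
  config <- validate_sim_config(config)
  if (config$n_ms_loci < 1) stop("n_ms_loci must be >= 1")
  set.seed(derive_seed(config$seed, "msloci"))
  n <- config$n_ms_loci
  len <- sample(seq(config$ms_len_range[1], config$ms_len_range[2]),
                n, replace = TRUE)
  total <- pmax(1L, stats::rpois(n, config$depth))
  del1 <- stats::rbinom(n, total, config$per_locus_deletion_mean)
  data.frame(locus_id = sprintf("MS%04d", seq_len(n)), base = "A",
             length = len, total_reads = total, del1_reads = del1,
             stringsAsFactors = FALSE)
}

# Fixed synthetic gene content of the expression panel: positive-control
# titration ladder, background negative controls, the four housekeeping
# genes, the TIS gene set and generic endogenous genes (103 non-control
# genes in total, matching a compact immuno-oncology panel).
.panel_genes <- function() {
  tis <- tis_gene_set()
  endo_other <- sprintf("ENDO%03d", seq_len(103 - 4 - length(tis)))
  data.frame(
    gene = c(paste0("POS_", LETTERS[1:6]), paste0("NEG_", LETTERS[1:8]),
             housekeeping_genes(), tis, endo_other),
    gene_class = c(rep("positive_control", 6), rep("negative_control", 8),
                   rep("housekeeping", 4),
                   rep("endogenous", length(tis) + length(endo_other))),
    mean = c(8000, 2000, 500, 128, 32, 8,         # POS titration ladder
             rep(8, 8),                           # background
             800, 600, 1000, 700,                 # housekeeping
             rep(NA, length(tis) + length(endo_other))),
    stringsAsFactors = FALSE)
}

#' Simulate an expression-panel count matrix
#'
#' Emulates a hybridization count panel: per-sample multiplicative technical
#' factors (lognormal), negative-binomial counts around gene means, a
#' positive-control titration ladder, background negative controls, the four
#' housekeeping genes and endogenous genes including the TIS set.
#'
#' @param config a [sim_config()].
#' @return a [panel_count_matrix()] with attribute `technical_factors`.
#' @export
simulate_panel_counts <- function(config) {
  config <- validate_sim_config(config)
  if (config$n_samples < 1) stop("n_samples must be >= 1")
  set.seed(derive_seed(config$seed, "panel"))
  genes <- .panel_genes()
  n_endo <- sum(is.na(genes$mean))
  genes$mean[is.na(genes$mean)] <- exp(stats::rnorm(n_endo, log(200), 1))
  tf <- exp(stats::rnorm(config$n_samples, 0, 0.4))
  counts <- matrix(0, nrow(genes), config$n_samples,
                   dimnames = list(genes$gene,
                                   sprintf("S%02d", seq_len(config$n_samples))))
  for (s in seq_len(config$n_samples))
    counts[, s] <- stats::rnbinom(nrow(genes),
                                  mu = genes$mean * tf[s],
                                  size = 1 / config$panel_dispersion)
  # spike-in positive controls are always detected on a real lane
  pos <- genes$gene_class == "positive_control"
  counts[pos, ] <- pmax(counts[pos, ], 1)
  m <- panel_count_matrix(counts, stats::setNames(genes$gene_class, genes$gene))
  attr(m, "technical_factors") <- stats::setNames(tf, colnames(counts))
  m
}

#' Simulate an 83-channel indel catalog from a signature mixture
#'
#' Draws `n_indels` multinomial counts over the 83 indel context channels,
#' with channel probabilities given by the signature matrix columns mixed
#' according to `signature_mix`.
#'
#' @param config a [sim_config()].
#' @param signatures channels x signatures probability matrix; defaults to
#'   the bundled synthetic reference ([example_signatures()]).
#' @return list with `catalog` (named integer vector over the 83 channels)
#'   and `mix` (the true mixture).
#' @export
simulate_indel_catalog <- function(config, signatures = example_signatures()) {
  config <- validate_sim_config(config)
  mix <- config$signature_mix
  missing <- setdiff(names(mix), colnames(signatures))
  if (length(missing))
    stop("signature_mix names absent from signature matrix: ",
         paste(missing, collapse = ", "))
  set.seed(derive_seed(config$seed, "indels"))
  p <- as.vector(signatures[, names(mix), drop = FALSE] %*% mix)
  counts <- if (config$n_indels == 0) integer(nrow(signatures))
            else as.integer(stats::rmultinom(1, config$n_indels, p))
  list(catalog = stats::setNames(counts, rownames(signatures)), mix = mix)
}

#' Simulate cohort survival records
#'
#' Event times are exponential with rate `log(2) / median` per group.
#' Censoring is independent: with probability `censoring_rate` a subject is
#' censored at a uniform time before its event.
#'
#' @param config a [sim_config()].
#' @return data frame with subject_id, group, time (months), event (0/1).
#' @export
simulate_survival <- function(config) {
  config <- validate_sim_config(config)
  set.seed(derive_seed(config$seed, "survival"))
  groups <- names(config$survival_medians)
  out <- lapply(groups, function(g) {
    n <- config$n_per_group
    t_event <- stats::rexp(n, rate = log(2) / config$survival_medians[[g]])
    cens <- stats::runif(n) < config$censoring_rate
    time <- ifelse(cens, stats::runif(n, 0, t_event), t_event)
    data.frame(subject_id = paste0(g, "_", seq_len(n)), group = g,
               time = time, event = as.integer(!cens),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
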