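# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Brute-force two-signature refit: grid over the relative weight of the
# first signature at 1e-4 resolution, with the optimal nonnegative scale in
# closed form for each grid point. Returns the relative weights (f, 1 - f).
grid_nnls_oracle <- function(catalog, s1, s2, step = 1e-4) {
  y <- as.numeric(catalog)
  d <- s1 - s2
  f <- seq(0, 1, by = step)
  yTs <- f * sum(y * d) + sum(y * s2)
  sTs <- f^2 * sum(d * d) + 2 * f * sum(d * s2) + sum(s2 * s2)
  alpha <- pmax(yTs / sTs, 0)
  rss <- sum(y * y) - 2 * alpha * yTs + alpha^2 * sTs
  best <- which.min(rss)
  c(f[best], 1 - f[best])
}

# Two-sided Fisher p by full hypergeometric enumeration (point-probability
# method): sum of probabilities of all tables, at the observed margins,
# whose probability does not exceed the observed table's (within the usual
# relative slack for floating-point ties).
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b          # row 1 margin
  n <- c + d          # row 2 margin
  k <- a + c          # column 1 margin
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Empirical survival function S(t) = P(T > t) evaluated at given times.
empirical_survival <- function(times, at) {
  vapply(at, function(t) mean(times > t), numeric(1))
}

# Homopolymer context provider returning a fixed run length per position,
# looked up from a table built in the test.
make_context_fn <- function(run_table) {
  function(chrom, pos, base) {
    hit <- run_table$run[run_table$chrom == chrom & run_table$pos == pos]
    if (length(hit) != 1) stop("no context for ", chrom, ":", pos)
    hit
  }
}

# Minimal call-set builder for consensus tests.
make_calls <- function(chrom, pos, ref, alt, caller = "callerA",
                       vaf = 0.3, depth = 100, gene = NA_character_) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             vclass = ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV", "indel"),
             caller = caller, vaf = vaf, depth = depth, gene = gene,
             stringsAsFactors = FALSE)
}
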