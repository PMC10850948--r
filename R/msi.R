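#' MMRDness microsatellite-instability score
#'
#' Quantifies mismatch-repair deficiency from low-pass sequencing read
#' summaries at adenine homopolymers. For each locus passing the filters
#' (repeat base 'A', length within \[`min_len`, `max_len`\] inclusive,
#' coverage at least `min_coverage`) the proportion of reads carrying a
#' single-base deletion is computed; the score is
#' `log10(sum of proportions) + 1.1`.
#'
#' Only single-base deletions count as mutated reads; insertions and longer
#' deletions are ignored upstream of this function. When the summed
#' proportion is zero the score is undefined and the result carries status
#' `"below_detection"` rather than `-Inf`.
#'
#' @param loci data frame with columns locus_id, base, length, total_reads,
#'   del1_reads (one row per locus).
#' @param min_len,max_len inclusive homopolymer length bounds (default 10-15).
#' @param min_coverage minimum total reads per locus (default 10); lower
#'   coverage makes per-locus proportions too unstable to sum.
#' @return list of class `mmrdness_result`: n_loci_used, sum_proportions,
#'   score (NA when below detection), offset (1.1), status.
#' @export
mmrdness_score <- function(loci, min_len = 10, max_len = 15,
                           min_coverage = 10) {
  need <- c("locus_id", "base", "length", "total_reads", "del1_reads")
  miss <- setdiff(need, names(loci))
  if (length(miss)) stop("loci missing columns: ", paste(miss, collapse = ", "))
  if (any(loci$del1_reads > loci$total_reads))
    stop("del1_reads cannot exceed total_reads")
  if (anyDuplicated(loci$locus_id))
    stop("one row per locus required; duplicated locus_id present")

  pass <- loci$base == "A" & loci$length >= min_len & loci$length <= max_len &
    loci$total_reads >= min_coverage
  if (!any(pass)) stop("no loci pass the length/coverage filters")
  used <- loci[pass, , drop = FALSE]
  s <- sum(used$del1_reads / used$total_reads)
  status <- if (s > 0) "ok" else "below_detection"
  structure(list(n_loci_used = nrow(used), sum_proportions = s,
                 score = if (s > 0) log10(s) + 1.1 else NA_real_,
                 offset = 1.1, status = status),
            class = "mmrdness_result")
}

#' @export
print.mmrdness_result <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("MMRDness score: %.4f (sum of deletion proportions %.4f over %d loci)\n",
                x$score, x$sum_proportions, x$n_loci_used))
  else
    cat(sprintf("MMRDness score: below detection (no deletion reads in %d loci)\n",
                x$n_loci_used))
  invisible(x)
}
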