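#' Down-sample a clonotype count table
#'
#' Draws exactly `target_reads` reads without replacement from the pooled
#' reads of the table (a multivariate hypergeometric draw across
#' clonotypes), emulating the fixed-depth down-sampling used to make
#' repertoire metrics comparable across libraries of unequal depth.
#' If the table holds fewer reads than the target it is returned unchanged
#' with a warning and attribute `status = "undersized"`.
#'
#' @param table data frame with columns clonotype, chain, count.
#' @param target_reads total reads to retain.
#' @param seed integer seed.
#' @return the down-sampled table (clonotypes with count 0 dropped), with
#'   attribute `status`.
#' @export
downsample_clonotypes <- function(table, target_reads, seed = 1L) {
  validate_clonotypes(table)
  total <- sum(table$count)
  if (total < target_reads) {
    warning("table holds fewer reads (", total, ") than target (",
            target_reads, "); returned unchanged")
    attr(table, "status") <- "undersized"
    return(table)
  }
  set.seed(derive_seed(seed, "downsample"))
  # sequential conditional hypergeometric draws: exact multivariate
  # hypergeometric sample without materializing individual reads
  k <- nrow(table)
  counts <- table$count
  drawn <- integer(k)
  remaining_target <- as.integer(target_reads)
  remaining_total <- total
  for (i in seq_len(k)) {
    if (remaining_target == 0) break
    drawn[i] <- stats::rhyper(1, counts[i], remaining_total - counts[i],
                              remaining_target)
    remaining_target <- remaining_target - drawn[i]
    remaining_total <- remaining_total - counts[i]
  }
  out <- table
  out$count <- drawn
  out <- out[out$count > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "status") <- "ok"
  out
}

validate_clonotypes <- function(table) {
  need <- c("clonotype", "chain", "count")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("clonotype table missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(table) == 0) stop("clonotype table is empty")
  if (any(table$count < 1)) stop("clonotype counts must be >= 1")
  if (anyDuplicated(table[, c("clonotype", "chain")]))
    stop("clonotype identifiers must be unique per chain")
  invisible(table)
}

#' Repertoire summary metrics
#'
#' Clone count (number of unique clonotypes), clonotypes per 1,000 reads
#' (clone count divided by total reads in thousands) and Shannon diversity
#' `H = -sum f_i ln f_i` over clonotype read frequencies (natural log, so a
#' repertoire of k equally abundant clones has H = ln k).
#'
#' @param table data frame with columns clonotype, chain, count.
#' @param per_reads denominator unit for the normalized clone count
#'   (default 1000).
#' @return list of class `repertoire_metrics`: clone_count, total_reads,
#'   clonotypes_per_1000_reads, shannon_diversity.
#' @export
repertoire_metrics <- function(table, per_reads = 1000) {
  validate_clonotypes(table)
  total <- sum(table$count)
  f <- table$count / total
  structure(list(clone_count = nrow(table), total_reads = total,
                 clonotypes_per_1000_reads = nrow(table) / (total / per_reads),
                 shannon_diversity = -sum(f * log(f))),
            class = "repertoire_metrics")
}

#' @export
print.repertoire_metrics <- function(x, ...) {
  cat(sprintf("Repertoire: %d clonotypes in %d reads (%.2f per 1,000 reads), Shannon H = %.3f\n",
              x$clone_count, x$total_reads, x$clonotypes_per_1000_reads,
              x$shannon_diversity))
  invisible(x)
}
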