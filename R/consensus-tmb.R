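#' Immune-escape gene panel
#'
#' Genes involved in antigen presentation and interferon signaling whose
#' somatic disruption marks immune resistance/escape under checkpoint
#' inhibition. "IRF" is kept as printed in the source gene list (no family
#' member number); supply your own vector to resolve it differently.
#'
#' @return character vector of gene symbols.
#' @export
immune_escape_genes <- function() {
  c("B2M", "JAK1", "JAK2", "IFNGR1", "IFNGR2", "TYK2",
    "STAT1", "STAT2", "STAT5A", "STAT5B", "IRF")
}

# Left-trim shared suffix then prefix of a ref/alt pair so that different
# caller representations of the same indel key identically. Position is
# advanced by the number of prefix bases removed.
normalize_allele <- function(chrom, pos, ref, alt) {
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1
  }
  list(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

validate_callset <- function(df, caller = NULL) {
  need <- c("chrom", "pos", "ref", "alt", "vclass", "vaf", "depth")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("call set missing columns: ", paste(miss, collapse = ", "))
  if (any(df$ref == df$alt)) stop("ref must differ from alt")
  check_fraction(df$vaf, "vaf")
  bad_snv <- df$vclass == "SNV" & (nchar(df$ref) != 1 | nchar(df$alt) != 1)
  if (any(bad_snv)) stop("SNV records must have single-base ref and alt")
  if (!"gene" %in% names(df)) df$gene <- NA_character_
  if (!"caller" %in% names(df)) df$caller <- caller %||% NA_character_
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge per-caller call sets by the k-of-n consensus rule
#'
#' Variants are keyed on (chrom, pos, ref, alt) after indel normalization
#' (shared prefix/suffix trimming), deduplicated within each caller, and
#' retained when supported by at least `min_callers` distinct callers.
#' SNVs and indels are merged separately and the results unioned.
#' Consensus VAF and depth are the medians across supporting callers.
#'
#' @param callsets named list (caller -> data frame of calls with columns
#'   chrom, pos, ref, alt, vclass, vaf, depth and optionally gene).
#' @param min_callers minimum number of supporting callers (default 2).
#' @return data frame of class `consensus_variants`: one row per retained
#'   variant with n_callers, callers, median vaf/depth and gene.
#' @export
merge_consensus <- function(callsets, min_callers = 2L) {
  if (length(callsets) < 1) stop("need at least one caller")
  if (is.null(names(callsets)) || any(!nzchar(names(callsets))))
    stop("callsets must be a named list (caller -> calls)")
  min_callers <- as.integer(min_callers)
  if (min_callers < 1) stop("min_callers must be >= 1")

  all_calls <- do.call(rbind, lapply(names(callsets), function(cl) {
    df <- validate_callset(callsets[[cl]], caller = cl)
    df$caller <- cl
    if (nrow(df) == 0) return(df)
    norm <- Map(normalize_allele, df$chrom, df$pos, df$ref, df$alt)
    df$pos <- vapply(norm, `[[`, numeric(1), "pos")
    df$ref <- vapply(norm, `[[`, character(1), "ref")
    df$alt <- vapply(norm, `[[`, character(1), "alt")
    df$key <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
    df[!duplicated(df$key), , drop = FALSE]   # dedup within caller
  }))

  merge_class <- function(calls) {
    if (is.null(calls) || nrow(calls) == 0)
      return(empty_consensus())
    sp <- split(calls, calls$key)
    keep <- sp[vapply(sp, function(g) length(unique(g$caller)), integer(1)) >=
                 min_callers]
    if (!length(keep)) return(empty_consensus())
    do.call(rbind, lapply(keep, function(g) {
      data.frame(chrom = g$chrom[1], pos = g$pos[1], ref = g$ref[1],
                 alt = g$alt[1], vclass = g$vclass[1],
                 n_callers = length(unique(g$caller)),
                 callers = paste(sort(unique(g$caller)), collapse = ","),
                 vaf = stats::median(g$vaf), depth = stats::median(g$depth),
                 gene = g$gene[1], stringsAsFactors = FALSE)
    }))
  }
  res <- rbind(merge_class(all_calls[all_calls$vclass == "SNV", , drop = FALSE]),
               merge_class(all_calls[all_calls$vclass == "indel", , drop = FALSE]))
  res <- res[order(res$chrom, res$pos, res$ref, res$alt), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("consensus_variants", "data.frame"),
            min_callers = min_callers, total_callers = length(callsets))
}

empty_consensus <- function() {
  data.frame(chrom = character(), pos = numeric(), ref = character(),
             alt = character(), vclass = character(), n_callers = integer(),
             callers = character(), vaf = numeric(), depth = numeric(),
             gene = character(), stringsAsFactors = FALSE)
}

#' @export
print.consensus_variants <- function(x, ...) {
  cat(sprintf("Consensus variant set: %d variants (%d SNV, %d indel), >= %d of %d callers\n",
              nrow(x), sum(x$vclass == "SNV"), sum(x$vclass == "indel"),
              attr(x, "min_callers"), attr(x, "total_callers")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Tumor mutational burden
#'
#' TMB is the number of somatic SNVs in the consensus set divided by the
#' callable territory in megabases (~50 Mb for whole-exome capture).
#' Indels are excluded from the numerator.
#'
#' @param consensus a `consensus_variants` set (or data frame with vclass).
#' @param callable_mb callable megabases; default 50.
#' @return list of class `tmb_result`: n_snv, callable_mb, tmb (mut/Mb).
#' @export
compute_tmb <- function(consensus, callable_mb = 50) {
  if (!is.finite(callable_mb) || callable_mb <= 0)
    stop("callable_mb must be > 0")
  n_snv <- sum(consensus$vclass == "SNV")
  structure(list(n_snv = n_snv, callable_mb = callable_mb,
                 tmb = n_snv / callable_mb),
            class = "tmb_result")
}

#' @export
print.tmb_result <- function(x, ...) {
  cat(sprintf("TMB: %.2f mutations/Mb (%d SNVs / %g Mb callable)\n",
              x$tmb, x$n_snv, x$callable_mb))
  invisible(x)
}

#' Count consensus variants in immune-escape genes
#'
#' Tallies consensus variants per panel gene. Matching is case-insensitive
#' after whitespace stripping; panel genes with no hits are reported with a
#' zero count.
#'
#' @param consensus a `consensus_variants` set with gene annotations.
#' @param genes character vector of panel gene symbols
#'   (default [immune_escape_genes()]).
#' @return data frame (gene, n_variants), one row per panel gene.
#' @export
flag_immune_escape <- function(consensus, genes = immune_escape_genes()) {
  if (!length(genes) || anyDuplicated(toupper(genes)))
    stop("gene panel must be non-empty with unique symbols")
  norm <- function(g) toupper(trimws(g))
  hit <- norm(consensus$gene[!is.na(consensus$gene)])
  data.frame(gene = genes,
             n_variants = vapply(norm(genes),
                                 function(g) sum(hit == g), integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
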