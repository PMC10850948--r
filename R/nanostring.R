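#' Default housekeeping gene set
#'
#' The four housekeeping genes whose raw-count geometric mean serves as the
#' per-sample RNA quality/quantity metric.
#'
#' @return character vector of four gene symbols.
#' @export
housekeeping_genes <- function() c("DDX50", "EIF2B4", "MRPS5", "SAP130")

#' Tumor inflammation signature gene set
#'
#' The TIS ("T-cell inflamed gene expression profile") genes: antigen-
#' presenting cell abundance (PSMB10, HLA-DQA1, HLA-DRB1), T/NK cell
#' abundance (HLA-E, NKG7, CD8A), interferon activity (CCL5, CXCL9, CD27,
#' CXCR6, IDO1, STAT1) and T-cell exhaustion (TIGIT, LAG3, CD274, PDCD1LG2,
#' CD276). The operative gene set for scoring is always taken from the
#' weights table, not from this list.
#'
#' @return character vector of gene symbols.
#' @export
tis_gene_set <- function() {
  c("PSMB10", "HLA-DQA1", "HLA-DRB1", "HLA-E", "NKG7", "CD8A",
    "CCL5", "CXCL9", "CD27", "CXCR6", "IDO1", "STAT1",
    "TIGIT", "LAG3", "CD274", "PDCD1LG2", "CD276")
}

#' Construct a classed panel count matrix
#'
#' @param counts genes x samples nonnegative numeric matrix with dimnames.
#' @param gene_class named character vector mapping each gene to one of
#'   `positive_control`, `negative_control`, `housekeeping`, `endogenous`.
#' @return object of class `panel_counts`.
#' @export
panel_count_matrix <- function(counts, gene_class) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (any(counts < 0)) stop("counts must be nonnegative")
  miss <- setdiff(rownames(counts), names(gene_class))
  if (length(miss))
    stop("gene_class missing for: ", paste(utils::head(miss, 5), collapse = ", "))
  gene_class <- gene_class[rownames(counts)]
  ok <- c("positive_control", "negative_control", "housekeeping", "endogenous")
  if (!all(gene_class %in% ok))
    stop("gene_class values must be one of: ", paste(ok, collapse = ", "))
  if (!any(gene_class == "positive_control"))
    stop("at least one positive control gene required")
  structure(list(counts = as.matrix(counts), gene_class = gene_class),
            class = "panel_counts")
}

#' @export
print.panel_counts <- function(x, ...) {
  tab <- table(x$gene_class)
  cat(sprintf("Panel count matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

hk_geomeans <- function(m, housekeeping = housekeeping_genes()) {
  absent <- setdiff(housekeeping, rownames(m$counts))
  if (length(absent))
    stop("housekeeping gene(s) absent from matrix: ",
         paste(absent, collapse = ", "))
  apply(m$counts[housekeeping, , drop = FALSE], 2, geomean)
}

#' QC filter on housekeeping geometric means
#'
#' The per-sample geometric mean of the four housekeeping raw counts is the
#' overall RNA quality/quantity metric; samples with a value strictly below
#' `floor` (default 100) are excluded. A geomean of exactly 100 is retained.
#'
#' @param m a [panel_count_matrix()].
#' @param floor exclusion threshold (default 100, strict `<`).
#' @param housekeeping housekeeping gene symbols.
#' @return list of class `panel_qc`: `pass` (filtered `panel_counts`),
#'   `passing`/`excluded` sample names, `geomeans`, and per-excluded-sample
#'   reasons.
#' @export
qc_filter <- function(m, floor = 100, housekeeping = housekeeping_genes()) {
  gm <- hk_geomeans(m, housekeeping)
  excl <- names(gm)[gm < floor]
  keep <- setdiff(colnames(m$counts), excl)
  if (!length(keep)) stop("all samples excluded by QC")
  structure(list(
    pass = panel_count_matrix(m$counts[, keep, drop = FALSE], m$gene_class),
    passing = keep, excluded = excl, geomeans = gm,
    reasons = stats::setNames(
      sprintf("housekeeping geomean %.2f < %g", gm[excl], floor), excl)),
    class = "panel_qc")
}

#' @export
print.panel_qc <- function(x, ...) {
  cat(sprintf("Panel QC: %d passing, %d excluded\n",
              length(x$passing), length(x$excluded)))
  for (s in x$excluded) cat("  excluded ", s, ": ", x$reasons[[s]], "\n", sep = "")
  invisible(x)
}

# One normalization step: per-sample geomean of the reference gene set,
# grand geomean of those, factor = grand / per-sample, applied to all genes.
normalize_step <- function(m, ref_genes, label) {
  gm <- apply(m$counts[ref_genes, , drop = FALSE], 2, geomean)
  if (any(gm == 0))
    stop("zero geometric mean in ", label, " set for sample(s): ",
         paste(names(gm)[gm == 0], collapse = ", "))
  grand <- geomean(gm)
  factors <- grand / gm
  m$counts <- sweep(m$counts, 2, factors, `*`)
  list(m = m, factors = factors)
}

#' Two-step geometric-mean normalization of panel counts
#'
#' Sequential content normalization: first every sample is scaled so its
#' positive-control geometric mean equals the grand geometric mean across
#' samples (technical normalization), then the identical procedure is
#' applied using the housekeeping genes on the step-1 output (content
#' normalization). Negative controls are carried through but play no role.
#'
#' @param m a QC-passing [panel_count_matrix()].
#' @param housekeeping housekeeping gene symbols.
#' @return list of class `panel_normalized`: `normalized` (panel_counts),
#'   `positive_factors`, `housekeeping_factors`.
#' @export
normalize_panel <- function(m, housekeeping = housekeeping_genes()) {
  pos <- names(m$gene_class)[m$gene_class == "positive_control"]
  absent <- setdiff(housekeeping, rownames(m$counts))
  if (length(absent))
    stop("housekeeping gene(s) absent from matrix: ",
         paste(absent, collapse = ", "))
  s1 <- normalize_step(m, pos, "positive control")
  s2 <- normalize_step(s1$m, housekeeping, "housekeeping")
  structure(list(normalized = s2$m,
                 positive_factors = s1$factors,
                 housekeeping_factors = s2$factors),
            class = "panel_normalized")
}

#' @export
print.panel_normalized <- function(x, ...) {
  cat(sprintf("Normalized panel: %d genes x %d samples\n",
              nrow(x$normalized$counts), ncol(x$normalized$counts)))
  cat("  positive-control factors: ",
      paste(sprintf("%.3f", x$positive_factors), collapse = ", "), "\n")
  cat("  housekeeping factors:     ",
      paste(sprintf("%.3f", x$housekeeping_factors), collapse = ", "), "\n")
  invisible(x)
}

#' Read a TIS weights table
#'
#' Two-column TSV (gene, weight). The operative TIS gene set is whatever
#' this table lists; the published weights live in the signature's
#' reference, so [unit_tis_weights()] is only a documented placeholder.
#'
#' @param path TSV file path.
#' @return named numeric vector of weights.
#' @export
read_tis_weights <- function(path) {
  w <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "weight") %in% names(w)))
    stop("weights file needs columns 'gene' and 'weight'")
  stats::setNames(as.numeric(w$weight), w$gene)
}

#' Placeholder unit weights over the TIS gene set
#'
#' Equal weights of 1 for every gene in [tis_gene_set()]. These are not the
#' published TIS weights; they make the score a plain sum of log2 counts so
#' the mechanics can be exercised and tested.
#'
#' @return named numeric vector of 1s.
#' @export
unit_tis_weights <- function() {
  stats::setNames(rep(1, length(tis_gene_set())), tis_gene_set())
}

#' Tumor inflammation signature score
#'
#' Weighted sum of log2-transformed normalized counts:
#' `score_s = sum_g w_g * log2(count_gs + pseudocount)`. A pseudocount of 1
#' guards against zero counts.
#'
#' @param normalized a normalized [panel_count_matrix()] (or the
#'   `panel_normalized` result).
#' @param weights named numeric vector gene -> weight; see
#'   [read_tis_weights()].
#' @param pseudocount added before the log2 (default 1).
#' @return named numeric vector: one score per sample.
#' @export
tis_score <- function(normalized, weights, pseudocount = 1) {
  if (inherits(normalized, "panel_normalized")) normalized <- normalized$normalized
  counts <- if (inherits(normalized, "panel_counts")) normalized$counts
            else as.matrix(normalized)
  missing <- setdiff(names(weights), rownames(counts))
  if (length(missing))
    stop("weight gene(s) missing from matrix: ",
         paste(missing, collapse = ", "))
  lg <- log2(counts[names(weights), , drop = FALSE] + pseudocount)
  s <- drop(weights %*% lg)
  stats::setNames(as.numeric(s), colnames(counts))
}
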