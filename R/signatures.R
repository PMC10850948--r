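#' The 83 indel context channels
#'
#' Channel names follow the COSMIC ID-83 convention:
#' `<size>:<Del|Ins>:<C|T|R|M>:<n>` — 1-bp deletions/insertions split by the
#' pyrimidine of the affected base pair (C for C:G, T for T:A) and
#' homopolymer run length; longer indels by repeat-unit count (R) and, for
#' deletions, microhomology length (M).
#'
#' @return character vector of 83 channel names in fixed order.
#' @export
id83_channels <- function() {
  ch <- c(
    paste0("1:Del:C:", 0:5), paste0("1:Del:T:", 0:5),
    paste0("1:Ins:C:", 0:5), paste0("1:Ins:T:", 0:5),
    paste0("2:Del:R:", 0:5), paste0("3:Del:R:", 0:5),
    paste0("4:Del:R:", 0:5), paste0("5:Del:R:", 0:5),
    paste0("2:Ins:R:", 0:5), paste0("3:Ins:R:", 0:5),
    paste0("4:Ins:R:", 0:5), paste0("5:Ins:R:", 0:5),
    "2:Del:M:1", "3:Del:M:1", "3:Del:M:2",
    paste0("4:Del:M:", 1:3), paste0("5:Del:M:", 1:5))
  stopifnot(length(ch) == 83)
  ch
}

#' Load a reference indel signature matrix from TSV
#'
#' First column `channel`, remaining columns one probability vector per
#' signature. Columns must sum to 1 (within 1e-6) and the channel set must
#' be the full ID-83 set.
#'
#' @param path TSV file path.
#' @return channels x signatures numeric matrix.
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "channel") stop("first column must be 'channel'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$channel
  validate_signature_matrix(m)
}

validate_signature_matrix <- function(m) {
  if (!setequal(rownames(m), id83_channels()) && nrow(m) != 96)
    stop("signature matrix must cover the 83 indel channels (or an SBS-96 set)")
  if (any(m < 0)) stop("signature probabilities must be >= 0")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-6))
    stop("signature columns must sum to 1: ",
         paste(names(cs)[abs(cs - 1) > 1e-6], collapse = ", "))
  m[if (nrow(m) == 83) id83_channels() else rownames(m), , drop = FALSE]
}

#' Bundled synthetic reference signatures (ID1/ID2/ID8-like)
#'
#' A small synthetic signature matrix shipped for tests and examples:
#' an ID1-like shape (1-bp T insertions at long homopolymers), an ID2-like
#' shape (1-bp T deletions at long homopolymers) and an ID8-like shape
#' (>=5-bp deletions and microhomology deletions, the end-joining footprint
#' of ionizing radiation). These are valid probability columns but are not
#' COSMIC's published values; a real COSMIC v3.2 ID-83 matrix in the same
#' TSV layout is a drop-in replacement.
#'
#' @return 83 x 3 probability matrix.
#' @export
example_signatures <- function() {
  read_signature_matrix(system.file("extdata", "id83_signatures_synthetic.tsv",
                                    package = "rrdkit", mustWork = TRUE))
}

#' Refit an indel catalog against reference signatures
#'
#' Solves the nonnegative least-squares problem
#' `argmin_{w >= 0} || catalog - signatures %*% w ||_2` and reports the
#' absolute contribution (mutations) and relative contribution (fraction of
#' the total fitted burden) of every signature, plus the residual norm.
#'
#' @param catalog named nonnegative counts over the signature matrix's
#'   channels.
#' @param signatures channels x signatures probability matrix.
#' @return list of class `signature_refit`: `absolute`, `relative`,
#'   `residual_norm`, `status` ("ok" or "undefined" for an all-zero
#'   catalog).
#' @export
refit_signatures <- function(catalog, signatures = example_signatures()) {
  signatures <- validate_signature_matrix(signatures)
  if (is.null(names(catalog)))
    stop("catalog must be a named vector over the signature channels")
  if (!setequal(names(catalog), rownames(signatures)))
    stop("catalog channels do not match the signature matrix")
  catalog <- catalog[rownames(signatures)]
  if (any(catalog < 0)) stop("catalog counts must be >= 0")
  if (sum(catalog) == 0) {
    return(structure(list(
      absolute = stats::setNames(rep(0, ncol(signatures)), colnames(signatures)),
      relative = stats::setNames(rep(NA_real_, ncol(signatures)),
                                 colnames(signatures)),
      residual_norm = 0, status = "undefined"), class = "signature_refit"))
  }
  fit <- pracma::lsqnonneg(signatures, as.numeric(catalog))
  w <- stats::setNames(fit$x, colnames(signatures))
  structure(list(absolute = w, relative = w / sum(w),
                 residual_norm = sqrt(sum((catalog - signatures %*% w)^2)),
                 status = "ok"),
            class = "signature_refit")
}

#' @export
print.signature_refit <- function(x, ...) {
  if (x$status == "undefined") {
    cat("Signature refit: undefined (all-zero catalog)\n")
    return(invisible(x))
  }
  cat("Signature refit (residual norm", format(x$residual_norm, digits = 4), ")\n")
  tab <- data.frame(signature = names(x$absolute),
                    absolute = round(x$absolute, 2),
                    relative = round(x$relative, 4))
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' Relative contribution of one signature
#'
#' @param result a [refit_signatures()] result.
#' @param signature_id signature column name, e.g. `"ID8"`.
#' @return fraction of the fitted burden attributed to that signature
#'   (0 is a legitimate value: absence of the signature).
#' @export
relative_contribution <- function(result, signature_id) {
  if (!inherits(result, "signature_refit")) stop("not a signature_refit result")
  if (result$status != "ok") stop("refit did not produce defined relatives")
  if (!signature_id %in% names(result$relative))
    stop("unknown signature id: ", signature_id)
  unname(result$relative[[signature_id]])
}

#' Bin 1-bp indels from variant calls into ID-83 homopolymer channels
#'
#' Bridges anchored VCF-style indel records to the 1-bp homopolymer
#' channels of the ID-83 catalog. A 1-bp deletion of base b within a
#' homopolymer run of length L (counting the deleted base) lands in
#' `1:Del:<class>:<min(L,6)-1>`; a 1-bp insertion adjacent to a run of L
#' like bases lands in `1:Ins:<class>:<min(L,5)>`. The base class is the
#' pyrimidine partner (A/T -> T, C/G -> C). All other indels (and any SNVs)
#' are counted in attribute `unclassified` and excluded from refitting.
#'
#' @param variants data frame with chrom, pos, ref, alt (VCF anchored
#'   representation: 1-bp del has nchar(ref) == 2, nchar(alt) == 1).
#' @param context_fn function(chrom, pos, base) returning the homopolymer
#'   run length of `base` at the locus in the reference.
#' @return named integer catalog over all 83 channels (non-homopolymer
#'   channels zero), with attribute `unclassified`.
#' @export
classify_1bp_indels <- function(variants, context_fn) {
  catalog <- stats::setNames(integer(83), id83_channels())
  unclassified <- 0L
  pyr <- c(A = "T", T = "T", C = "C", G = "C")
  for (i in seq_len(nrow(variants))) {
    ref <- variants$ref[i]; alt <- variants$alt[i]
    if (nchar(ref) == 2 && nchar(alt) == 1 && substr(ref, 1, 1) == alt) {
      base <- substr(ref, 2, 2)                     # 1-bp deletion
      run <- context_fn(variants$chrom[i], variants$pos[i], base)
      ch <- sprintf("1:Del:%s:%d", pyr[[base]], min(run, 6) - 1)
    } else if (nchar(ref) == 1 && nchar(alt) == 2 && substr(alt, 1, 1) == ref) {
      base <- substr(alt, 2, 2)                     # 1-bp insertion
      run <- context_fn(variants$chrom[i], variants$pos[i], base)
      ch <- sprintf("1:Ins:%s:%d", pyr[[base]], min(run, 5))
    } else {
      unclassified <- unclassified + 1L
      next
    }
    catalog[ch] <- catalog[ch] + 1L
  }
  attr(catalog, "unclassified") <- unclassified
  catalog
}
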