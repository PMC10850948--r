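#' Cancer cell fraction of a somatic variant
#'
#' CCF estimates the fraction of tumor cells carrying a mutation from its
#' variant allele fraction, tumor purity and local copy-number state:
#' \deqn{CCF = vaf \cdot (p c + (1-p) c_{normal}) / (m p)}
#' where `p` is tumor purity, `c` the local tumor copy number, `c_normal`
#' the normal copy number (2 for autosomes) and `m` the multiplicity (number
#' of mutated copies). Sampling noise can push the raw estimate above 1;
#' the returned value is capped at 1 for classification, with the raw value
#' kept in attribute `"raw"`.
#'
#' When `multiplicity` is `NULL` it is estimated as
#' `clip(round(vaf*(p*c + (1-p)*c_normal)/p), 1, max(c, 1))`, the usual
#' default in clonality reconstruction.
#'
#' @param vaf variant allele fraction(s) in \[0, 1\].
#' @param purity tumor purity in (0, 1\].
#' @param local_cn local tumor copy number (>= 0).
#' @param multiplicity integer number of mutated copies (>= 1), or `NULL`.
#' @param normal_cn copy number in normal cells (default 2).
#' @param cap cap the returned CCF at 1 (default TRUE).
#' @return numeric CCF vector (capped), with attribute `raw` holding the
#'   uncapped values.
#' @export
compute_ccf <- function(vaf, purity, local_cn, multiplicity = NULL,
                        normal_cn = 2, cap = TRUE) {
  check_fraction(vaf, "vaf")
  check_fraction(purity, "purity", allow_zero = FALSE)
  if (any(local_cn < 0)) stop("local_cn must be >= 0")
  denom_cn <- purity * local_cn + (1 - purity) * normal_cn
  if (is.null(multiplicity))
    multiplicity <- pmin(pmax(1, round(vaf * denom_cn / purity)),
                         pmax(local_cn, 1))
  if (any(multiplicity < 1)) stop("multiplicity must be >= 1")
  raw <- vaf * denom_cn / (multiplicity * purity)
  out <- if (cap) pmin(raw, 1) else raw
  attr(out, "raw") <- raw
  out
}

#' Classify variants as clonal by CCF threshold
#'
#' A variant is clonal when its CCF strictly exceeds the threshold
#' (default 0.85); a CCF exactly at the threshold is subclonal.
#'
#' @param ccf CCF values in \[0, 1\].
#' @param threshold clonality cutoff (default 0.85).
#' @return logical vector.
#' @export
classify_clonal <- function(ccf, threshold = 0.85) {
  check_fraction(as.numeric(ccf), "ccf")
  as.numeric(ccf) > threshold
}

#' Per-variant CCF/clonality table
#'
#' Convenience wrapper producing the one-row-per-variant table written by
#' the pipeline: inputs, capped and raw CCF, and the clonal flag.
#'
#' @inheritParams compute_ccf
#' @param threshold clonality cutoff passed to [classify_clonal()].
#' @return data frame with vaf, purity, local_cn, multiplicity, normal_cn,
#'   ccf_raw, ccf, clonal.
#' @export
ccf_table <- function(vaf, purity, local_cn, multiplicity = NULL,
                      normal_cn = 2, threshold = 0.85) {
  ccf <- compute_ccf(vaf, purity, local_cn, multiplicity, normal_cn)
  if (is.null(multiplicity)) {
    denom_cn <- purity * local_cn + (1 - purity) * normal_cn
    multiplicity <- pmin(pmax(1, round(vaf * denom_cn / purity)),
                         pmax(local_cn, 1))
  }
  data.frame(vaf = vaf, purity = purity, local_cn = local_cn,
             multiplicity = multiplicity, normal_cn = normal_cn,
             ccf_raw = attr(ccf, "raw"), ccf = as.numeric(ccf),
             clonal = classify_clonal(as.numeric(ccf), threshold))
}
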