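#' Write variant calls as minimal VCF v4.2
#'
#' One record per call with CHROM, POS, ID, REF, ALT, QUAL, FILTER and an
#' INFO field carrying `VAF` and `DP`.
#'
#' @param calls data frame with chrom, pos, ref, alt, vaf, depth (and
#'   optionally gene, written as INFO `GENE`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf_minimal <- function(calls, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=VAF,Number=1,Type=Float,Description="Variant allele fraction">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- sprintf("VAF=%.6g;DP=%d", calls$vaf, as.integer(calls$depth))
  if ("gene" %in% names(calls) && any(!is.na(calls$gene)))
    info <- ifelse(is.na(calls$gene), info,
                   paste0(info, ";GENE=", calls$gene))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  calls$chrom, as.integer(calls$pos), calls$ref, calls$alt,
                  info)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a minimal VCF into a variant-call data frame
#'
#' Parses CHROM/POS/REF/ALT via `vcfR`; VAF and DP are taken from the INFO
#' field, or reconstructed from a first sample's FORMAT `AD`/`DP` when the
#' INFO field lacks them. Multiallelic records are split into one row per
#' ALT allele. Records with no recoverable VAF get `NA` and are flagged in
#' attribute `missing_vaf`.
#'
#' @param path VCF file path.
#' @return data frame with chrom, pos, ref, alt, vclass, vaf, depth, gene.
#' @export
read_vcf_minimal <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)      # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  info_vaf <- suppressWarnings(as.numeric(vcfR::extract.info(v, "VAF")))
  info_dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  info_gene <- vcfR::extract.info(v, "GENE")
  if (is.null(info_gene)) info_gene <- rep(NA_character_, nrow(fix))

  # FORMAT AD/DP fallback for VAF
  if (any(is.na(info_vaf)) && ncol(v@gt) >= 2) {
    ad <- vcfR::extract.gt(v, "AD")[, 1]
    dp <- suppressWarnings(as.numeric(vcfR::extract.gt(v, "DP")[, 1]))
    alt_reads <- suppressWarnings(
      as.numeric(vapply(strsplit(ad, ","), function(x)
        if (length(x) >= 2) x[2] else NA_character_, character(1))))
    fill <- is.na(info_vaf) & !is.na(alt_reads) & !is.na(dp) & dp > 0
    info_vaf[fill] <- alt_reads[fill] / dp[fill]
    info_dp[is.na(info_dp)] <- dp[is.na(info_dp)]
  }

  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    data.frame(chrom = fix$CHROM[i], pos = as.numeric(fix$POS[i]),
               ref = fix$REF[i], alt = alts,
               vaf = info_vaf[i], depth = info_dp[i],
               gene = info_gene[i], stringsAsFactors = FALSE,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$vclass <- ifelse(nchar(out$ref) == 1 & nchar(out$alt) == 1,
                       "SNV", "indel")
  out <- out[, c("chrom", "pos", "ref", "alt", "vclass", "vaf", "depth", "gene")]
  attr(out, "missing_vaf") <- which(is.na(out$vaf))
  out
}

#' Read a microsatellite locus table (TSV)
#'
#' @param path TSV with columns locus_id, base, length, total_reads,
#'   del1_reads.
#' @return data frame.
#' @export
read_ms_loci <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus_id", "base", "length", "total_reads", "del1_reads")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("locus table missing columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' Read a clonotype count table (TSV)
#'
#' @param path TSV with columns clonotype, chain, count.
#' @return validated data frame.
#' @export
read_clonotype_table <- function(path) {
  validate_clonotypes(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Read a pipeline/simulation configuration from YAML or JSON
#'
#' @param path file ending in .yaml/.yml or .json.
#' @return named list of configuration values.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .yaml/.yml or .json")
}
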