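#' @keywords internal
"_PACKAGE"

# Geometric mean; returns 0 if any value is 0 (log is never taken of 0).
geomean <- function(x) {
  if (any(is.na(x))) stop("NA values in geometric mean input")
  if (any(x < 0)) stop("negative values in geometric mean input")
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

#' Round half away from zero
#'
#' Rounding convention used for reported percentages: nearest value at the
#' requested number of digits, ties going away from zero (so 12.5 -> 13 at
#' zero digits, -0.5 -> -1), unlike base R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Derive a per-stage 32-bit seed from a master seed and a stage label.
# Keeps all randomness traceable to one integer while decorrelating stages.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) * 2654435 + h * 97 + 13) %% .Machine$integer.max)
}

check_fraction <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  lo <- if (allow_zero) 0 else .Machine$double.eps
  if (any(!is.finite(x)) || any(x < lo) || any(x > 1) || (!allow_one && any(x == 1)))
    stop(sprintf("'%s' must be a fraction in %s", name,
                 paste0(if (allow_zero) "[0," else "(0,", if (allow_one) "1]" else "1)")))
  invisible(x)
}
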