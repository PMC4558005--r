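#' Round half away from zero
#'
#' Commercial ("half-up") rounding: halves round away from zero, unlike
#' [base::round()]'s round-half-to-even. Speeds are carried unrounded
#' internally and rounded half-up only for display, matching how walking
#' speeds are conventionally printed to two decimals.
#'
#' @param x Numeric vector.
#' @param digits Integer number of decimal places (default 0).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' round_half_up(1.045, 2) # 1.05, where round(1.045, 2) gives 1.04
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  scale <- 10^digits
  z <- abs(x) * scale
  # nudge past binary-representation error so values stored just under .5
  # (e.g. 1.0449999999) still round as their decimal value would
  z <- trunc(z + 0.5 + 1e-9)
  sign(x) * z / scale
}

#' Weighted-average empirical percentile
#'
#' The (n+1)-based weighted-average percentile: with sorted values
#' \eqn{x_{(1)} \le \dots \le x_{(n)}} and rank position
#' \eqn{h = (n+1)p/100}, the result interpolates linearly between
#' \eqn{x_{(\lfloor h \rfloor)}} and the next order statistic, clamped to
#' the observed range. This is the definition common statistical packages
#' use by default (equivalent to `stats::quantile(type = 6)`), and is the
#' one used to place the speed-stratum thresholds.
#'
#' @param values Non-empty numeric vector.
#' @param p Percentile in (0, 100).
#' @return A single number.
#' @examples
#' percentile(c(1, 2, 3, 4), 50) # 2.5
#' percentile(c(1, 2, 3, 4), 75) # 3.75
#' @export
percentile <- function(values, p) {
  if (length(values) == 0L) abort("`values` is empty.")
  stopifnot(is.numeric(values), length(p) == 1L, p > 0, p < 100)
  x <- sort(values)
  n <- length(x)
  h <- (n + 1) * p / 100
  if (h <= 1) return(x[1L])
  if (h >= n) return(x[n])
  lo <- floor(h)
  x[lo] + (h - lo) * (x[lo + 1L] - x[lo])
}

# internal: coerce to the ordered stratum factor
as_stratum <- function(x) factor(as.character(x), levels = STRATA)

# internal: coerce to the condition factor, erroring on unknown values
as_condition <- function(x) {
  x <- toupper(as.character(x))
  bad <- setdiff(unique(x), CONDITIONS)
  if (length(bad) > 0) {
    abort(paste0("unknown bout condition(s): ", paste(bad, collapse = ", ")))
  }
  factor(x, levels = CONDITIONS)
}
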