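#' @keywords internal
"_PACKAGE"

# Milliseconds in one day / week, used throughout the retention math.
MS_DAY <- 86400000
MS_WEEK <- 7 * MS_DAY

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Fixed-point rounding with ties going up (half-up), the convention used for
#' every percentage the pipeline prints.  Base `round()` rounds half to even,
#' which would disagree with published two-decimal percentages on boundary
#' ratios.
#'
#' @param x numeric vector (non-negative in all pipeline uses).
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties upward.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Percentage with two-decimal half-up rounding
#'
#' Computes `100 * numerator / denominator` rounded to two decimals, half-up:
#' the form in which engagement and retention proportions are reported.
#'
#' @param numerator count, `0 <= numerator <= denominator`.
#' @param denominator positive count.
#' @param digits decimal places (default 2).
#' @return numeric percentage.
#' @examples
#' proportion_pct(65458, 104067)  # 62.90
#' @export
proportion_pct <- function(numerator, denominator, digits = 2) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(numerator < 0) || any(numerator > denominator)) {
    stop("numerator must lie in [0, denominator]")
  }
  round_half_up(100 * numerator / denominator, digits)
}

# Cumulative sum restarting at each contiguous group in `g`.
group_cumsum <- function(x, g) {
  if (length(x) == 0L) return(numeric(0))
  r <- rle(as.character(g))$lengths
  starts <- cumsum(c(1L, r[-length(r)]))
  cs <- cumsum(x)
  base <- cs[starts] - x[starts]
  cs - rep(base, r)
}

# Epoch-millisecond <-> POSIXct (UTC) helpers.  Milliseconds are stored as
# integer-valued doubles, which represent them exactly.
ms_to_posix <- function(ms) as.POSIXct(ms / 1000, origin = "1970-01-01", tz = "UTC")

posix_to_ms <- function(t) {
  if (is.character(t)) t <- as.POSIXct(t, tz = "UTC")
  if (inherits(t, "POSIXt")) return(round(as.numeric(t) * 1000))
  as.numeric(t)  # plain numerics are taken to be epoch ms already
}

# Stable sort order for an event table: install, then timestamp, input order
# breaking ties (radix sort in base R is stable).
stream_order <- function(install_id, timestamp_ms) {
  order(install_id, timestamp_ms, method = "radix")
}
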