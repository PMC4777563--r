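# small numeric helpers shared across modules

# round half away from zero, to `digits` decimals (report tables round 94.95 up
# to 95.0; base round() would go to even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# money: dollars -> integer-valued cents held in doubles (exact below 2^53)
as_cents <- function(dollars) round(dollars * 100)

cents_to_dollars <- function(cents) cents / 100

# quantile under the two supported conventions
quantile_value <- function(x, prob, method = c("linear_interpolation", "lower_value")) {
  method <- match.arg(method)
  type <- if (method == "linear_interpolation") 7L else 1L
  unname(stats::quantile(x, probs = prob, type = type, names = FALSE))
}

# whole-day difference b - a for Date vectors
days_between <- function(a, b) as.integer(b) - as.integer(a)

#' Percentage shares as printed in report tables
#'
#' `share_percent()` is the percent arithmetic every census and characteristics
#' table uses: `100 * n / denominator`, rounded half-up to one decimal.
#' `allocation_percent()` is the allocation-ledger variant,
#' `100 * allocated / (allocated + remaining)`, same rounding.
#'
#' @param n,denominator count and denominator.
#' @return percent rounded half-up to one decimal.
#' @export
#' @examples
#' share_percent(314550, 587982) # 53.5
share_percent <- function(n, denominator) {
  round_half_up(100 * n / denominator, 1)
}

#' @rdname share_percent
#' @param allocated,remaining in-episode and out-of-episode dollars.
#' @export
#' @examples
#' allocation_percent(251.8, 192.3) # 56.7
allocation_percent <- function(allocated, remaining) {
  round_half_up(100 * allocated / (allocated + remaining), 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(..., call. = call.)
}

.as_date <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  out <- suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) {
    stop(sprintf("invalid %s value(s): %s", what,
                 paste(head(unique(x[bad]), 5), collapse = ", ")), call. = FALSE)
  }
  out[!is.na(x) & x == ""] <- NA
  out
}
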