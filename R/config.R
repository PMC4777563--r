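#' Study configuration
#'
#' Parameters governing episode construction, cohort selection and censoring.
#' Defaults reflect an April-to-March fiscal study year with the conventional
#' 30-day stabilization window and a top-5% expenditure cohort.
#'
#' All dates are calendar dates (day granularity); all intervals are closed
#' `[admit, discharge]`. Encounters with a missing discharge date are treated as
#' ongoing at `study_end` downstream.
#'
#' @param study_start,study_end study period bounds (inclusive), `Date` or
#'   ISO-8601 strings. Costs and episodes are censored at `study_end`.
#' @param window_days stabilization window in days (default 30): an episode
#'   remains open while the next institutional admission falls within
#'   `window_days` of the running discharge date. A gap of exactly
#'   `window_days` chains; `window_days + 1` does not.
#' @param percentile expenditure percentile defining the high-cost cohort
#'   (default 95); selection is strictly greater-than the threshold.
#' @param ed_starts_episode can an emergency-department visit anchor an
#'   episode? Default `TRUE`.
#' @param quantile_method `"linear_interpolation"` (default) or
#'   `"lower_value"`; the quantile convention for the cohort threshold.
#' @param currency_label label attached to money columns in reports.
#' @return an object of class `pce_config` (a validated list).
#' @export
#' @examples
#' cfg <- study_config()
#' cfg$window_days
study_config <- function(study_start = "2010-04-01",
                         study_end = "2011-03-31",
                         window_days = 30L,
                         percentile = 95,
                         ed_starts_episode = TRUE,
                         quantile_method = c("linear_interpolation", "lower_value"),
                         currency_label = "CAD") {
  study_start <- .as_date(study_start, "study_start")
  study_end <- .as_date(study_end, "study_end")
  quantile_method <- match.arg(quantile_method)
  .assert(length(study_start) == 1 && !is.na(study_start), "study_start must be a single date")
  .assert(length(study_end) == 1 && !is.na(study_end), "study_end must be a single date")
  .assert(study_start < study_end, "study_start must precede study_end")
  .assert(is.numeric(window_days) && length(window_days) == 1 && window_days >= 1,
          "window_days must be a single integer >= 1")
  .assert(is.numeric(percentile) && percentile > 0 && percentile < 100,
          "percentile must lie strictly between 0 and 100")
  .assert(is.logical(ed_starts_episode) && length(ed_starts_episode) == 1,
          "ed_starts_episode must be TRUE or FALSE")
  structure(
    list(
      study_start = study_start,
      study_end = study_end,
      window_days = as.integer(window_days),
      percentile = percentile,
      ed_starts_episode = ed_starts_episode,
      quantile_method = quantile_method,
      currency_label = currency_label
    ),
    class = "pce_config"
  )
}

#' @export
print.pce_config <- function(x, ...) {
  cat("<pce_config>\n")
  cat(sprintf("  study period : %s .. %s\n", x$study_start, x$study_end))
  cat(sprintf("  window_days  : %d\n", x$window_days))
  cat(sprintf("  percentile   : %g (strict >)\n", x$percentile))
  cat(sprintf("  ed anchors   : %s\n", x$ed_starts_episode))
  cat(sprintf("  quantiles    : %s\n", x$quantile_method))
  invisible(x)
}
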