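#' Published reference aggregates
#'
#' Aggregate summary tables transcribed from a province-wide application of
#' the person-centred episode methodology (fiscal-year 2010/11 cohort of
#' 587,982 high-cost community-dwelling persons and their 697,059 episodes).
#' The underlying person-level holdings are not available, so these printed
#' aggregates serve two purposes: (a) arithmetic-identity checks — the
#' package's share/percent/mean-times-n arithmetic must reproduce each table's
#' derived column from its count columns — and (b) documentation of the scale
#' the methodology was designed for.
#'
#' @param which one of `"cohort"` (cohort characteristics: `characteristic,
#'   category, n, percent, denominator`), `"groupings"` (episode counts and
#'   cost statistics per clinical grouping, dollars and $ millions), or
#'   `"allocation"` (per-service costs allocated to episodes vs. remaining,
#'   $ millions).
#' @return a `data.table`.
#' @export
#' @examples
#' ref <- reference_table("groupings")
#' ref[ref$grouping == "acute_planned_surgical", c("n", "percent")]
reference_table <- function(which = c("cohort", "groupings", "allocation")) {
  which <- match.arg(which)
  file <- switch(which,
    cohort = "cohort_characteristics.csv",
    groupings = "episode_groupings.csv",
    allocation = "cost_allocation.csv"
  )
  path <- system.file("extdata", "reference", file, package = "pcekit", mustWork = TRUE)
  data.table::fread(path)
}
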